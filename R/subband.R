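#' Fisher score of a labeled feature matrix
#'
#' Ratio of between-class to within-class scatter,
#' `Tr(S_B) / (Tr(S_W) + eps)`, with
#' `S_B = sum_i n_i (m_i - m)(m_i - m)'` and
#' `S_W = sum_i sum_j (x_ij - m_i)(x_ij - m_i)'` over the two classes.
#' Used to rank subbands by how separable their spatially-filtered features
#' are. `eps = 1e-12` guards zero within-class scatter.
#'
#' @param features numeric matrix `n_trials x d`.
#' @param labels vector in `{+1, -1}`, both classes present.
#' @return A non-negative scalar.
#' @examples
#' fisher_score(matrix(c(0, 2, -2, 0)), c(1, 1, -1, -1))  # 1
#' @export
fisher_score <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  classes <- c(1L, -1L)
  if (!all(classes %in% labels))
    stop("empty-class error: both classes must be present")
  m <- colMeans(features)
  tr_sb <- 0
  tr_sw <- 0
  for (k in classes) {
    Xi <- features[labels == k, , drop = FALSE]
    mi <- colMeans(Xi)
    tr_sb <- tr_sb + nrow(Xi) * sum((mi - m)^2)
    tr_sw <- tr_sw + sum(sweep(Xi, 2L, mi)^2)
  }
  tr_sb / (tr_sw + 1e-12)
}

#' Subband weight
#'
#' The frequency-decay weight `w(n) = n^(-a) + b` applied to the squared
#' Fisher score of the `n`-th subband. EEG band power falls with frequency,
#' so for `a > 0` lower-index (lower-frequency) bands are favored; `b` lifts
#' all bands uniformly, damping the decay.
#'
#' @param n band index (1-based).
#' @param a,b non-negative weight parameters.
#' @return `n^(-a) + b`.
#' @export
subband_weight <- function(n, a, b) {
  if (any(n < 1)) stop("band index must be >= 1")
  n^(-a) + b
}

#' Weighted-squared subband criterion
#'
#' Computes `xi_n = w(n) * (f_s^n)^2` for each subband and selects the
#' `k_bands` bands with the largest criterion (ties broken toward the lowest
#' band index). The square sharpens the contrast between subbands; the
#' weight encodes the frequency prior of [subband_weight].
#'
#' @param fs_scores vector of per-band Fisher scores.
#' @param a,b weight parameters (see [subband_weight]).
#' @param k_bands number of bands to select.
#' @return An object of class `subband_scores`: list with `fs_scores`,
#'   `weights`, `xi`, `a`, `b`, `selected` (1-based indices).
#' @export
weighted_scores <- function(fs_scores, a = 0, b = 0, k_bands = 1L) {
  N <- length(fs_scores)
  if (N < 1L) stop("need at least one subband score")
  w <- subband_weight(seq_len(N), a, b)
  xi <- w * fs_scores^2
  if (all(xi == 0)) warning("all subband criteria are zero; selecting band 1")
  # order by xi descending, index ascending on ties
  ord <- order(-xi, seq_len(N))
  structure(list(fs_scores = as.numeric(fs_scores), weights = w, xi = xi,
                 a = a, b = b, selected = ord[seq_len(min(k_bands, N))]),
            class = "subband_scores")
}

#' @export
print.subband_scores <- function(x, ...) {
  cat(sprintf("<subband_scores> N=%d, a=%g, b=%g, selected: %s\n",
              length(x$xi), x$a, x$b, paste(x$selected, collapse = ", ")))
  invisible(x)
}

# deterministic stratified fold assignment (round-robin within class)
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# closed-form ridge classifier used for inner model selection: the
# single-task form of the multi-task weight update with mu = 0, Sigma = I
ridge_cv_accuracy <- function(features, labels, n_folds = 5L, lam = 1) {
  F_ <- add_bias(features)
  fold <- stratified_folds(labels, n_folds)
  correct <- 0L
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) next
    w <- update_ws(F_[tr, , drop = FALSE], labels[tr],
                   mu = rep(0, ncol(F_)), sigma = diag(ncol(F_)), lam = lam)
    pred <- ifelse(F_[!tr, , drop = FALSE] %*% w >= 0, 1L, -1L)
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}

#' Optimal-subband selection by Fisher score and grid search
#'
#' For each `(a, b)` cell of the weight grid, ranks the subbands by the
#' weighted-squared Fisher criterion ([weighted_scores]) and keeps the top
#' `k_bands`; each candidate selection is then scored by stratified
#' `n_folds`-fold cross-validated classification accuracy (closed-form ridge
#' classifier) on the concatenated features of the selected bands, and the
#' `(a, b)` with the best accuracy wins (ties resolved toward the
#' lexicographically smallest `(a, b)`). The criterion value `xi` alone
#' cannot be compared across `(a, b)` — only the induced band ranking
#' changes — which is why an inner accuracy check arbitrates the grid.
#'
#' Fold assignment is deterministic (round-robin within class in trial
#' order), so repeated calls give identical selections.
#'
#' @param band_features list of `n_trials x d` feature matrices, one per
#'   subband, all with the same rows (trials).
#' @param labels vector in `{+1, -1}`.
#' @param grid_a,grid_b candidate values for the weight parameters.
#' @param k_bands number of subbands to select.
#' @param n_folds inner cross-validation folds.
#' @return The winning `subband_scores`, with attributes `cv_accuracy` (its
#'   inner-CV accuracy) and `grid` (a data.frame of all cells evaluated).
#' @export
select_optimal_band <- function(band_features, labels,
                                grid_a = c(0, 0.5, 1, 1.5, 2),
                                grid_b = c(0, 0.5, 1),
                                k_bands = 1L, n_folds = 5L) {
  if (!length(grid_a) || !length(grid_b)) stop("grids must be nonempty")
  if (k_bands < 1L) stop("k_bands must be >= 1")
  fs_scores <- vapply(band_features, fisher_score, numeric(1L), labels = labels)
  cache <- new.env(parent = emptyenv())
  best <- NULL
  best_acc <- -Inf
  rows <- list()
  for (a in sort(grid_a)) {
    for (b in sort(grid_b)) {
      sc <- suppressWarnings(weighted_scores(fs_scores, a, b, k_bands))
      key <- paste(sc$selected, collapse = ",")
      if (is.null(cache[[key]])) {
        feats <- do.call(cbind, band_features[sc$selected])
        cache[[key]] <- ridge_cv_accuracy(feats, labels, n_folds)
      }
      acc <- cache[[key]]
      rows[[length(rows) + 1L]] <- data.frame(a = a, b = b, acc = acc,
                                              selected = key)
      if (acc > best_acc) {            # strict: first (smallest a, b) wins ties
        best_acc <- acc
        best <- sc
      }
    }
  }
  attr(best, "cv_accuracy") <- best_acc
  attr(best, "grid") <- do.call(rbind, rows)
  best
}
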