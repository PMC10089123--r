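#' Class-mean spatial covariance
#'
#' Averages the trace-normalized per-trial covariance `X X' / tr(X X')` over
#' the trials of one class. Trace normalization makes trials commensurate
#' under amplitude drift (the classic CSP convention); the result always has
#' unit trace.
#'
#' @param epochs a labeled [epoch_set].
#' @param k class label, `+1` or `-1`.
#' @return A symmetric `c x c` matrix with trace 1.
#' @export
class_mean_covariance <- function(epochs, k) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$labels)) stop("epochs must be labeled")
  idx <- which(epochs$labels == k)
  if (!length(idx)) stop(sprintf("empty-class error: no trials of class %+d", k))
  c_ <- n_channels(epochs)
  acc <- matrix(0, c_, c_)
  for (i in idx) {
    X <- epochs$data[i, , ]
    C <- tcrossprod(X)
    acc <- acc + C / sum(diag(C))
  }
  R <- acc / length(idx)
  (R + t(R)) / 2
}

# running accumulator used by the evaluation harness: sum of normalized
# per-trial covariances and the trial count, per class
class_cov_sums <- function(epochs) {
  stopifnot(!is.null(epochs$labels))
  c_ <- n_channels(epochs)
  out <- list(`1` = list(sum = matrix(0, c_, c_), n = 0L),
              `-1` = list(sum = matrix(0, c_, c_), n = 0L))
  for (i in seq_len(n_trials(epochs))) {
    X <- epochs$data[i, , ]
    C <- tcrossprod(X)
    C <- C / sum(diag(C))
    key <- as.character(epochs$labels[i])
    out[[key]]$sum <- out[[key]]$sum + C
    out[[key]]$n <- out[[key]]$n + 1L
  }
  out
}

#' Per-class target/source covariance bundle
#'
#' Holds, for one class, the mean spatial covariance of the target subject's
#' (labeled calibration) trials and of the pooled source subjects' trials,
#' together with the trial counts that weight them in the regularized
#' mixture ([rcsp_covariance]).
#'
#' @param C_target,C_source symmetric `c x c` class-mean covariances (either
#'   may be `NULL` when the corresponding count is 0).
#' @param N_l,N_s target / source trial counts (non-negative, not both 0).
#' @return An object of class `class_covariances`.
#' @export
class_covariances <- function(C_target, C_source, N_l, N_s) {
  if (N_l < 0 || N_s < 0 || N_l + N_s == 0)
    stop("need N_l >= 0, N_s >= 0, N_l + N_s > 0")
  if (N_l > 0 && is.null(C_target)) stop("C_target required when N_l > 0")
  if (N_s > 0 && is.null(C_source)) stop("C_source required when N_s > 0")
  structure(list(C_target = C_target, C_source = C_source,
                 N_l = N_l, N_s = N_s),
            class = "class_covariances")
}

#' Regularized class covariance (covariance mixing + shrinkage)
#'
#' Two-stage regularization of a class covariance for few-trial,
#' cross-subject CSP. First the target and pooled-source class covariances
#' are mixed with trial-count weighting,
#' \deqn{\hat C(\beta) = \frac{\beta N_l \bar C_t + (1-\beta) N_s \bar C_s}
#'                            {\beta N_l + (1-\beta) N_s},}
#' then the mixture is shrunk toward a scaled identity,
#' \deqn{\hat C(\beta,\gamma) = (1-\gamma)\,\hat C(\beta) +
#'       \gamma\,\frac{tr(\hat C(\beta))}{c}\, I.}
#' The shrinkage target is the average-eigenvalue identity (`trace/c * I`),
#' so the trace is preserved for every `gamma`. `beta = 1, gamma = 0`
#' recovers the target-only covariance; `beta = 0` uses source subjects
#' only; `gamma = 1` gives the fully shrunk scaled identity.
#'
#' @param cc a [class_covariances] bundle for one class.
#' @param beta mixing weight in `[0, 1]` (weight on the target).
#' @param gamma shrinkage weight in `[0, 1]`.
#' @return A symmetric positive-definite `c x c` matrix.
#' @export
rcsp_covariance <- function(cc, beta, gamma) {
  stopifnot(inherits(cc, "class_covariances"))
  if (beta < 0 || beta > 1 || gamma < 0 || gamma > 1)
    stop("beta and gamma must lie in [0, 1]")
  denom <- beta * cc$N_l + (1 - beta) * cc$N_s
  if (denom == 0)
    stop("degenerate-mixture error: beta * N_l + (1 - beta) * N_s = 0")
  num <- 0
  if (beta * cc$N_l > 0) num <- num + beta * cc$N_l * cc$C_target
  if ((1 - beta) * cc$N_s > 0) num <- num + (1 - beta) * cc$N_s * cc$C_source
  Cb <- num / denom
  c_ <- nrow(Cb)
  (1 - gamma) * Cb + gamma * (sum(diag(Cb)) / c_) * diag(c_)
}

#' Common spatial patterns from a pair of class covariances
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` via
#' whitening of the composite covariance. Eigenvalues are the variance
#' ratios of class 1 in the composite metric and lie in (0, 1); the filters
#' with the largest and smallest eigenvalues respectively maximize the
#' variance of one class relative to the other. The returned matrix keeps
#' the `n_pairs` top and `n_pairs` bottom filters, scaled so that
#' `W' (C1 + C2) W = I` on the kept subspace, with the sign convention that
#' each filter's largest-magnitude entry is positive.
#'
#' @param C1,C2 symmetric positive-definite `c x c` class covariances.
#' @param n_pairs filter pairs to keep; `2 * n_pairs <= c`.
#' @param beta,gamma regularization bookkeeping stored on the model (the
#'   covariances are assumed already regularized).
#' @return An object of class `spatial_filter_model`: list with the filter
#'   matrix `W` (`c x 2 n_pairs`), the full descending eigenvalue vector,
#'   `n_pairs`, `beta`, `gamma`.
#' @examples
#' m <- csp_fit(diag(c(2, 1)), diag(c(1, 2)), n_pairs = 1)
#' m$eigenvalues  # 2/3, 1/3
#' @export
csp_fit <- function(C1, C2, n_pairs = 2L, beta = NA_real_, gamma = NA_real_) {
  c_ <- nrow(C1)
  if (2L * n_pairs > c_) stop("2 * n_pairs must not exceed the channel count")
  Cc <- (C1 + C2 + t(C1 + C2)) / 2
  e <- eigen(Cc, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("decomposition error: composite covariance is not positive definite")
  P <- e$vectors %*% (t(e$vectors) / sqrt(e$values))   # whitener of C1 + C2
  S <- t(P) %*% C1 %*% P
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)        # descending eigenvalues
  Wfull <- P %*% es$vectors
  keep <- c(seq_len(n_pairs), seq.int(c_ - n_pairs + 1L, c_))
  W <- Wfull[, keep, drop = FALSE]
  # determinism across eigen-solvers: largest-|entry| positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = W, eigenvalues = es$values, n_pairs = n_pairs,
                 beta = beta, gamma = gamma),
            class = "spatial_filter_model")
}

#' @export
print.spatial_filter_model <- function(x, ...) {
  cat(sprintf("<spatial_filter_model> %d filters (%d pairs), beta=%s gamma=%s\n",
              ncol(x$W), x$n_pairs, format(x$beta), format(x$gamma)))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Regularized CSP fit from target and source epoch sets
#'
#' Builds the per-class regularized covariances ([rcsp_covariance]) from a
#' (possibly absent) target epoch set and a pooled source epoch set, then
#' fits CSP on the regularized pair. With `beta = 1, gamma = 0` this reduces
#' exactly to CSP on the target alone; with `beta = 0` the filters depend
#' only on the source subjects (the strict leave-one-subject-out setting,
#' where no target labels may be touched).
#'
#' @param target labeled [epoch_set] of target-subject calibration trials,
#'   or `NULL` (then `beta` must be 0).
#' @param source labeled [epoch_set] pooling the source subjects' trials.
#' @param beta,gamma regularization parameters in `[0, 1]`.
#' @param n_pairs filter pairs to keep.
#' @return A `spatial_filter_model` (see [csp_fit]).
#' @export
rcsp_fit <- function(target, source, beta = 0, gamma = 0, n_pairs = 2L) {
  if (is.null(target) && beta > 0)
    stop("beta > 0 requires labeled target trials")
  covs <- lapply(c(1L, -1L), function(k) {
    N_l <- if (is.null(target)) 0L else sum(target$labels == k)
    C_t <- if (N_l > 0) class_mean_covariance(target, k) else NULL
    N_s <- sum(source$labels == k)
    C_s <- if (N_s > 0) class_mean_covariance(source, k) else NULL
    rcsp_covariance(class_covariances(C_t, C_s, N_l, N_s), beta, gamma)
  })
  csp_fit(covs[[1L]], covs[[2L]], n_pairs = n_pairs, beta = beta, gamma = gamma)
}

#' Log-variance features after spatial filtering
#'
#' Projects each trial through the spatial filters and returns the log of
#' each filter's share of the total projected variance,
#' `f_j = log(v_j / sum_j v_j)`. The ratio normalization makes the features
#' invariant to per-trial amplitude scaling. A floor of `1e-12` guards the
#' zero-variance case (with a warning).
#'
#' @param epochs an [epoch_set].
#' @param model a `spatial_filter_model` (or any list with a `W` matrix).
#' @return Numeric matrix `n_trials x ncol(W)`.
#' @export
logvar_features <- function(epochs, model) {
  W <- model$W
  nt <- n_trials(epochs)
  f <- ncol(W)
  out <- matrix(0, nt, f)
  warned <- FALSE
  for (i in seq_len(nt)) {
    Y <- crossprod(W, epochs$data[i, , ])
    v <- rowSums(Y^2)
    tot <- sum(v)
    if (tot <= 0) {
      if (!warned) { warning("zero total projected variance; flooring at 1e-12"); warned <- TRUE }
      v <- v + 1e-12
      tot <- sum(v)
    }
    out[i, ] <- log(pmax(v / tot, 1e-12))
  }
  out
}

#' Log band-power features
#'
#' The band-power (BP) baseline feature set: for each trial, band and
#' channel, the log of the mean squared amplitude of the band-filtered
#' signal (floored at `1e-12`). No spatial filtering is involved.
#'
#' @param epochs an [epoch_set].
#' @param spec a [band_spec].
#' @param order subband Butterworth design order.
#' @return Numeric matrix `n_trials x (n_bands * n_channels)`, bands varying
#'   slowest.
#' @export
bandpower_features <- function(epochs, spec, order = 4L) {
  sub <- fb_decompose(epochs, spec, order = order)
  nt <- n_trials(epochs)
  feats <- lapply(sub, function(e) {
    m <- apply(e$data^2, c(1L, 2L), mean)
    matrix(log(pmax(m, 1e-12)), nt)
  })
  do.call(cbind, feats)
}
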