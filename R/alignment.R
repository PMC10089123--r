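#' Mean trial covariance of an epoch set
#'
#' Computes `(1/N) sum_i X_i X_i' / T` over trials, i.e. the arithmetic mean
#' of per-trial channel covariances, each normalized by the sample count so
#' the scale is variance-like. This is the reference matrix that Euclidean
#' Alignment whitens to the identity. Label-free: all trials (both classes
#' and any unlabeled trials) contribute.
#'
#' If the result is numerically rank deficient (smallest eigenvalue below
#' `1e-12` of the largest) a ridge `1e-10 * trace/c * I` is added with a
#' warning.
#'
#' @param epochs an [epoch_set] with at least one trial and >= 2 channels.
#' @return A symmetric positive-definite `c x c` matrix.
#' @export
mean_trial_covariance <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  c_ <- n_channels(epochs)
  if (c_ < 2L) stop("need at least 2 channels")
  nt <- n_trials(epochs)
  if (nt < 1L) stop("need at least 1 trial")
  ns <- n_samples(epochs)
  # concatenate trials along time: sum_i X_i X_i' = XX' of the wide matrix
  X <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), nrow = c_)
  R <- tcrossprod(X) / (nt * ns)
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    warning("mean trial covariance is rank deficient; adding ridge conditioning")
    R <- R + 1e-10 * (sum(diag(R)) / c_) * diag(c_)
  }
  R
}

# principal (symmetric) inverse square root with relative eigenvalue floor
inv_sqrtm <- function(R, floor_rel = 1e-10) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, floor_rel * max(e$values))
  if (max(lam) <= 0) stop("alignment error: reference matrix is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

#' Euclidean Alignment of a subject's trials
#'
#' Whitens every trial by the inverse principal square root of the subject's
#' mean trial covariance, so that the aligned mean trial covariance is the
#' identity. Applying this per subject makes all subjects share the same
#' reference covariance, shrinking the inter-subject distribution shift that
#' cross-subject (transfer) decoding must bridge. The transform is label-free
#' and is applied after broadband filtering and cropping, before filter-bank
#' decomposition.
#'
#' @param epochs an [epoch_set].
#' @return An object of class `alignment_result`: list with
#'   \describe{
#'     \item{aligned}{the whitened `epoch_set`;}
#'     \item{reference}{the mean trial covariance that was whitened;}
#'     \item{whitener}{its inverse principal square root.}
#'   }
#' @examples
#' ep <- epoch_set(array(rnorm(10 * 4 * 200), c(10, 4, 200)), 250,
#'                 c("C3", "Cz", "C4", "CPz"))
#' res <- euclidean_align(ep)
#' max(abs(mean_trial_covariance(res$aligned) - diag(4)))  # ~1e-16
#' @export
euclidean_align <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  R <- mean_trial_covariance(epochs)
  W <- inv_sqrtm(R)
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), nrow = d[2L])
  Y <- W %*% X
  epochs$data <- aperm(array(Y, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  epochs$meta$aligned <- TRUE
  epochs <- record_history(epochs, "euclidean_align")
  structure(list(aligned = epochs, reference = R, whitener = W),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d-channel Euclidean Alignment, subject %s\n",
              nrow(x$reference), x$aligned$subject_id))
  invisible(x)
}
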