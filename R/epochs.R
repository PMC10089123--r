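#' Labeled multichannel EEG trial container
#'
#' `epoch_set` is the currency passed between every pipeline stage: a numeric
#' tensor of epoched trials (`n_trials x n_channels x n_samples`, microvolts
#' by convention), optional binary labels, the sampling rate and the ordered
#' channel names. Every transformation (filtering, cropping, channel
#' selection, alignment, subband decomposition) returns a new `epoch_set` and
#' appends a one-line record to `meta$history`, so the provenance of any
#' object can be read back in order.
#'
#' @param data numeric 3-d array `[n_trials, n_channels, n_samples]`; all
#'   values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channels character vector of channel names, length `n_channels`.
#' @param labels optional integer vector in `{+1, -1}`, one per trial
#'   (`NULL` for unlabeled data).
#' @param subject_id opaque subject identifier.
#' @param meta list of provenance entries; `meta$history` is a character
#'   vector of applied transformations.
#'
#' @return An object of class `epoch_set`.
#' @examples
#' x <- array(rnorm(4 * 2 * 100), c(4, 2, 100))
#' ep <- epoch_set(x, fs = 250, channels = c("C3", "C4"),
#'                 labels = c(1, -1, 1, -1))
#' ep
#' @export
epoch_set <- function(data, fs, channels, labels = NULL,
                      subject_id = "S1", meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [n_trials, n_channels, n_samples]")
  if (!all(is.finite(data)))
    stop("data error: non-finite values in trial tensor")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (dim(data)[3L] < 1L) stop("`data` must contain at least one sample")
  channels <- as.character(channels)
  if (length(channels) != dim(data)[2L])
    stop("length(channels) must equal dim(data)[2]")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != dim(data)[1L])
      stop("length(labels) must equal the number of trials")
    if (!all(labels %in% c(1L, -1L)))
      stop("labels must be in {+1, -1}")
  }
  if (is.null(meta$history)) meta$history <- character(0)
  structure(
    list(data = data, labels = labels, fs = fs, channels = channels,
         subject_id = as.character(subject_id), meta = meta),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1L], d[2L], d[3L], x$fs))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d (+1) / %d (-1)\n",
                sum(x$labels == 1L), sum(x$labels == -1L)))
  if (length(x$meta$history))
    cat("  history:", paste(x$meta$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @rdname epoch_set
#' @param x an `epoch_set`.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname epoch_set
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname epoch_set
#' @export
n_samples <- function(x) dim(x$data)[3L]

# append a provenance record, returning the modified epoch_set
record_history <- function(epochs, entry) {
  epochs$meta$history <- c(epochs$meta$history, entry)
  epochs
}

#' The 8-channel sensorimotor montage
#'
#' The few-channel montage used throughout: three rows of electrodes over the
#' sensorimotor strip (frontocentral, central, centroparietal), which carry
#' the mu/beta rhythms modulated by hand motor imagery.
#'
#' @return Character vector of the 8 channel names.
#' @export
mi_montage_8 <- function() {
  c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "CP4")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Filters every channel of every trial with a Butterworth band-pass applied
#' forward and backward (zero phase lag; the effective magnitude response is
#' the squared design response). Edge transients are controlled by
#' odd-reflection padding of at least 3x the filter order on both ends.
#'
#' The pipeline default for the broad sensorimotor band is 8--30 Hz at design
#' order 6, covering the mu (8--12 Hz) and beta (18--25 Hz) rhythms where
#' ERD/ERS power changes occur.
#'
#' @param epochs an [epoch_set].
#' @param low,high band corner frequencies in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth design order (>= 1).
#' @return A filtered `epoch_set` of identical shape.
#' @examples
#' ep <- epoch_set(array(rnorm(2 * 1 * 500), c(2, 1, 500)), 250, "Cz")
#' filt <- bandpass_filter(ep, 8, 30)
#' @export
bandpass_filter <- function(epochs, low, high, order = 6L) {
  stopifnot(inherits(epochs, "epoch_set"))
  check_band(low, high, epochs$fs)
  if (order < 1L) stop("`order` must be >= 1")
  ba <- butter_coef(low, high, order, epochs$fs)
  epochs$data <- filter_epoch_array(epochs$data, ba$b, ba$a)
  record_history(epochs, sprintf("bandpass(%g-%g Hz, order %d)", low, high, order))
}

check_band <- function(low, high, fs) {
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high)
    stop(sprintf("invalid band: (%g, %g) Hz requires 0 < low < high", low, high))
  if (high >= fs / 2)
    stop(sprintf("invalid band: high edge %g Hz >= Nyquist %g Hz", high, fs / 2))
  invisible(TRUE)
}

butter_coef <- function(low, high, order, fs) {
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  list(b = flt$b, a = flt$a)
}

# Zero-phase IIR filtering of the columns of a samples x series matrix:
# odd-reflection padding (2*x[1] - x[k] style) to suppress edge transients,
# then a forward and a backward pass of the compiled direct-form II
# transposed filter.
filtfilt_mat <- function(b, a, X) {
  n <- nrow(X)
  np <- 3L * (max(length(a), length(b)) - 1L) * 3L
  if (np >= n) np <- n - 1L
  one_pass <- function(M) {
    top <- 2 * matrix(M[1L, ], np, ncol(M), byrow = TRUE) -
      M[seq(np + 1L, 2L), , drop = FALSE]
    nr <- nrow(M)
    bot <- 2 * matrix(M[nr, ], np, ncol(M), byrow = TRUE) -
      M[seq(nr - 1L, nr - np), , drop = FALSE]
    Mp <- rbind(top, M, bot)
    y <- iir_filter_mat(b, a, Mp)
    y[(np + 1L):(np + nr), , drop = FALSE]
  }
  y <- one_pass(X)
  y <- one_pass(y[n:1L, , drop = FALSE])
  y[n:1L, , drop = FALSE]
}

# reference implementation of the same causal filter built from
# stats::filter (convolution for the MA part, recursive for the AR part);
# kept as an independent cross-check of the compiled kernel
filter_ba_reference <- function(b, a, X) {
  b <- b / a[1L]
  a <- a / a[1L]
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1L, ncol(X)), X)
  v <- stats::filter(Xp, b, method = "convolution", sides = 1L)
  v <- as.matrix(v)[nb:nrow(Xp), , drop = FALSE]
  if (length(a) > 1L)
    y <- stats::filter(v, -a[-1L], method = "recursive")
  else
    y <- v
  matrix(as.numeric(y), nrow(X), ncol(X))
}

# apply a zero-phase (b, a) filter to every (trial, channel) series
filter_epoch_array <- function(data, b, a) {
  d <- dim(data)
  # samples on rows, one column per (channel, trial) series
  X <- matrix(aperm(data, c(3L, 2L, 1L)), nrow = d[3L])
  Y <- filtfilt_mat(b, a, X)
  aperm(array(Y, c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
}

#' Crop epochs to a time window
#'
#' Extracts the samples in the half-open window `[t_start, t_end)` relative
#' to trial onset (the cue at t = 0). The output sample count is
#' `round((t_end - t_start) * fs)`.
#'
#' @param epochs an [epoch_set].
#' @param t_start,t_end window in seconds; `0 <= t_start < t_end <= duration`.
#' @return A cropped `epoch_set`.
#' @examples
#' ep <- epoch_set(array(0, c(1, 1, 1000)), 250, "Cz")
#' n_samples(crop_epochs(ep, 0.5, 3.5))  # 750
#' @export
crop_epochs <- function(epochs, t_start, t_end) {
  stopifnot(inherits(epochs, "epoch_set"))
  ns <- n_samples(epochs)
  dur <- ns / epochs$fs
  if (t_start < 0 || t_start >= t_end || t_end > dur + 1e-9)
    stop(sprintf("range error: crop window [%g, %g) outside epoch [0, %g)",
                 t_start, t_end, dur))
  i0 <- round(t_start * epochs$fs)
  nout <- round((t_end - t_start) * epochs$fs)
  idx <- seq.int(i0 + 1L, i0 + nout)
  if (idx[length(idx)] > ns)
    stop("range error: crop window exceeds available samples")
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  record_history(epochs, sprintf("crop(%g-%g s)", t_start, t_end))
}

#' Select and reorder channels
#'
#' Returns the requested channels in the requested order; values are
#' untouched. The default profile is the 8-channel sensorimotor montage
#' ([mi_montage_8]).
#'
#' @param epochs an [epoch_set].
#' @param names character vector of channel names, all present in
#'   `epochs$channels`.
#' @return An `epoch_set` restricted to `names`, in that order.
#' @export
select_channels <- function(epochs, names = mi_montage_8()) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- match(names, epochs$channels)
  if (anyNA(idx))
    stop("lookup error: unknown channel name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$channels <- epochs$channels[idx]
  record_history(epochs, sprintf("select_channels(%s)", paste(names, collapse = ",")))
}
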