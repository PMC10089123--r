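#' Write an epoch set to the plain-text fixture format
#'
#' One subject per fixture: `<path>.dat` holds the trial tensor as
#' tab-separated text (one line per trial-channel series, trial-major,
#' values printed with `%.17g` so doubles round-trip bit exactly) and
#' `<path>.json` is the metadata sidecar (dims, fs, channels, labels,
#' subject id, provenance history).
#'
#' @param epochs an [epoch_set].
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @seealso [read_epochs]
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  # one row per (trial, channel), samples across
  M <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = d[3L])
  lines <- apply(M, 2L, function(col) paste(sprintf("%.17g", col), collapse = "\t"))
  writeLines(lines, paste0(path, ".dat"))
  meta <- list(format = "vfbrcsp-epochs-v1",
               dims = d, fs = epochs$fs, channels = epochs$channels,
               labels = epochs$labels, subject_id = epochs$subject_id,
               meta = epochs$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an epoch set from the plain-text fixture format
#'
#' @param path file path without extension (expects `<path>.dat` and
#'   `<path>.json`).
#' @return An [epoch_set].
#' @seealso [write_epochs]
#' @export
read_epochs <- function(path) {
  jf <- paste0(path, ".json")
  df <- paste0(path, ".dat")
  if (!file.exists(jf) || !file.exists(df))
    stop("schema error: missing fixture file(s) for ", path)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "vfbrcsp-epochs-v1")
    stop("schema error: ", jf, " is not a vfbrcsp epochs fixture")
  d <- as.integer(meta$dims)
  vals <- scan(df, what = numeric(), quiet = TRUE)
  if (length(vals) != prod(d))
    stop("schema error: ", df, " has ", length(vals),
         " values, expected ", prod(d))
  # rows were written trial-major with samples across; scan reads row by row
  M <- matrix(vals, nrow = d[3L], ncol = d[1L] * d[2L])
  data <- aperm(array(M, c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  labels <- if (is.null(meta$labels) || !length(meta$labels)) NULL
            else as.integer(meta$labels)
  epoch_set(data, fs = as.numeric(meta$fs), channels = meta$channels,
            labels = labels,
            subject_id = meta$subject_id,
            meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Serialize a spatial filter model to JSON
#'
#' @param model a `spatial_filter_model` (see [csp_fit]).
#' @param path output file.
#' @param band_id optional band identifier recorded alongside.
#' @return `path`, invisibly.
#' @export
write_spatial_model <- function(model, path, band_id = NULL) {
  stopifnot(inherits(model, "spatial_filter_model"))
  obj <- list(format = "vfbrcsp-spatial-v1", W = model$W,
              eigenvalues = model$eigenvalues, n_pairs = model$n_pairs,
              beta = model$beta, gamma = model$gamma, band_id = band_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_spatial_model
#' @export
read_spatial_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "vfbrcsp-spatial-v1")
    stop("schema error: ", path, " is not a spatial filter model")
  structure(list(W = as.matrix(obj$W), eigenvalues = obj$eigenvalues,
                 n_pairs = as.integer(obj$n_pairs),
                 beta = obj$beta, gamma = obj$gamma),
            class = "spatial_filter_model")
}

#' Serialize a multi-task classifier model to JSON
#'
#' @param model an `mtl_model` (see [mtl_fit]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mtl_model <- function(model, path) {
  stopifnot(inherits(model, "mtl_model"))
  obj <- list(format = "vfbrcsp-mtl-v1", weights = model$weights,
              mu = model$mu, sigma = model$sigma, lam = model$lam,
              history = model$history, converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_mtl_model
#' @export
read_mtl_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "vfbrcsp-mtl-v1")
    stop("schema error: ", path, " is not an mtl model")
  structure(list(weights = lapply(seq_len(nrow(obj$weights)),
                                  function(i) obj$weights[i, ]),
                 mu = obj$mu, sigma = as.matrix(obj$sigma), lam = obj$lam,
                 history = obj$history, converged = obj$converged),
            class = "mtl_model")
}

#' Adapter contract for BCI Competition IV-2a GDF recordings
#'
#' Placeholder for the external-data path: cue-locked epoching of a GDF
#' recording with the event-code-to-label map left = +1, right = -1, 8- or
#' 22-channel montage. The competition files are an external download and
#' no GDF reader is bundled, so this function documents the contract and
#' stops with a pointer; the rest of the pipeline consumes the
#' [epoch_set] it would produce.
#'
#' @param path path to a GDF file.
#' @param channels channel subset to keep (default [mi_montage_8]).
#' @return (Would return) a labeled [epoch_set].
#' @export
import_gdf <- function(path, channels = mi_montage_8()) {
  stop("import_gdf requires the external BCI Competition IV-2a download and ",
       "a GDF reader; convert the recording to the plain-text fixture ",
       "format (see write_epochs) and use read_epochs instead")
}
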