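VARIANTS <- c("BP", "RCSP", "FBCSP", "CFB-RCSP", "VFB-RCSP")

#' Method configuration for the evaluation harness
#'
#' Bundles everything [loso_evaluate] needs to run one method variant:
#'
#' * `"BP"` — log band power of the broadband (8--30 Hz) signal per
#'   channel, straight to the classifier (no spatial filtering);
#' * `"RCSP"` — regularized CSP on the single broadband, log-variance
#'   features;
#' * `"FBCSP"` — constant filter bank, plain CSP per subband, all-band
#'   features concatenated;
#' * `"CFB-RCSP"` / `"VFB-RCSP"` — constant / variable filter bank, RCSP per
#'   subband, Fisher-score optimal-subband selection, selected-band
#'   features.
#'
#' All variants share the multi-task classifier. In the default strict
#' leave-one-subject-out mode (`calibration = 0`) no target label is ever
#' touched: `beta` is forced to 0 and prediction uses the shared prior mean.
#' With `calibration > 0` the first fraction of the target's trials (in
#' trial order) becomes labeled calibration data: it enters the target
#' class covariances (`beta` mixing), is added as an extra classifier task,
#' and is excluded from testing.
#'
#' `beta`/`gamma` may be fixed numbers or `NULL`, in which case they are
#' chosen per fold by inner cross-validation over `beta_grid`/`gamma_grid`
#' on the broadband RCSP features (the chosen values are reused for every
#' subband and recorded in the audit log).
#'
#' @param variant one of `"BP"`, `"RCSP"`, `"FBCSP"`, `"CFB-RCSP"`,
#'   `"VFB-RCSP"`.
#' @param apply_ea apply Euclidean Alignment per subject before feature
#'   extraction.
#' @param band_scheme optional [band_spec] override for the filter-bank
#'   variants; a config error for variants that use no filter bank.
#' @param n_pairs CSP filter pairs per band.
#' @param beta,gamma RCSP regularization; `NULL` selects by inner CV.
#' @param beta_grid,gamma_grid candidate grids for that selection.
#' @param grid_a,grid_b weight-parameter grids for subband selection.
#' @param k_bands subbands to select (features concatenated if > 1).
#' @param lam classifier noise scale `lambda`.
#' @param calibration fraction of target trials used as labeled calibration
#'   data (0 = strict LOSO).
#' @param few_shot predict with a weight vector calibrated on the
#'   calibration trials instead of the prior mean (needs `calibration > 0`).
#' @param crop optional `c(t_start, t_end)` seconds applied after broadband
#'   filtering.
#' @param broadband broad band-pass edges in Hz.
#' @param broad_order,sub_order Butterworth design orders for the broadband
#'   and subband filters.
#' @param seed recorded in provenance (the harness itself is deterministic).
#' @return An object of class `method_config`.
#' @export
method_config <- function(variant, apply_ea = TRUE, band_scheme = NULL,
                          n_pairs = 2L, beta = NULL, gamma = NULL,
                          beta_grid = seq(0, 0.9, by = 0.1),
                          gamma_grid = c(0, 0.001, 0.01, 0.1),
                          grid_a = c(0, 0.5, 1, 1.5, 2),
                          grid_b = c(0, 0.5, 1),
                          k_bands = 1L, lam = 1, calibration = 0,
                          few_shot = FALSE, crop = NULL,
                          broadband = c(8, 30), broad_order = 6L,
                          sub_order = 4L, seed = 1L) {
  if (!variant %in% VARIANTS)
    stop("config error: unknown variant '", variant, "'; valid variants are: ",
         paste(VARIANTS, collapse = ", "))
  uses_bands <- variant %in% c("FBCSP", "CFB-RCSP", "VFB-RCSP")
  if (!is.null(band_scheme)) {
    if (!uses_bands)
      stop("config error: variant '", variant, "' uses no filter bank")
    stopifnot(inherits(band_scheme, "band_spec"))
  }
  if (few_shot && calibration <= 0)
    stop("config error: few_shot prediction requires calibration > 0")
  if (calibration < 0 || calibration >= 1)
    stop("config error: calibration fraction must be in [0, 1)")
  if (calibration == 0 && !is.null(beta) && beta > 0)
    stop("config error: beta > 0 requires calibration > 0 (target labels)")
  structure(list(variant = variant, apply_ea = apply_ea,
                 band_scheme = band_scheme, n_pairs = as.integer(n_pairs),
                 beta = beta, gamma = gamma, beta_grid = beta_grid,
                 gamma_grid = gamma_grid, grid_a = grid_a, grid_b = grid_b,
                 k_bands = as.integer(k_bands), lam = lam,
                 calibration = calibration, few_shot = few_shot,
                 crop = crop, broadband = broadband,
                 broad_order = as.integer(broad_order),
                 sub_order = as.integer(sub_order), seed = as.integer(seed)),
            class = "method_config")
}

#' Classification accuracy from a confusion matrix
#'
#' @param confusion 2x2 count matrix, rows = truth (`+1` first), columns =
#'   prediction (`+1` first).
#' @return Accuracy in percent.
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total <= 0) stop("undefined: empty confusion matrix")
  100 * sum(diag(confusion)) / total
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_e` is the
#' expected agreement under independent marginals. Defined as 0 when
#' `p_e = 1`.
#'
#' @inheritParams accuracy
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  total <- sum(confusion)
  if (total <= 0) stop("undefined: empty confusion matrix")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

confusion_matrix <- function(truth, pred) {
  m <- matrix(0L, 2L, 2L, dimnames = list(truth = c("+1", "-1"),
                                          pred = c("+1", "-1")))
  m[1L, 1L] <- sum(truth == 1L & pred == 1L)
  m[1L, 2L] <- sum(truth == 1L & pred == -1L)
  m[2L, 1L] <- sum(truth == -1L & pred == 1L)
  m[2L, 2L] <- sum(truth == -1L & pred == -1L)
  m
}

# broadband filter + optional crop + optional per-subject EA
preprocess_subject <- function(epochs, config) {
  out <- bandpass_filter(epochs, config$broadband[1L], config$broadband[2L],
                         config$broad_order)
  if (!is.null(config$crop))
    out <- crop_epochs(out, config$crop[1L], config$crop[2L])
  if (config$apply_ea) out <- euclidean_align(out)$aligned
  out
}

scheme_for_variant <- function(config) {
  if (!is.null(config$band_scheme)) return(config$band_scheme)
  switch(config$variant,
         "FBCSP" = make_cfb(), "CFB-RCSP" = make_cfb(),
         "VFB-RCSP" = make_vfb(), NULL)
}

# pooled class-mean covariances over a set of subjects' precomputed sums
pool_class_covs <- function(covsums, subjects) {
  lapply(c("1", "-1"), function(key) {
    tot <- Reduce(`+`, lapply(covsums[subjects], function(s) s[[key]]$sum))
    n <- sum(vapply(covsums[subjects], function(s) s[[key]]$n, integer(1L)))
    list(C = tot / n, n = n)
  })
}

# regularized class covariance pair from pooled source (and optional target)
# per-class covariances, for both classes
rcsp_pair <- function(src_pool, tgt_pool, beta, gamma) {
  lapply(1:2, function(i) {
    N_l <- if (is.null(tgt_pool)) 0L else tgt_pool[[i]]$n
    C_t <- if (N_l > 0) tgt_pool[[i]]$C else NULL
    rcsp_covariance(
      class_covariances(C_t, src_pool[[i]]$C, N_l, src_pool[[i]]$n),
      beta, gamma)
  })
}

# choose (beta, gamma) by inner CV accuracy on broadband RCSP features
select_reg_params <- function(bb_covsums, prep, src, tgt_pool, config) {
  betas <- if (!is.null(config$beta)) config$beta
           else if (config$calibration > 0) config$beta_grid else 0
  gammas <- if (!is.null(config$gamma)) config$gamma else config$gamma_grid
  if (length(betas) == 1L && length(gammas) == 1L)
    return(list(beta = betas, gamma = gammas))
  src_pool <- pool_class_covs(bb_covsums, src)
  labels <- unlist(lapply(prep[src], function(e) e$labels))
  best <- NULL
  best_acc <- -Inf
  for (b in sort(betas)) {
    for (g in sort(gammas)) {
      covs <- rcsp_pair(src_pool, if (b > 0) tgt_pool else NULL, b, g)
      model <- csp_fit(covs[[1L]], covs[[2L]], config$n_pairs, b, g)
      feats <- do.call(rbind, lapply(prep[src], logvar_features, model = model))
      acc <- ridge_cv_accuracy(feats, labels, lam = config$lam)
      if (acc > best_acc) { best_acc <- acc; best <- list(beta = b, gamma = g) }
    }
  }
  best
}

#' Leave-one-subject-out evaluation of a method variant
#'
#' Each subject is held out in turn as the unseen target; every fitted
#' quantity (spatial filters, regularization parameters, selected subbands,
#' the multi-task prior) is estimated from the remaining subjects only
#' (plus the target's declared calibration trials, if any), and the target
#' subject's remaining trials are classified. An audit log records, per
#' fold, exactly which subjects and trials influenced the fit; the harness
#' is fully deterministic, so a rerun with the same inputs is bit-identical.
#'
#' @param cohort list of labeled [epoch_set], one per subject (>= 2, each
#'   with both classes).
#' @param config a [method_config].
#' @param cache optional environment reused across calls to share the
#'   filter-bank decompositions of the same cohort between variants.
#' @return An object of class `eval_result`: per-subject confusion matrices,
#'   accuracy (percent) and kappa, cohort mean and sd of both, and a
#'   provenance list (config, audit log).
#' @export
loso_evaluate <- function(cohort, config, cache = NULL) {
  stopifnot(inherits(config, "method_config"))
  if (length(cohort) < 2L) stop("need at least 2 subjects")
  for (e in cohort) {
    stopifnot(inherits(e, "epoch_set"))
    if (is.null(e$labels) || !all(c(1L, -1L) %in% e$labels))
      stop("every subject needs trials of both classes")
  }
  nsub <- length(cohort)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  pkey <- key_of("prep", config$apply_ea, paste(config$crop, collapse = "-"),
                 paste(config$broadband, collapse = "-"), config$broad_order)

  prep <- cache_get(cache, pkey, function()
    lapply(cohort, preprocess_subject, config = config))

  scheme <- scheme_for_variant(config)
  if (!is.null(scheme)) {
    bkey <- key_of(pkey, scheme$scheme_name,
                   paste(scheme$bands, collapse = ","), config$sub_order)
    sub <- cache_get(cache, key_of("bands", bkey), function()
      lapply(prep, fb_decompose, spec = scheme, order = config$sub_order))
    covsums <- cache_get(cache, key_of("covsums", bkey), function()
      lapply(sub, function(bands) lapply(bands, class_cov_sums)))
  }
  needs_bb_cov <- config$variant %in% c("RCSP", "CFB-RCSP", "VFB-RCSP")
  if (needs_bb_cov)
    bb_covsums <- cache_get(cache, key_of("bbcov", pkey), function()
      lapply(prep, class_cov_sums))
  if (config$variant == "BP") {
    bp_spec <- band_spec(matrix(config$broadband, 1L), "custom")
    feat_bp <- cache_get(cache, key_of("bp", pkey), function()
      lapply(prep, bandpower_features, spec = bp_spec,
             order = config$broad_order))
  }

  per_subject <- vector("list", nsub)
  audit <- vector("list", nsub)
  for (t in seq_len(nsub)) {
    src <- setdiff(seq_len(nsub), t)
    tgt <- prep[[t]]
    n_t <- n_trials(tgt)
    calib_idx <- integer(0)
    if (config$calibration > 0)
      calib_idx <- seq_len(ceiling(config$calibration * n_t))
    test_idx <- setdiff(seq_len(n_t), calib_idx)
    tgt_cal <- if (length(calib_idx)) subset_trials(tgt, calib_idx) else NULL
    tgt_pool <- if (!is.null(tgt_cal)) {
      cs <- class_cov_sums(tgt_cal)
      lapply(c("1", "-1"), function(k) list(C = cs[[k]]$sum / max(cs[[k]]$n, 1L),
                                            n = cs[[k]]$n))
    } else NULL

    fold_info <- list(target = t, source = src, calibration = calib_idx,
                      tested = test_idx)

    if (config$variant == "BP") {
      tasks <- lapply(src, function(s)
        list(F = add_bias(feat_bp[[s]]), y = prep[[s]]$labels))
      F_test <- add_bias(feat_bp[[t]][test_idx, , drop = FALSE])
      F_cal <- if (length(calib_idx))
        add_bias(feat_bp[[t]][calib_idx, , drop = FALSE]) else NULL
    } else {
      reg <- if (config$variant == "FBCSP") list(beta = 0, gamma = 0)
             else select_reg_params(bb_covsums, prep, src, tgt_pool, config)
      fold_info$beta <- reg$beta
      fold_info$gamma <- reg$gamma

      if (config$variant == "RCSP") {
        src_pool <- pool_class_covs(bb_covsums, src)
        covs <- rcsp_pair(src_pool, if (reg$beta > 0) tgt_pool else NULL,
                          reg$beta, reg$gamma)
        model <- csp_fit(covs[[1L]], covs[[2L]], config$n_pairs,
                         reg$beta, reg$gamma)
        src_feats <- lapply(src, function(s) logvar_features(prep[[s]], model))
        tgt_feats <- logvar_features(tgt, model)
      } else {
        nb <- n_bands(scheme)
        models <- vector("list", nb)
        for (n in seq_len(nb)) {
          src_pool <- pool_class_covs(lapply(covsums, `[[`, n), src)
          tp <- if (reg$beta > 0 && !is.null(tgt_cal)) {
            cs <- class_cov_sums(subset_trials(sub[[t]][[n]], calib_idx))
            lapply(c("1", "-1"), function(k)
              list(C = cs[[k]]$sum / max(cs[[k]]$n, 1L), n = cs[[k]]$n))
          } else NULL
          covs <- rcsp_pair(src_pool, tp, reg$beta, reg$gamma)
          models[[n]] <- csp_fit(covs[[1L]], covs[[2L]], config$n_pairs,
                                 reg$beta, reg$gamma)
        }
        band_feats_src <- lapply(seq_len(nb), function(n)
          do.call(rbind, lapply(src, function(s)
            logvar_features(sub[[s]][[n]], models[[n]]))))
        src_labels <- unlist(lapply(prep[src], function(e) e$labels))
        if (config$variant == "FBCSP") {
          sel <- seq_len(nb)
        } else {
          scores <- select_optimal_band(band_feats_src, src_labels,
                                        grid_a = config$grid_a,
                                        grid_b = config$grid_b,
                                        k_bands = config$k_bands)
          sel <- scores$selected
          fold_info$a <- scores$a
          fold_info$b <- scores$b
          fold_info$selected_bands <- sel
          fold_info$band_edges <- scheme$bands[sel, , drop = FALSE]
        }
        src_feats <- lapply(seq_along(src), function(i)
          do.call(cbind, lapply(sel, function(n) {
            rows <- split_rows(band_feats_src[[n]], prep[src])[[i]]
            rows
          })))
        tgt_feats <- do.call(cbind, lapply(sel, function(n)
          logvar_features(sub[[t]][[n]], models[[n]])))
      }
      tasks <- lapply(seq_along(src), function(i)
        list(F = add_bias(src_feats[[i]]), y = prep[[src[i]]]$labels))
      F_test <- add_bias(tgt_feats[test_idx, , drop = FALSE])
      F_cal <- if (length(calib_idx))
        add_bias(tgt_feats[calib_idx, , drop = FALSE]) else NULL
    }

    if (!is.null(F_cal))
      tasks <- c(tasks, list(list(F = F_cal, y = tgt$labels[calib_idx])))
    model_mtl <- mtl_fit(tasks, lam = config$lam)
    w_pred <- if (config$few_shot && !is.null(F_cal))
      update_ws(F_cal, tgt$labels[calib_idx], model_mtl$mu, model_mtl$sigma,
                config$lam)
    else NULL
    pred <- mtl_predict(F_test, model_mtl, weights = w_pred)
    conf <- confusion_matrix(tgt$labels[test_idx], pred)
    per_subject[[t]] <- conf
    audit[[t]] <- fold_info
  }

  acc <- vapply(per_subject, accuracy, numeric(1L))
  kap <- vapply(per_subject, cohen_kappa, numeric(1L))
  structure(list(
    variant = config$variant,
    confusion = per_subject,
    per_subject = data.frame(
      subject = vapply(cohort, function(e) e$subject_id, character(1L)),
      n_test = vapply(per_subject, sum, numeric(1L)),
      accuracy = acc, kappa = kap),
    mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
    mean_kappa = mean(kap), sd_kappa = stats::sd(kap),
    provenance = list(config = config, audit = audit)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s, %d-fold leave-one-subject-out\n",
              x$variant, nrow(x$per_subject)))
  df <- x$per_subject
  df$accuracy <- sprintf("%.2f", df$accuracy)
  df$kappa <- sprintf("%.2f", df$kappa)
  print(df, row.names = FALSE)
  cat(sprintf("  mean accuracy %.2f +/- %.2f %%, mean kappa %.2f +/- %.2f\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_kappa, x$sd_kappa))
  invisible(x)
}

#' Run a named method variant with default settings
#'
#' Convenience wrapper building the [method_config] for `variant` and
#' calling [loso_evaluate].
#'
#' @inheritParams loso_evaluate
#' @param variant one of `"BP"`, `"RCSP"`, `"FBCSP"`, `"CFB-RCSP"`,
#'   `"VFB-RCSP"`.
#' @param ... passed to [method_config].
#' @return An `eval_result`.
#' @export
run_variant <- function(cohort, variant, ..., cache = NULL) {
  loso_evaluate(cohort, method_config(variant, ...), cache = cache)
}

# --- small internals -------------------------------------------------------

subset_trials <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  if (!is.null(epochs$labels)) epochs$labels <- epochs$labels[idx]
  epochs
}

split_rows <- function(mat, subject_list) {
  counts <- vapply(subject_list, n_trials, integer(1L))
  ends <- cumsum(counts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(counts), function(i)
    mat[starts[i]:ends[i], , drop = FALSE])
}

key_of <- function(...) paste(..., sep = "|")

cache_get <- function(cache, key, compute) {
  if (!is.null(cache[[key]])) return(cache[[key]])
  cache[[key]] <- compute()
  cache[[key]]
}
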