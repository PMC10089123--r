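test_that("class-mean covariance is the mean of trace-normalized covariances", {
  ep <- make_epochs(n_trials = 6, n_channels = 3, n_samples = 200, seed = 4)
  C <- class_mean_covariance(ep, 1)
  expect_equal(sum(diag(C)), 1, tolerance = 1e-10)
  # explicit mean over the class trials
  idx <- which(ep$labels == 1)
  covs <- lapply(idx, function(i) {
    M <- tcrossprod(ep$data[i, , ])
    M / sum(diag(M))
  })
  expect_equal(C, Reduce(`+`, covs) / length(covs), tolerance = 1e-12)
  expect_error(class_mean_covariance(make_epochs(labeled = FALSE), 1),
               "labeled")
  only_pos <- make_epochs()
  only_pos$labels <- rep(1L, 4)
  expect_error(class_mean_covariance(only_pos, -1), "empty-class")
})

test_that("csp on diagonal covariances recovers the closed-form solution", {
  m <- csp_fit(diag(c(2, 1)), diag(c(1, 2)), n_pairs = 1)
  expect_equal(m$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # filters along the coordinate axes, scaled so W' (C1+C2) W = I (3I here)
  expect_equal(abs(m$W), matrix(c(1, 0, 0, 1), 2) / sqrt(3), tolerance = 1e-10)
  # largest-magnitude entry positive
  expect_true(all(apply(m$W, 2, function(w) w[which.max(abs(w))] > 0)))
})

test_that("csp satisfies its scaling contract and swap identity on random SPD pairs", {
  for (seed in 1:5) {
    C1 <- rand_spd(6, seed)
    C2 <- rand_spd(6, seed + 100)
    m <- csp_fit(C1, C2, n_pairs = 2)
    expect_lt(max(abs(t(m$W) %*% (C1 + C2) %*% m$W - diag(4))), 1e-8)
    expect_true(all(m$eigenvalues > 0 & m$eigenvalues < 1))
    expect_true(all(diff(m$eigenvalues) <= 1e-12))
    swapped <- csp_fit(C2, C1, n_pairs = 2)
    expect_equal(swapped$eigenvalues, rev(1 - m$eigenvalues), tolerance = 1e-8)
    # role reversal: top filters of one are bottom filters of the other
    expect_equal(abs(swapped$W[, 3:4]), abs(m$W[, 2:1]), tolerance = 1e-6)
  }
})

test_that("csp filters are invariant (up to sign) under joint congruence", {
  C1 <- rand_spd(4, 1)
  C2 <- rand_spd(4, 2)
  set.seed(3)
  M <- matrix(rnorm(16), 4) + 2 * diag(4)
  m0 <- csp_fit(C1, C2, 1)
  m1 <- csp_fit(t(M) %*% C1 %*% M, t(M) %*% C2 %*% M, 1)
  # eigenvalues are congruence invariants
  expect_equal(m1$eigenvalues, m0$eigenvalues, tolerance = 1e-8)
  # filters transform contravariantly: M w1 ~ w0 up to sign and scale
  for (j in 1:2) {
    v <- M %*% m1$W[, j]
    cosang <- abs(sum(v * m0$W[, j])) / sqrt(sum(v^2) * sum(m0$W[, j]^2))
    expect_gt(cosang, 1 - 1e-8)
  }
})

test_that("regularized covariance reproduces the closed-form mixture cases", {
  cc <- class_covariances(2 * diag(2), diag(2), N_l = 10, N_s = 90)
  # hand-worked mixture: (0.5*10*2I + 0.5*90*I) / 50 = 1.1 I
  expect_equal(rcsp_covariance(cc, beta = 0.5, gamma = 0), 1.1 * diag(2),
               tolerance = 1e-12)
  # beta = 1, gamma = 0 reduces to the target covariance
  expect_equal(rcsp_covariance(cc, 1, 0), 2 * diag(2))
  # beta = 0 uses the source only
  expect_equal(rcsp_covariance(cc, 0, 0), diag(2))
  # gamma = 1 is the fully shrunk scaled identity
  Ct <- rand_spd(4, 8)
  cc2 <- class_covariances(Ct, rand_spd(4, 9), 20, 50)
  full <- rcsp_covariance(cc2, 1, 1)
  expect_equal(full, (sum(diag(Ct)) / 4) * diag(4), tolerance = 1e-12)
  expect_error(rcsp_covariance(class_covariances(diag(2), NULL, 2, 0), 0, 0),
               "degenerate-mixture")
})

test_that("regularized covariance stays SPD and trace-preserving on [0,1]^2", {
  cc <- class_covariances(rand_spd(5, 3), rand_spd(5, 4), 15, 85)
  for (beta in c(0, 0.3, 0.7, 1)) for (gamma in c(0, 0.01, 0.5, 1)) {
    C <- rcsp_covariance(cc, beta, gamma)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    C0 <- rcsp_covariance(cc, beta, 0)
    expect_equal(sum(diag(C)), sum(diag(C0)), tolerance = 1e-10)
  }
})

test_that("rcsp_fit reduces to target csp at beta=1 and to source at beta=0", {
  coh <- small_cohort(2)
  tgt <- coh[[1]]
  src <- coh[[2]]
  m_rcsp <- rcsp_fit(tgt, src, beta = 1, gamma = 0)
  m_csp <- csp_fit(class_mean_covariance(tgt, 1),
                   class_mean_covariance(tgt, -1))
  expect_equal(m_rcsp$W, m_csp$W, tolerance = 1e-8)
  m_src <- rcsp_fit(NULL, src, beta = 0, gamma = 0)
  m_src2 <- csp_fit(class_mean_covariance(src, 1),
                    class_mean_covariance(src, -1))
  expect_equal(m_src$W, m_src2$W, tolerance = 1e-8)
  expect_error(rcsp_fit(NULL, src, beta = 0.5), "target")
})

test_that("rcsp recovers the planted discriminative direction", {
  # strong effect: the top filter must align with the whitened mixing column
  cfg <- synthetic_config(n_subjects = 2, trials_per_class = 60,
                          duration = 2, effect_size = 8, subject_shift = 0,
                          sensor_noise = 0.05, background_density = 0,
                          seed = 17)
  coh <- generate_cohort(cfg)
  prep <- lapply(coh, function(e) bandpass_filter(e, 18, 26, 4))
  m <- rcsp_fit(NULL, prep[[1]], beta = 0, gamma = 0, n_pairs = 1)
  # ground truth: class + 1 boosts source 1, mixed through column 1 of A;
  # the CSP filter w maximizing class-1 variance satisfies w ~ C^-1 a1
  A <- vfbrcsp:::base_mixing(cfg)
  Cavg <- (class_mean_covariance(prep[[1]], 1) +
           class_mean_covariance(prep[[1]], -1)) / 2
  d_expect <- solve(Cavg, A[, 1])
  w <- m$W[, 1]
  cosang <- abs(sum(w * d_expect)) / sqrt(sum(w^2) * sum(d_expect^2))
  expect_gte(cosang, 0.9)
})

test_that("log-variance features follow the ratio formula and its symmetries", {
  # construct projected variances 1 and 3 through an identity model
  ns <- 1000
  set.seed(31)
  X <- rbind(rnorm(ns), sqrt(3) * rnorm(ns))
  ep <- epoch_set(array(X, c(1, 2, ns)), 250, c("A", "B"))
  model <- list(W = diag(2))
  f <- logvar_features(ep, model)
  v <- rowSums(X^2)
  expect_equal(f[1, ], log(v / sum(v)), tolerance = 1e-12)
  expect_equal(f[1, ], c(log(1 / 4), log(3 / 4)), tolerance = 0.2)
  # equal variances across f filters -> all log(1/f)
  eq_data <- array(0, c(1, 2, ns))
  eq_data[1, 1, ] <- X[1, ]
  eq_data[1, 2, ] <- X[1, ]
  eq <- epoch_set(eq_data, 250, c("A", "B"))
  feq <- logvar_features(eq, model)
  expect_equal(unname(feq[1, ]), rep(log(1 / 2), 2), tolerance = 1e-10)
  # amplitude scale invariance
  scaled <- ep
  scaled$data <- 10 * ep$data
  expect_equal(logvar_features(scaled, model), f, tolerance = 1e-10)
  # zero signal is floored with a warning
  zero <- epoch_set(array(0, c(1, 2, 100)), 250, c("A", "B"))
  expect_warning(fz <- logvar_features(zero, model), "floor")
  expect_true(all(is.finite(fz)))
})

test_that("band-power features give A^2/2 for a sinusoid and log(eps) for silence", {
  ep <- sinusoid_epochs(20, fs = 250, dur = 4)
  spec <- band_spec(rbind(c(8, 12), c(18, 22)))
  f <- bandpower_features(ep, spec)
  expect_equal(dim(f), c(1, 2))
  expect_equal(exp(f[1, 2]), 0.5, tolerance = 0.05)  # in-band power
  expect_lt(exp(f[1, 1]), 0.01)                       # out-of-band
  zero <- epoch_set(array(0, c(2, 3, 500)), 250, c("A", "B", "C"))
  fz <- bandpower_features(zero, make_cfb())
  expect_equal(dim(fz), c(2, 10 * 3))
  expect_true(all(fz == log(1e-12)))
})
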