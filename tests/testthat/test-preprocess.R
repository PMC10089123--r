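# analytic magnitude response of the digital Butterworth band-pass obtained
# by bilinear transform: |H(f)|^2 = 1 / (1 + Omega(f)^(2n)), with
# Omega = (v^2 - v1 v2) / (v (v2 - v1)), v = tan(pi f / fs). Zero-phase
# application squares the magnitude. Used as the independent oracle for the
# filtering gains.
butter_gain_zero_phase <- function(f, low, high, order, fs) {
  v <- tan(pi * f / fs)
  v1 <- tan(pi * low / fs)
  v2 <- tan(pi * high / fs)
  omega <- (v^2 - v1 * v2) / (v * (v2 - v1))
  (1 / (1 + omega^(2 * order)))  # one pass is |H|^2 = this; two passes square it
}

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  for (f0 in c(20, 2)) {
    ep <- sinusoid_epochs(f0, fs = 250, dur = 12)
    out <- bandpass_filter(ep, 8, 30, order = 6)
    core <- 1000:2000  # away from epoch edges
    gain <- rms(out$data[1, 1, core]) / rms(ep$data[1, 1, core])
    expected <- butter_gain_zero_phase(f0, 8, 30, 6, 250)
    expect_equal(gain, expected, tolerance = 0.02)
  }
  src20 <- sinusoid_epochs(20, dur = 12)
  in_band <- bandpass_filter(src20, 8, 30, 6)
  expect_gte(rms(in_band$data[1, 1, 1000:2000]) / rms(src20$data[1, 1, 1000:2000]),
             0.95)
  src2 <- sinusoid_epochs(2, dur = 12)
  out_band <- bandpass_filter(src2, 8, 30, 6)
  expect_lte(rms(out_band$data[1, 1, ]) / rms(src2$data[1, 1, ]), 0.1)
})

test_that("filtering is linear, shape preserving, and maps zero to zero", {
  ep <- make_epochs(n_trials = 3, n_channels = 2, n_samples = 400)
  out <- bandpass_filter(ep, 8, 30)
  expect_identical(dim(out$data), dim(ep$data))
  scaled <- ep
  scaled$data <- 2.5 * ep$data
  out_scaled <- bandpass_filter(scaled, 8, 30)
  # linear up to IIR rounding accumulation
  expect_equal(out_scaled$data, 2.5 * out$data, tolerance = 1e-8)
  zero <- epoch_set(array(0, c(2, 2, 300)), 250, c("A", "B"))
  expect_equal(bandpass_filter(zero, 8, 30)$data, zero$data)
})

test_that("band-pass rejects invalid bands and non-finite input", {
  ep <- make_epochs()
  expect_error(bandpass_filter(ep, 8, 130), "Nyquist")
  expect_error(bandpass_filter(ep, 30, 8), "invalid band")
  bad <- make_epochs()
  expect_error({
    bad$data[1, 1, 1] <- NA_real_
    epoch_set(bad$data, bad$fs, bad$channels)
  }, "finite")
})

test_that("cropping yields the documented sample counts", {
  ep250 <- epoch_set(array(0, c(1, 1, 1000)), 250, "Cz")
  expect_equal(n_samples(crop_epochs(ep250, 0.5, 3.5)), 750)
  ep1000 <- epoch_set(array(0, c(1, 1, 4000)), 1000, "Cz")
  expect_equal(n_samples(crop_epochs(ep1000, 0.5, 4.0)), 3500)
})

test_that("cropping composes and the full window is the identity", {
  ep <- make_epochs(n_samples = 1000)
  full <- crop_epochs(ep, 0, n_samples(ep) / ep$fs)
  expect_equal(full$data, ep$data)
  two_step <- crop_epochs(crop_epochs(ep, 0.4, 3.2), 0.4, 2.0)
  one_step <- crop_epochs(ep, 0.8, 2.4)
  expect_equal(two_step$data, one_step$data)
  expect_error(crop_epochs(ep, 2.0, 9.0), "range error")
  expect_error(crop_epochs(ep, -0.5, 2.0), "range error")
})

test_that("channel selection subsets and reorders without touching values", {
  set.seed(2)
  ch22 <- c(mi_montage_8(), paste0("X", 1:14))
  ep <- epoch_set(array(rnorm(3 * 22 * 50), c(3, 22, 50)), 250, ch22)
  sel <- select_channels(ep)  # default montage profile
  expect_identical(sel$channels, mi_montage_8())
  expect_equal(n_channels(sel), 8)
  expect_equal(sel$data[, 1, ], ep$data[, match("FC3", ch22), ])
  ident <- select_channels(ep, ep$channels)
  expect_equal(ident$data, ep$data)
  rev2 <- select_channels(ep, c("C4", "C3"))
  expect_equal(rev2$data[, 1, ], ep$data[, match("C4", ch22), ])
  expect_error(select_channels(ep, c("C3", "XX")), "XX")
})

test_that("every transformation is recorded in meta history", {
  ep <- make_epochs(n_samples = 500)
  out <- select_channels(crop_epochs(bandpass_filter(ep, 8, 30), 0.2, 1.2),
                         c("CH2", "CH1"))
  expect_length(out$meta$history, 3)
  expect_match(out$meta$history[1], "bandpass")
  expect_match(out$meta$history[2], "crop")
  expect_match(out$meta$history[3], "select_channels")
})
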