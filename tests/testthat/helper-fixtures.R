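# small deterministic fixtures built in code

make_epochs <- function(n_trials = 4, n_channels = 2, n_samples = 100,
                        fs = 250, labeled = TRUE, seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n_trials * n_channels * n_samples),
                  c(n_trials, n_channels, n_samples)),
            fs = fs,
            channels = paste0("CH", seq_len(n_channels)),
            labels = if (labeled) rep_len(c(1L, -1L), n_trials) else NULL)
}

sinusoid_epochs <- function(freq, fs = 250, dur = 8, n_trials = 1,
                            n_channels = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * freq * t)
  data <- array(0, c(n_trials, n_channels, length(t)))
  for (i in seq_len(n_trials)) for (j in seq_len(n_channels))
    data[i, j, ] <- s
  epoch_set(data, fs = fs, channels = paste0("CH", seq_len(n_channels)))
}

rms <- function(x) sqrt(mean(x^2))

# random SPD matrix
rand_spd <- function(c_, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(c_ * c_), c_)
  crossprod(A) + diag(c_) * 0.1
}

small_cohort <- function(n_subjects = 3, trials_per_class = 12,
                         duration = 1.5, seed = 7, ...) {
  generate_cohort(synthetic_config(
    n_subjects = n_subjects, trials_per_class = trials_per_class,
    duration = duration, seed = seed, ...))
}

# give an epoch set a nonempty provenance history for round-trip checks
record_roundtrip_meta <- function(ep) select_channels(ep, rev(ep$channels))
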