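# Shared simulation helpers: a shortened paradigm for fast unit tests and
# sample-level generators feeding the attenuation stage directly.

# small but structurally complete paradigm (2 blocks x 3 trials, 13 s)
small_spec <- function() {
  paradigm_spec(pre_rest_s = 1, n_blocks = 2, rest_s = 2.4,
                trials_per_block = 3, close_s = 0.6, open_s = 0.6)
}

# full-paradigm simulation + preprocessing, smallest useful channel count
quick_cohort <- function(n_channels = 4, responsive = 1:2, seed = 1, ...) {
  cfg <- synthetic_config(n_channels = n_channels,
                          responsive_channels = responsive,
                          seed = seed, ...)
  sim <- generate_recording(cfg, paradigm_spec())
  c(sim, hga_preprocess(sim$recording, sim$timeline))
}

# trial_samples drawn from per-cell normal means (channels x blocks x trials)
sampled_trials <- function(mean_arr, sd = 1) {
  noise <- array(stats::rnorm(length(mean_arr), sd = sd), dim = dim(mean_arr))
  trial_samples(mean_arr + noise)
}

# mean array from planted per-trial/per-block amplitude profiles
profile_means <- function(n_channels = 1, s = rep(1, 10), l = rep(1, 10),
                          gain = 1) {
  arr <- array(0, dim = c(n_channels, length(l), length(s)))
  for (b in seq_along(l)) for (tr in seq_along(s))
    arr[, b, tr] <- gain * s[tr] * l[b]
  arr
}
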