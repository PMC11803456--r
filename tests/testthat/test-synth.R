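# Generator checks: spectral shape, determinism, burst placement and
# ground-truth consistency.

test_that("background noise has the configured 1/f spectral slope", {
  cfg <- synthetic_config(n_channels = 1, responsive_channels = integer(0),
                          shared_noise_fraction = 0, seed = 31)
  dur <- 2^16 / 1200
  rec <- generate_background(cfg, dur)
  slope <- oracle_psd_slope(rec$data[, 1], 1200, fmin = 2, fmax = 150)
  expect_lt(abs(slope - (-1)), 0.1)
  # alpha = 2 steepens accordingly
  cfg2 <- synthetic_config(n_channels = 1, responsive_channels = integer(0),
                           shared_noise_fraction = 0, noise_exponent = 2,
                           seed = 31)
  slope2 <- oracle_psd_slope(generate_background(cfg2, dur)$data[, 1], 1200,
                             fmin = 2, fmax = 150)
  expect_lt(abs(slope2 - (-2)), 0.1)
})

test_that("background is deterministic and fully shared when requested", {
  cfg <- synthetic_config(n_channels = 3, responsive_channels = integer(0),
                          seed = 5)
  a <- generate_background(cfg, 2)
  b <- generate_background(cfg, 2)
  expect_identical(a$data, b$data)
  shared <- synthetic_config(n_channels = 3, responsive_channels = integer(0),
                             shared_noise_fraction = 1, seed = 5)
  s <- generate_background(shared, 2)
  expect_equal(s$data[, 1], s$data[, 2])
  expect_equal(s$data[, 1], s$data[, 3])
  expect_error(generate_background(cfg, -1), "positive")
})

test_that("bursts are band-limited, cue-locked and profile-scaled", {
  spec <- paradigm_spec()
  base <- list(n_channels = 2, responsive_channels = 1L, seed = 77,
               short_term_profile = rep(1, 10), long_term_profile = rep(1, 10))
  with_gain <- do.call(synthetic_config, c(base, burst_gain = 0.5))
  no_gain <- do.call(synthetic_config, c(base, burst_gain = 0))
  sim1 <- generate_recording(with_gain, spec)
  sim0 <- generate_recording(no_gain, spec)
  # same seed: background identical, difference isolates the bursts
  burst <- sim1$recording$data[, 1] - sim0$recording$data[, 1]
  expect_true(all(sim1$recording$data[, 2] == sim0$recording$data[, 2]))
  expect_gt(band_power_fraction(burst, 1200, c(60, 170)), 0.9)
  # burst energy sits inside trials, none during rest
  cues <- sim1$timeline[sim1$timeline$label == "close_cue", ]
  rest1 <- sim1$timeline[sim1$timeline$label == "rest", ][1, ]
  rest_idx <- (rest1$onset_s * 1200 + 1):((rest1$onset_s + 12) * 1200)
  expect_equal(sum(burst[rest_idx]^2), 0)
  trial_idx <- (cues$onset_s[1] * 1200 + 1):((cues$onset_s[1] + 1.2) * 1200)
  expect_gt(sum(burst[trial_idx]^2), 0)
  # zero gain: recording equals background everywhere
  expect_identical(sim0$recording$data[, 1] - sim0$recording$data[, 1],
                   numeric(length(burst)))
})

test_that("planted amplitudes follow burst_gain * s[trial] * l[block]", {
  spec <- paradigm_spec()
  s <- c(1, rep(0.5, 9)); l <- c(1, rep(0.25, 9))
  cfg <- synthetic_config(n_channels = 2, responsive_channels = 1L,
                          burst_gain = 1, short_term_profile = s,
                          long_term_profile = l, seed = 13)
  cfg0 <- synthetic_config(n_channels = 2, responsive_channels = 1L,
                           burst_gain = 0, short_term_profile = s,
                           long_term_profile = l, seed = 13)
  burst <- generate_recording(cfg, spec)$recording$data[, 1] -
    generate_recording(cfg0, spec)$recording$data[, 1]
  cues <- cue_events(build_timeline(spec))
  rms_at <- function(b, tr) {
    on <- cues$onset_s[cues$block == b & cues$trial == tr]
    idx <- round((on + 0.55) * 1200):round((on + 0.85) * 1200) # around peak
    sqrt(mean(burst[idx]^2))
  }
  # amplitude ratios across (block, trial) cells track the planted profile
  expect_equal(rms_at(1, 2) / rms_at(1, 1), 0.5, tolerance = 0.25)
  expect_equal(rms_at(2, 1) / rms_at(1, 1), 0.25, tolerance = 0.15)
})

test_that("default profiles have the documented shape", {
  p <- default_profiles()
  expect_length(p$s, 10)
  expect_length(p$l, 10)
  expect_equal(which.max(p$s), 1L)     # first trial is the largest response
  expect_true(all(diff(p$s[1:5]) < 0)) # decay to the fifth trial
  expect_true(all(diff(p$s[5:8]) > 0)) # rebound over 6-8
  expect_lt(p$s[9], p$s[8])            # dip at the ninth
  expect_gt(p$l[1], p$l[2])            # block drop after B1
  expect_true(all(abs(diff(p$l[2:10])) < 0.05)) # then a plateau
  expect_equal(default_profiles(attenuation = FALSE),
               list(s = rep(1, 10), l = rep(1, 10)))
})

test_that("ground truth flags are a deterministic function of the profiles", {
  cfg <- synthetic_config(n_channels = 4, responsive_channels = c(1, 3),
                          short_term_profile = c(1, 1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5),
                          long_term_profile = rep(1, 10))
  gt <- ground_truth(cfg)
  expect_equal(gt$responsive, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(gt$short_term_attenuated, c(TRUE, FALSE, TRUE, FALSE))
  expect_false(any(gt$long_term_attenuated))
  # margin rule: an 18% drop stays below the default 20% margin
  cfg2 <- synthetic_config(n_channels = 1, responsive_channels = 1L,
                           short_term_profile = c(rep(1, 6), rep(0.82, 4)),
                           long_term_profile = rep(1, 10))
  expect_false(ground_truth(cfg2)$short_term_attenuated)
  # recomputing from the emitted profiles reproduces the flags exactly
  sim <- generate_recording(synthetic_config(n_channels = 2,
                                             responsive_channels = 1L,
                                             seed = 2))
  s <- sim$truth$short_term_profile
  drop <- (mean(s[1:3]) - mean(s[7:9])) / mean(s[1:3])
  expect_identical(sim$truth$short_term_attenuated,
                   sim$truth$responsive & drop >= sim$truth$attenuation_margin)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(fs = 1000), "1200")
  expect_error(synthetic_config(n_channels = 2, responsive_channels = 5),
               "out of range")
  expect_error(synthetic_config(short_term_profile = c(1, -1)))
  expect_error(generate_recording(
    synthetic_config(short_term_profile = rep(1, 7)), paradigm_spec()),
    "trials_per_block")
})
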