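# Attenuation statistics: pooling bookkeeping, classification behaviour
# under planted effects and nulls, dynamics curves, baseline drift.

test_that("consecutive-position pooling yields one sample per electrode-block", {
  set.seed(8)
  trials <- sampled_trials(profile_means(n_channels = 60))
  res <- consecutive_position_test(trials, "trial")
  expect_equal(unname(res$n_per_group), rep(600L, 10))
  expect_equal(nrow(res$pairs), 9)
  expect_equal(res$pairs$i, 1:9)
  res_b <- consecutive_position_test(trials, "block")
  expect_equal(unname(res_b$n_per_group), rep(600L, 10))
  # statistics do not depend on electrode ordering
  perm <- sample(60)
  trials_perm <- trial_samples(trials$hga[perm, , ])
  res_perm <- consecutive_position_test(trials_perm, "trial")
  expect_equal(res_perm$H, res$H, tolerance = 1e-12)
  expect_equal(res_perm$pairs$z, res$pairs$z, tolerance = 1e-12)
})

test_that("a planted first-to-second-trial drop is detected consistently", {
  s <- c(1.6, rep(0.4, 9))
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    trials <- sampled_trials(profile_means(n_channels = 12, s = s), sd = 1)
    res <- consecutive_position_test(trials, "trial")
    hits <- hits + (res$pairs$p_adjusted[1] < 0.05)
  }
  expect_gte(hits, 18)  # >= 90% of replicates
})

test_that("the consecutive-pair family controls false positives", {
  set.seed(314)
  fp <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    trials <- sampled_trials(profile_means(n_channels = 6))
    res <- consecutive_position_test(trials, "trial")
    fp <- fp + any(res$pairs$p_adjusted < 0.05)
  }
  margin <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fp / n_rep, 0.05 + margin)
})

test_that("classification groups carry 30 (NR) and 27 (R) samples and detect drops", {
  s_drop <- c(1, 1, 1, 0.9, 0.8, 0.7, 0.5, 0.5, 0.5, 0.5) # 50% NR3 vs NR1
  set.seed(99)
  trials <- sampled_trials(profile_means(n_channels = 1, s = s_drop, gain = 6),
                           sd = 1)
  res <- classify_attenuation(trials)
  spg <- attr(res, "samples_per_group")
  expect_equal(spg$nr, rep(30L, 3), ignore_attr = TRUE)
  expect_equal(spg$r, rep(27L, 3), ignore_attr = TRUE)
  expect_equal(res$nr1_n, 30)
  expect_equal(res$r1_n, 27)
  expect_true(res$nr_attenuated)
  expect_false(res$r_attenuated)
  # rank-based: any strictly increasing transform leaves the class unchanged
  trials_t <- trial_samples(exp(trials$hga / 4))
  res_t <- classify_attenuation(trials_t)
  expect_equal(res_t$nr_attenuated, res$nr_attenuated)
  expect_equal(res_t$nr_p13_adj, res$nr_p13_adj, tolerance = 1e-12)
})

test_that("classification direction rule: significantly *lower* only", {
  s_rise <- c(0.5, 0.5, 0.5, 0.7, 0.8, 0.9, 1, 1, 1, 1)
  set.seed(100)
  trials <- sampled_trials(profile_means(n_channels = 1, s = s_rise, gain = 6))
  res <- classify_attenuation(trials)
  expect_false(res$nr_attenuated)       # NR3 is higher, not lower
  expect_lt(res$nr_p13_adj, 0.05)       # despite a significant difference
})

test_that("null data stays below the false-positive budget and degenerate data warns", {
  set.seed(271)
  fp_nr <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    trials <- sampled_trials(profile_means(n_channels = 1))
    res <- classify_attenuation(trials)
    fp_nr <- fp_nr + res$nr_attenuated
  }
  margin <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fp_nr / n_rep, 0.05 + margin)
  # all-tied electrode: not attenuated, flagged
  flat <- trial_samples(array(1, dim = c(1, 10, 10)))
  expect_warning(res <- classify_attenuation(flat), "degenerate")
  expect_false(res$nr_attenuated)
  expect_true(res$degenerate)
})

test_that("dynamics curves report mean and 2 SEM on the cue-locked grid", {
  spec <- paradigm_spec()
  tl <- build_timeline(spec)
  n_ep <- session_length(spec) * 10
  zc <- structure(list(z = matrix(2, nrow = n_ep, ncol = 2), epoch_s = 0.1,
                       epoch_start_s = (seq_len(n_ep) - 1) * 0.1,
                       channel_names = c("a", "b"),
                       excluded_channels = integer(0)),
                  class = "zscored_hga")
  dyn <- temporal_dynamics(zc, tl, "trial")
  expect_equal(unique(dyn$curve), c("trial1", "trial9"))
  expect_equal(dyn$time_s[dyn$curve == "trial1"], seq(-0.2, 1.1, by = 0.1))
  expect_true(all(dyn$mean == 2))
  expect_true(all(dyn$sem2 == 0))
  expect_true(all(dyn$n == 20))  # 2 channels x 10 blocks
  nr <- temporal_dynamics(zc, tl, "nr")
  expect_true(all(nr$n == 60))   # 2 channels x 10 blocks x 3 trials
  blk <- temporal_dynamics(zc, tl, "block")
  expect_true(all(blk$n == 20))  # 2 channels x 10 trials
})

test_that("planted short-term attenuation separates the NR1 and NR3 curves", {
  pre <- quick_cohort(n_channels = 4, responsive = 1:2, seed = 21,
                      burst_gain = 0.5,
                      short_term_profile = c(1, 1, 1, 0.8, 0.7, 0.6, 0.5, 0.5, 0.5, 0.5),
                      long_term_profile = rep(1, 10))
  dyn <- temporal_dynamics(pre$z, pre$timeline, "nr", channels = 1:2)
  win <- dyn$time_s >= 0.4 & dyn$time_s <= 0.9
  nr1 <- dyn[dyn$curve == "NR1" & win, ]
  nr3 <- dyn[dyn$curve == "NR3" & win, ]
  expect_true(all(nr3$mean < nr1$mean))
})

test_that("baseline drift is caught by the rest-epoch Mann-Whitney test", {
  gains <- c(1, 1, 1, 1, 1, 1, 1.6, 1.6, 1.6, 1.6)
  p_drift <- p_null <- numeric(3)
  for (i in 1:3) {
    drift <- quick_cohort(n_channels = 2, responsive = integer(0),
                          seed = 40 + i, block_background_gain = gains)
    p_drift[i] <- baseline_drift_test(drift$z, drift$timeline)$p
  }
  expect_true(all(p_drift < 0.05))
  flat <- quick_cohort(n_channels = 2, responsive = integer(0), seed = 50)
  bd <- baseline_drift_test(flat$z, flat$timeline)
  expect_gt(bd$p, 0.001)  # no planted drift: no overwhelming evidence
  expect_equal(bd$n_early, bd$n_late)
  expect_equal(bd$n_early, 2 * 3 * 120)  # 2 channels x 3 blocks x 120 epochs
  # identical pools give p = 1
  same <- baseline_drift_test(flat$z, flat$timeline, early_blocks = 2:3,
                              late_blocks = 2:3)
  expect_equal(same$p, 1)
  expect_error(baseline_drift_test(flat$z, flat$timeline,
                                   early_blocks = 99), "empty")
})
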