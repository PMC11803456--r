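# Signal-chain checks against analytic filter responses and hand-computed
# epoch arithmetic.

sine_rec <- function(freq, fs = 1200, dur = 10, amp = 1) {
  t <- seq_len(fs * dur) / fs
  continuous_recording(cbind(amp * sin(2 * pi * freq * t),
                             amp * cos(2 * pi * freq * t)), fs)
}

steady_rms <- function(rec, ch = 1) {
  n <- nrow(rec$data)
  i <- seq(floor(n * 0.3), floor(n * 0.7))
  sqrt(mean(rec$data[i, ch]^2))
}

test_that("drift filter removes DC and slow drift, passes 100 Hz", {
  fs <- 1200
  const <- continuous_recording(matrix(5, nrow = fs * 5, ncol = 2), fs)
  out <- remove_drift(const)
  expect_lt(max(abs(out$data[(4 * fs):(5 * fs), ])), 5 * 1e-6)  # past transient
  slow <- sine_rec(0.2, dur = 30)
  expect_lt(steady_rms(remove_drift(slow)) / steady_rms(slow), 0.05)
  fast <- sine_rec(100)
  ratio <- steady_rms(remove_drift(fast)) / steady_rms(fast)
  expect_equal(ratio, oracle_butter_mag(100, fs, 2, 4, "high"),
               tolerance = 1e-3)
  expect_lt(abs(ratio - 1), 0.01)
  expect_error(remove_drift(continuous_recording(matrix(c(1, NA), 2, 1),
                                                 1200)), "non-finite")
})

test_that("band-pass cascade matches the analytic Butterworth magnitudes", {
  fs <- 1200
  cascade <- function(f, passes = 1)
    oracle_butter_mag(f, fs, 60, 4, "high", passes) *
    oracle_butter_mag(f, fs, 170, 4, "low", passes)
  inband <- sine_rec(100)
  r100 <- steady_rms(bandpass_hga(inband)) / steady_rms(inband)
  expect_equal(r100, cascade(100), tolerance = 1e-3)
  expect_lt(abs(r100 - 1), 0.02)
  low <- sine_rec(10, dur = 20)
  r10 <- steady_rms(bandpass_hga(low)) / steady_rms(low)
  expect_lt(20 * log10(r10), -40)
  high <- sine_rec(300)
  r300 <- steady_rms(bandpass_hga(high)) / steady_rms(high)
  expect_lt(20 * log10(r300), -15)
  # zero-phase option doubles the attenuation in dB
  r100_zp <- steady_rms(bandpass_hga(inband, zero_phase = TRUE)) /
    steady_rms(inband)
  expect_equal(r100_zp, cascade(100, passes = 2), tolerance = 1e-3)
  expect_error(bandpass_hga(sine_rec(10), band = c(60, 700)), "Nyquist")
})

test_that("common average reference zeroes the included-channel mean", {
  fs <- 1200
  set.seed(2)
  m <- matrix(rnorm(fs * 4), ncol = 4)
  rec <- continuous_recording(m, fs, excluded_channels = 4L)
  out <- common_average_reference(rec)
  expect_lt(max(abs(rowMeans(out$data[, 1:3]))), 1e-12)
  expect_identical(out$data[, 4], m[, 4])  # excluded passed through
  # two-channel algebra
  two <- common_average_reference(continuous_recording(m[, 1:2], fs))
  expect_equal(two$data[, 1], (m[, 1] - m[, 2]) / 2)
  expect_equal(two$data[, 2], (m[, 2] - m[, 1]) / 2)
  # identical channels cancel
  same <- common_average_reference(continuous_recording(m[, c(1, 1)], fs))
  expect_lt(max(abs(same$data)), 1e-12)
  expect_error(common_average_reference(
    continuous_recording(m, fs, excluded_channels = 2:4)), ">= 2")
})

test_that("Hilbert envelope recovers tone amplitude and downsampling averages", {
  fs <- 1200
  rec <- sine_rec(100, amp = 2.5)
  env <- envelope_downsample(rec)
  expect_equal(env$fs, 400)
  n <- nrow(env$data)
  mid <- seq(floor(n * 0.1), floor(n * 0.9))
  expect_true(all(abs(env$data[mid, 1] - 2.5) / 2.5 < 0.03))
  expect_equal(n, floor(nrow(rec$data) / (fs / 400)))
  zero <- envelope_downsample(continuous_recording(matrix(0, 2400, 1), fs))
  expect_true(all(zero$data == 0))
  expect_error(envelope_downsample(
    continuous_recording(matrix(1, 10, 1), 1200), target_fs = 700),
    "divisible")
})

test_that("epoch log band-power follows the 40-sample mean-square rule", {
  mk_env <- function(v) structure(list(data = cbind(v), fs = 400,
                                       channel_names = "e1",
                                       excluded_channels = integer(0)),
                                  class = "hga_envelope")
  pw <- epoch_log_bandpower(mk_env(rep(3, 400)))
  expect_equal(as.numeric(pw$log_power), rep(log(9), 10))
  # alternating 0.5-s amplitude 1 / 2 -> runs of five ln(1), ln(4) epochs
  alt <- rep(rep(c(1, 2), each = 200), 5)
  pw <- epoch_log_bandpower(mk_env(alt))
  expect_equal(as.numeric(pw$log_power),
               rep(rep(c(log(1), log(4)), each = 5), 5))
  # a 250-s envelope yields 2500 epochs; trailing partials are dropped
  expect_equal(nrow(epoch_log_bandpower(mk_env(rep(1, 250 * 400)))$log_power),
               2500)
  expect_equal(nrow(epoch_log_bandpower(mk_env(rep(1, 119)))$log_power), 2)
  expect_error(epoch_log_bandpower(mk_env(c(rep(1, 40), rep(0, 40)))),
               "zero power")
})

mk_power <- function(vals) {
  structure(list(log_power = cbind(vals), epoch_s = 0.1,
                 epoch_start_s = (seq_along(vals) - 1) * 0.1,
                 channel_names = "e1", excluded_channels = integer(0)),
            class = "envelope_power")
}
mk_tl <- function(df) structure(df, class = c("hga_timeline", "data.frame"))

test_that("rest z-scoring uses the sample SD of rest epochs only", {
  tl <- mk_tl(data.frame(onset_s = 0, duration_s = 0.2, label = "rest",
                         block = 1L, trial = NA_integer_))
  z <- zscore_to_rest(mk_power(c(1, 3, 4)), tl)
  expect_equal(as.numeric(z$z), c((1 - 2) / sqrt(2), (3 - 2) / sqrt(2),
                                  (4 - 2) / sqrt(2)))
  expect_equal(as.numeric(z$z[3, 1]), 1.41421, tolerance = 1e-5)
  expect_equal(unname(z$baseline_mean), 2)
  expect_equal(unname(z$baseline_sd), sqrt(2))
  expect_error(zscore_to_rest(mk_power(c(1, 1, 4)), tl), "zero rest variance")
  # pre-rest epochs are not part of the baseline
  tl2 <- mk_tl(data.frame(onset_s = c(0, 0.2), duration_s = c(0.2, 0.2),
                          label = c("pre_rest", "rest"),
                          block = c(NA, 1L), trial = NA_integer_))
  z2 <- zscore_to_rest(mk_power(c(100, 200, 1, 3)), tl2)
  expect_equal(unname(z2$baseline_mean), 2)
})

test_that("trial extraction picks exactly the six window epochs", {
  spec <- small_spec()
  tl <- build_timeline(spec)
  n_ep <- session_length(spec) * 10
  zmat <- matrix(0, nrow = n_ep, ncol = 2)
  cue <- cue_events(tl)[1, ]  # block 1, trial 1
  win <- evaluation_window(cue$onset_s)
  zmat[win + 1, 1] <- 1
  z <- structure(list(z = zmat, epoch_s = 0.1,
                      epoch_start_s = (seq_len(n_ep) - 1) * 0.1,
                      channel_names = c("e1", "e2"),
                      excluded_channels = integer(0)),
                 class = "zscored_hga")
  trials <- extract_trial_samples(z, tl)
  expect_equal(dim(trials$hga), c(2, 2, 3))
  expect_equal(unname(trials$hga[1, 1, 1]), 1)
  expect_equal(sum(trials$hga), 1)
  expect_equal(dim(trials$epochs)[4], 6)
})

test_that("scaling the raw signal shifts log-power by 2 ln k and leaves z fixed", {
  spec <- small_spec()
  tl <- build_timeline(spec)
  set.seed(4)
  n <- session_length(spec) * 1200
  m <- matrix(rnorm(3 * n), ncol = 3)
  rec1 <- continuous_recording(m, 1200)
  rec2 <- continuous_recording(3 * m, 1200)
  chain <- function(rec) {
    r <- bandpass_hga(common_average_reference(remove_drift(rec)))
    epoch_log_bandpower(envelope_downsample(r))
  }
  p1 <- chain(rec1); p2 <- chain(rec2)
  expect_equal(p2$log_power, p1$log_power + 2 * log(3), tolerance = 1e-9)
  z1 <- zscore_to_rest(p1, tl); z2 <- zscore_to_rest(p2, tl)
  expect_equal(z2$z, z1$z, tolerance = 1e-7)
})

test_that("rest epochs standardize to mean 0, sample SD 1 per channel", {
  pre <- quick_cohort(n_channels = 3, responsive = 1, seed = 9)
  z <- pre$z
  rest <- z$z[z$rest_epochs + 1, , drop = FALSE]
  expect_lt(max(abs(colMeans(rest))), 1e-9)
  expect_lt(max(abs(apply(rest, 2, sd) - 1)), 1e-9)
  expect_equal(length(z$rest_epochs), 10 * 120)
})
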