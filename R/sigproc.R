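#' Continuous multichannel recording container
#'
#' @param data Numeric matrix, samples in rows, channels in columns
#'   (microvolts).
#' @param fs Sampling rate in Hz; must be at least 1200 and divisible by 400
#'   so that the envelope can be reduced to 400 Hz by exact block averaging.
#' @param channel_names Character vector, one per column.
#' @param excluded_channels Integer indices of ground/bad channels; these
#'   never enter the common average or any statistic.
#' @return Object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_names = NULL,
                                 excluded_channels = integer(0)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric", call. = FALSE)
  check_fs(fs)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(ncol(data)))
  if (length(channel_names) != ncol(data))
    stop("channel_names length must match channel count", call. = FALSE)
  excluded_channels <- as.integer(excluded_channels)
  if (any(excluded_channels < 1L | excluded_channels > ncol(data)))
    stop("excluded_channels out of range", call. = FALSE)
  colnames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 excluded_channels = excluded_channels),
            class = "continuous_recording")
}

check_fs <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs < 1200 || fs %% 400 != 0)
    stop("sampling rate must be >= 1200 Hz and divisible by 400 (got ",
         fs, ")", call. = FALSE)
  invisible(fs)
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  if (length(x$excluded_channels))
    cat("  excluded:", paste(x$channel_names[x$excluded_channels],
                             collapse = ", "), "\n")
  invisible(x)
}

# Apply an IIR filter to every channel. Causal by default (single pass,
# matching a real-time acquisition chain); zero_phase = TRUE runs
# forward-backward, doubling the magnitude response in dB.
apply_filter <- function(rec, filt, zero_phase = FALSE) {
  fun <- if (zero_phase) {
    function(x) signal::filtfilt(filt$b, filt$a, x)
  } else {
    function(x) as.numeric(signal::filter(filt$b, filt$a, x))
  }
  rec$data <- apply(rec$data, 2L, fun)
  rec
}

#' Drift-removal high-pass filter
#'
#' 2 Hz high-pass, fourth-order Butterworth, removing DC offset and slow
#' drift before referencing.
#'
#' @param rec A [continuous_recording()].
#' @param cutoff_hz High-pass cutoff (Hz).
#' @param order Butterworth order.
#' @param zero_phase Apply forward-backward (zero-phase) instead of a single
#'   causal pass. Default `FALSE`; the cascade's group delay (a few ms) is
#'   negligible at the 100-ms epoch resolution.
#' @return Filtered `continuous_recording` of identical shape.
#' @export
remove_drift <- function(rec, cutoff_hz = 2, order = 4, zero_phase = FALSE) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (!all(is.finite(rec$data)))
    stop("remove_drift: recording contains non-finite samples", call. = FALSE)
  filt <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  apply_filter(rec, filt, zero_phase)
}

#' Common average reference
#'
#' Subtracts, per sample, the mean over all included channels from every
#' included channel. Channels listed in `excluded_channels` (ground/bad) are
#' passed through untouched and do not contribute to the average.
#'
#' @param rec A [continuous_recording()] with at least two included channels.
#' @return Re-referenced `continuous_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "continuous_recording"))
  incl <- setdiff(seq_len(ncol(rec$data)), rec$excluded_channels)
  if (length(incl) < 2L)
    stop("common_average_reference: need >= 2 included channels", call. = FALSE)
  avg <- rowMeans(rec$data[, incl, drop = FALSE])
  rec$data[, incl] <- rec$data[, incl, drop = FALSE] - avg
  rec
}

#' High-gamma band-pass filter
#'
#' Cascade of a fourth-order Butterworth high-pass at 60 Hz and a
#' fourth-order Butterworth low-pass at 170 Hz, isolating the high-gamma
#' band.
#'
#' @inheritParams remove_drift
#' @param band Two-element band edges (Hz); both must be below Nyquist.
#' @return Band-limited `continuous_recording`.
#' @export
bandpass_hga <- function(rec, band = c(60, 170), order = 4, zero_phase = FALSE) {
  stopifnot(inherits(rec, "continuous_recording"), length(band) == 2L)
  if (max(band) >= rec$fs / 2)
    stop("bandpass_hga: cutoff at or above Nyquist (fs = ", rec$fs, ")",
         call. = FALSE)
  hp <- signal::butter(order, band[1] / (rec$fs / 2), type = "high")
  lp <- signal::butter(order, band[2] / (rec$fs / 2), type = "low")
  apply_filter(apply_filter(rec, hp, zero_phase), lp, zero_phase)
}

# Analytic-signal magnitude via the FFT half-spectrum method.
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Hilbert envelope, reduced to 400 Hz
#'
#' Computes the magnitude of the analytic signal per channel at the native
#' rate, then averages consecutive non-overlapping groups of `fs / 400`
#' samples (block averaging doubles as the anti-alias step for the
#' nonnegative envelope). Any trailing partial group is dropped.
#'
#' @param rec A band-limited [continuous_recording()].
#' @param target_fs Output rate; native `fs` must be divisible by it.
#' @return Object of class `hga_envelope`: list with `data` (samples x
#'   channels at `target_fs`), `fs`, `channel_names`, `excluded_channels`.
#' @export
envelope_downsample <- function(rec, target_fs = 400) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (rec$fs %% target_fs != 0)
    stop("envelope_downsample: fs (", rec$fs, ") not divisible by ",
         target_fs, call. = FALSE)
  dec <- rec$fs / target_fs
  env <- apply(rec$data, 2L, hilbert_envelope)
  n_out <- floor(nrow(env) / dec)
  env <- env[seq_len(n_out * dec), , drop = FALSE]
  # column-wise mean of each consecutive group of `dec` samples
  down <- sapply(seq_len(ncol(env)), function(j)
    colMeans(matrix(env[, j], nrow = dec)))
  down <- matrix(down, ncol = ncol(env),
                 dimnames = list(NULL, rec$channel_names))
  structure(list(data = down, fs = target_fs,
                 channel_names = rec$channel_names,
                 excluded_channels = rec$excluded_channels),
            class = "hga_envelope")
}

#' Log band-power in 100-ms epochs
#'
#' Per epoch and channel, power is the mean squared envelope over the
#' `epoch_s * fs` samples of the epoch; the natural log is applied to
#' approximate a Gaussian distribution. Epochs are contiguous,
#' non-overlapping, aligned to the time origin; a trailing partial epoch is
#' dropped. Epoch indexing is 0-based half-open: epoch `i` covers
#' `[i * epoch_s, (i + 1) * epoch_s)`.
#'
#' @param env An `hga_envelope` (400 Hz).
#' @param epoch_s Epoch length, default 0.1 s.
#' @return Object of class `envelope_power`: `log_power` (epochs x
#'   channels), `epoch_s`, `epoch_start_s`, channel metadata.
#' @export
epoch_log_bandpower <- function(env, epoch_s = 0.1) {
  stopifnot(inherits(env, "hga_envelope"))
  spe <- epoch_s * env$fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_s must be a whole number of envelope samples", call. = FALSE)
  spe <- as.integer(round(spe))
  n_ep <- floor(nrow(env$data) / spe)
  pw <- sapply(seq_len(ncol(env$data)), function(j)
    colMeans(matrix(env$data[seq_len(n_ep * spe), j]^2, nrow = spe)))
  pw <- matrix(pw, ncol = ncol(env$data),
               dimnames = list(NULL, env$channel_names))
  if (any(pw <= 0)) {
    bad <- which(pw <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "epoch_log_bandpower: zero power in channel '%s', epoch %d (log undefined)",
      env$channel_names[bad["col"]], bad["row"] - 1L), call. = FALSE)
  }
  structure(list(log_power = log(pw), epoch_s = epoch_s,
                 epoch_start_s = (seq_len(n_ep) - 1L) * epoch_s,
                 channel_names = env$channel_names,
                 excluded_channels = env$excluded_channels),
            class = "envelope_power")
}

# 0-based epoch indices fully inside the 12-s rest phases (pre-rest excluded)
rest_epoch_index <- function(power, timeline) {
  rests <- timeline[timeline$label == "rest", , drop = FALSE]
  if (nrow(rests) == 0L) stop("timeline contains no rest phases", call. = FALSE)
  idx <- unlist(lapply(seq_len(nrow(rests)), function(i) {
    first <- ceiling(rests$onset_s[i] / power$epoch_s - 1e-9)
    last <- floor((rests$onset_s[i] + rests$duration_s[i]) / power$epoch_s + 1e-9) - 1
    seq(first, last)
  }))
  idx <- idx[idx >= 0 & idx < nrow(power$log_power)]
  as.integer(idx)
}

#' Standardize log band-power to rest z-scores
#'
#' Per channel, the mean and sample standard deviation (n - 1 denominator)
#' are computed from all epochs fully inside the ten 12-s rest phases
#' (the pre-session rest is excluded), and every epoch is standardized:
#' `z = (log_power - mean) / sd`. By construction the pooled rest epochs of
#' each channel then have mean 0 and sample SD 1.
#'
#' @param power An [epoch_log_bandpower()] result.
#' @param timeline An `hga_timeline` covering the recording.
#' @return Object of class `zscored_hga`: `z` (epochs x channels),
#'   `baseline_mean`, `baseline_sd` (per channel), `rest_epochs` (0-based
#'   indices used as baseline), plus epoch/channel metadata.
#' @export
zscore_to_rest <- function(power, timeline) {
  stopifnot(inherits(power, "envelope_power"))
  ridx <- rest_epoch_index(power, timeline)
  if (length(ridx) < 2L)
    stop("zscore_to_rest: need >= 2 rest epochs", call. = FALSE)
  base <- power$log_power[ridx + 1L, , drop = FALSE]
  mu <- colMeans(base)
  sd_ <- apply(base, 2L, stats::sd)
  if (any(sd_ <= 0))
    stop("zscore_to_rest: zero rest variance in channel(s) ",
         paste(power$channel_names[sd_ <= 0], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(power$log_power, 2L, mu), 2L, sd_, `/`)
  structure(list(z = z, baseline_mean = mu, baseline_sd = sd_,
                 rest_epochs = ridx, epoch_s = power$epoch_s,
                 epoch_start_s = power$epoch_start_s,
                 channel_names = power$channel_names,
                 excluded_channels = power$excluded_channels),
            class = "zscored_hga")
}

#' Trial-sample container
#'
#' Holds one window-mean high-gamma score per (channel, block, trial).
#' Normally produced by [extract_trial_samples()]; the constructor is also
#' useful for concatenating multiple runs of one patient (each run z-scored
#' against its own rest phases) along the block axis, or for feeding
#' sample-level simulations to the attenuation stage.
#'
#' @param hga Numeric array, channels x blocks x trials.
#' @param epochs Optional channels x blocks x trials x window-epochs array
#'   of per-epoch z-values.
#' @param window Evaluation window (s, cue-relative) the samples came from.
#' @param channel_names Channel names; defaults to the array dimnames.
#' @param excluded_channels Indices excluded from statistics.
#' @return Object of class `trial_samples`.
#' @export
trial_samples <- function(hga, epochs = NULL, window = c(0.4, 1.0),
                          channel_names = NULL,
                          excluded_channels = integer(0)) {
  hga <- as.array(hga)
  if (length(dim(hga)) != 3L)
    stop("hga must be a channels x blocks x trials array", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- dimnames(hga)[[1]] %||% sprintf("ch%02d", seq_len(dim(hga)[1]))
  structure(list(hga = hga, epochs = epochs, window = window,
                 blocks = seq_len(dim(hga)[2]), trials = seq_len(dim(hga)[3]),
                 channel_names = channel_names,
                 excluded_channels = as.integer(excluded_channels)),
            class = "trial_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-trial evaluation-window samples
#'
#' One high-gamma score per (channel, block, trial): the mean z over the six
#' 100-ms epochs of the 0.4-1.0 s window after the close cue. The per-epoch
#' z-values inside each window are retained for temporal-dynamics analyses.
#'
#' @param z A [zscore_to_rest()] result.
#' @param timeline An `hga_timeline` with close-cue events.
#' @param window Scoring window in seconds relative to the cue.
#' @return Object of class `trial_samples`: `hga` (channels x blocks x
#'   trials array of window means), `epochs` (channels x blocks x trials x
#'   window-epochs array), `window`, channel metadata.
#' @export
extract_trial_samples <- function(z, timeline, window = c(0.4, 1.0)) {
  stopifnot(inherits(z, "zscored_hga"))
  cues <- cue_events(timeline)
  blocks <- sort(unique(cues$block))
  trials <- sort(unique(cues$trial))
  n_ch <- ncol(z$z)
  n_ep <- as.integer(round(diff(window) / z$epoch_s))
  hga <- array(NA_real_, dim = c(n_ch, length(blocks), length(trials)),
               dimnames = list(z$channel_names, NULL, NULL))
  eps <- array(NA_real_, dim = c(n_ch, length(blocks), length(trials), n_ep))
  for (i in seq_len(nrow(cues))) {
    idx <- evaluation_window(cues$onset_s[i], window = window,
                             epoch_s = z$epoch_s, n_epochs = nrow(z$z))
    b <- match(cues$block[i], blocks)
    tr <- match(cues$trial[i], trials)
    w <- t(z$z[idx + 1L, , drop = FALSE])     # channels x epochs
    eps[, b, tr, ] <- w
    hga[, b, tr] <- rowMeans(w)
  }
  structure(list(hga = hga, epochs = eps, window = window,
                 blocks = blocks, trials = trials,
                 channel_names = z$channel_names,
                 excluded_channels = z$excluded_channels),
            class = "trial_samples")
}

#' Full preprocessing chain
#'
#' Convenience wrapper running the fixed stage order: drift removal, common
#' average reference, 60-170 Hz band-pass, Hilbert envelope at 400 Hz,
#' 100-ms log band-power epochs, rest z-scoring, and per-trial window
#' extraction.
#'
#' @param rec A [continuous_recording()].
#' @param timeline An `hga_timeline`.
#' @param zero_phase Passed to the filtering stages.
#' @param window Trial scoring window (s, cue-relative).
#' @return List with elements `z` ([zscore_to_rest()] output) and `trials`
#'   ([extract_trial_samples()] output).
#' @export
hga_preprocess <- function(rec, timeline, zero_phase = FALSE,
                           window = c(0.4, 1.0)) {
  rec <- remove_drift(rec, zero_phase = zero_phase)
  rec <- common_average_reference(rec)
  rec <- bandpass_hga(rec, zero_phase = zero_phase)
  env <- envelope_downsample(rec)
  pw <- epoch_log_bandpower(env)
  z <- zscore_to_rest(pw, timeline)
  list(z = z, trials = extract_trial_samples(z, timeline, window = window))
}
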