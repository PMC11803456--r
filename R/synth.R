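# Paradigm-locked synthetic ECoG: 1/f background plus cue-locked band-limited
# (60-170 Hz) bursts on responsive channels, with planted per-trial (short
# term) and per-block (long term) amplitude attenuation profiles.

#' Default planted attenuation profiles
#'
#' Per-trial multipliers `s` (short term) and per-block multipliers `l`
#' (long term) applied to the burst amplitude of trial t in block b as
#' `burst_gain * s[t] * l[b]`. The default shape mirrors the phenomenology
#' of sensorimotor repetition suppression: `s` decays from the first to the
#' fifth trial, rebounds over trials 6-8, and dips again at trials 9-10;
#' `l` drops after the first block and then plateaus. `s[1]` and `l[1]` are
#' the respective maxima.
#'
#' @param attenuation If `FALSE`, both profiles are all ones (no planted
#'   attenuation).
#' @return List with numeric vectors `s` and `l`, each of length 10.
#' @export
default_profiles <- function(attenuation = TRUE) {
  if (!attenuation) return(list(s = rep(1, 10), l = rep(1, 10)))
  list(s = c(1.00, 0.80, 0.70, 0.65, 0.62, 0.66, 0.70, 0.72, 0.66, 0.58),
       l = c(1.00, 0.80, 0.78, 0.77, 0.76, 0.75, 0.75, 0.74, 0.74, 0.73))
}

#' Synthetic recording configuration
#'
#' @param fs Sampling rate (Hz), >= 1200 and divisible by 400.
#' @param n_channels Number of channels.
#' @param responsive_channels Integer indices of channels that receive
#'   cue-locked high-gamma bursts.
#' @param burst_gain Burst amplitude relative to the unit-variance
#'   background (per-trial amplitude is `burst_gain * s[t] * l[b]`). The
#'   default is calibrated so that the full pipeline's grand-average
#'   first-trial z-curve peaks near 1.25 at 0.7 s.
#' @param short_term_profile,long_term_profile Per-trial / per-block
#'   amplitude multipliers (length = trials per block / blocks); see
#'   [default_profiles()].
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param shared_noise_fraction Amplitude fraction (0-1) of a single shared
#'   background component mixed into every channel.
#' @param line_noise_hz Optional mains frequency; `NULL` disables.
#' @param line_noise_amp Amplitude of the mains sinusoid.
#' @param block_background_gain Optional per-block amplitude multiplier of
#'   the background (models baseline drift across blocks); default all ones.
#' @param burst_onset_s,burst_peak_s Landmarks of the burst envelope: the
#'   Gaussian bump peaks at `burst_peak_s` post-cue and first exceeds 5% of
#'   its peak at `burst_onset_s`.
#' @param burst_width_s Optional explicit Gaussian SD of the envelope;
#'   derived from the onset/peak landmarks when `NULL`.
#' @param attenuation_margin Relative amplitude drop (late vs early thirds
#'   of a profile) above which a channel counts as planted-attenuated in the
#'   ground truth.
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @param electrode_layout Electrode table (see [electrode_table()]);
#'   defaults to a deterministic grid around the hand-knob reference.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 1200, n_channels = 8,
                             responsive_channels = seq_len(max(1L, n_channels %/% 2L)),
                             burst_gain = 0.222,
                             short_term_profile = default_profiles()$s,
                             long_term_profile = default_profiles()$l,
                             noise_exponent = 1,
                             shared_noise_fraction = 0.2,
                             line_noise_hz = NULL, line_noise_amp = 0.5,
                             block_background_gain = NULL,
                             burst_onset_s = 0.3, burst_peak_s = 0.7,
                             burst_width_s = NULL,
                             attenuation_margin = 0.2,
                             seed = 1,
                             electrode_layout = NULL) {
  check_fs(fs)
  stopifnot(n_channels >= 1, burst_gain >= 0,
            shared_noise_fraction >= 0, shared_noise_fraction <= 1,
            all(short_term_profile > 0), all(long_term_profile > 0),
            burst_peak_s > burst_onset_s, attenuation_margin >= 0)
  responsive_channels <- as.integer(responsive_channels)
  if (length(responsive_channels) &&
      any(responsive_channels < 1L | responsive_channels > n_channels))
    stop("responsive_channels out of range", call. = FALSE)
  if (is.null(burst_width_s))
    burst_width_s <- (burst_peak_s - burst_onset_s) / sqrt(-2 * log(0.05))
  if (is.null(electrode_layout))
    electrode_layout <- default_electrode_layout(n_channels,
                                                 responsive_channels)
  structure(list(fs = fs, n_channels = n_channels,
                 responsive_channels = responsive_channels,
                 burst_gain = burst_gain,
                 short_term_profile = short_term_profile,
                 long_term_profile = long_term_profile,
                 noise_exponent = noise_exponent,
                 shared_noise_fraction = shared_noise_fraction,
                 line_noise_hz = line_noise_hz,
                 line_noise_amp = line_noise_amp,
                 block_background_gain = block_background_gain,
                 burst_onset_s = burst_onset_s, burst_peak_s = burst_peak_s,
                 burst_width_s = burst_width_s,
                 attenuation_margin = attenuation_margin,
                 seed = as.integer(seed),
                 electrode_layout = electrode_layout),
            class = "synthetic_config")
}

#' Deterministic default electrode layout
#'
#' Places channels on a 10-mm grid on the left hemisphere around the
#' hand-knob reference point. Responsive channels alternate between PreCG
#' and PostCG labels; the remaining channels cycle through PreCG, PostCG
#' and "other".
#'
#' @param n_channels Channel count.
#' @param responsive_channels Indices labeled as sensorimotor.
#' @param sigma Hand-knob reference point (MNI mm, RAS).
#' @return An [electrode_table()] data frame.
#' @export
default_electrode_layout <- function(n_channels,
                                     responsive_channels = integer(0),
                                     sigma = c(-36, -22, 54)) {
  n_col <- max(1L, ceiling(sqrt(n_channels)))
  row_i <- (seq_len(n_channels) - 1L) %/% n_col
  col_i <- (seq_len(n_channels) - 1L) %% n_col
  region <- rep(c("PreCG", "PostCG", "other"),
                length.out = n_channels)
  region[responsive_channels] <-
    rep(c("PreCG", "PostCG"), length.out = length(responsive_channels))
  electrode_table(name = sprintf("ch%02d", seq_len(n_channels)),
                  x = rep(sigma[1], n_channels),
                  y = sigma[2] + 10 * (col_i - (n_col - 1) / 2),
                  z = sigma[3] + 10 * (row_i - (max(row_i)) / 2),
                  region = region,
                  ground = rep(FALSE, n_channels))
}

# Unit-variance 1/f^(alpha) noise by spectral shaping of white Gaussian
# noise (PSD ~ 1/f^alpha; amplitude shaping with f^(-alpha/2), DC removed).
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  if (alpha == 0) return((w - mean(w)) / stats::sd(w))
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f) # two-sided frequency magnitude
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

# Unit-variance band-limited noise: white Gaussian noise shaped in the
# frequency domain by a flat 60-170 Hz mask with smooth half-cosine edges
# (+-edge_hz), keeping essentially all power inside the band.
band_noise <- function(n, fs, band = c(60, 170), edge_hz = 4) {
  w <- stats::rnorm(n)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)
  mask <- numeric(n)
  inside <- f >= band[1] & f <= band[2]
  mask[inside] <- 1
  lo <- f >= band[1] - edge_hz & f < band[1]
  mask[lo] <- 0.5 * (1 + cos(pi * (band[1] - f[lo]) / edge_hz))
  hi <- f > band[2] & f <= band[2] + edge_hz
  mask[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / edge_hz))
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

#' Generate continuous multichannel background
#'
#' Each channel is `(1 - f_sh) * independent + f_sh * shared`, where both
#' components are unit-variance 1/f^alpha noise (so
#' `shared_noise_fraction = 1` makes all channels identical), plus an
#' optional mains sinusoid. Reproducible under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param duration_s Duration in seconds.
#' @return A [continuous_recording()].
#' @export
generate_background <- function(config, duration_s) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("generate_background: duration must be positive", call. = FALSE)
  set.seed(config$seed)
  n <- as.integer(round(duration_s * config$fs))
  f_sh <- config$shared_noise_fraction
  shared <- pink_noise(n, config$noise_exponent)
  data <- matrix(0, nrow = n, ncol = config$n_channels)
  for (ch in seq_len(config$n_channels))
    data[, ch] <- (1 - f_sh) * pink_noise(n, config$noise_exponent) +
      f_sh * shared
  if (!is.null(config$line_noise_hz)) {
    tt <- seq_len(n) / config$fs
    data <- data + config$line_noise_amp *
      sin(2 * pi * config$line_noise_hz * tt)
  }
  continuous_recording(data, config$fs,
                       channel_names = config$electrode_layout$name,
                       excluded_channels = which(config$electrode_layout$ground))
}

# smooth unimodal burst envelope: Gaussian bump peaking at burst_peak_s
burst_envelope <- function(config, trial_len_s) {
  tt <- seq(0, trial_len_s, by = 1 / config$fs)
  tt <- tt[-length(tt)]
  exp(-(tt - config$burst_peak_s)^2 / (2 * config$burst_width_s^2))
}

#' Ground truth implied by a configuration
#'
#' Flags are derived deterministically from the planted profiles: a channel
#' is short-term attenuated iff it is responsive and the mean of `s` over
#' trials 7-9 falls below the mean over trials 1-3 by at least the
#' configured relative margin; long-term attenuation is the analogue over
#' blocks 1-3 vs 7-9 of `l`.
#'
#' @param config A [synthetic_config()].
#' @return List with per-channel logical vectors `responsive`,
#'   `short_term_attenuated`, `long_term_attenuated`, the planted profiles,
#'   and the margin used.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  resp <- seq_len(config$n_channels) %in% config$responsive_channels
  rel_drop <- function(p) {
    early <- mean(p[1:3]); late <- mean(p[7:9])
    (early - late) / early
  }
  st <- resp & rel_drop(config$short_term_profile) >= config$attenuation_margin
  lt <- resp & rel_drop(config$long_term_profile) >= config$attenuation_margin
  list(responsive = resp, short_term_attenuated = st,
       long_term_attenuated = lt,
       short_term_profile = config$short_term_profile,
       long_term_profile = config$long_term_profile,
       attenuation_margin = config$attenuation_margin)
}

#' Generate a paradigm-locked synthetic recording
#'
#' Produces background noise for the whole session and, on responsive
#' channels, adds one band-limited (60-170 Hz) burst per close cue, shaped
#' by a smooth unimodal envelope (5%-onset at `burst_onset_s`, peak at
#' `burst_peak_s` post-cue) with amplitude
#' `burst_gain * s[trial] * l[block]`. Non-responsive channels carry
#' background only. Byte-identical output for identical (config, spec).
#'
#' @param config A [synthetic_config()].
#' @param spec A [paradigm_spec()]; profile lengths must match its trial
#'   and block counts.
#' @return List with `recording` ([continuous_recording()]), `timeline`
#'   ([build_timeline()]), `truth` ([ground_truth()]) and `electrodes`.
#' @export
generate_recording <- function(config, spec = paradigm_spec()) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(spec, "paradigm_spec"))
  if (length(config$short_term_profile) != spec$trials_per_block)
    stop("short_term_profile length must equal trials_per_block", call. = FALSE)
  if (length(config$long_term_profile) != spec$n_blocks)
    stop("long_term_profile length must equal n_blocks", call. = FALSE)
  bg_gain <- config$block_background_gain
  if (!is.null(bg_gain) && length(bg_gain) != spec$n_blocks)
    stop("block_background_gain length must equal n_blocks", call. = FALSE)
  timeline <- build_timeline(spec)
  dur <- session_length(spec)
  rec <- generate_background(config, dur) # seeds the RNG
  n <- nrow(rec$data)
  if (!is.null(bg_gain)) {
    blk <- timeline[timeline$label %in% c("rest", "close_cue"), ]
    for (b in seq_len(spec$n_blocks)) {
      rows <- blk[blk$block == b, ]
      i0 <- as.integer(round(min(rows$onset_s) * config$fs)) + 1L
      i1 <- if (b < spec$n_blocks)
        as.integer(round(min(blk$onset_s[blk$block == b + 1]) * config$fs))
      else n
      rec$data[i0:i1, ] <- rec$data[i0:i1, , drop = FALSE] * bg_gain[b]
    }
  }
  env <- burst_envelope(config, spec$close_s + spec$open_s)
  cues <- cue_events(timeline)
  for (ch in config$responsive_channels) {
    carrier <- band_noise(n, config$fs)
    add <- numeric(n)
    for (i in seq_len(nrow(cues))) {
      amp <- config$burst_gain *
        config$short_term_profile[cues$trial[i]] *
        config$long_term_profile[cues$block[i]]
      i0 <- as.integer(round(cues$onset_s[i] * config$fs))
      span <- seq_along(env) + i0
      span_ok <- span <= n
      add[span[span_ok]] <- add[span[span_ok]] + amp * env[span_ok]
    }
    rec$data[, ch] <- rec$data[, ch] + carrier * add
  }
  list(recording = rec, timeline = timeline, truth = ground_truth(config),
       electrodes = config$electrode_layout)
}
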