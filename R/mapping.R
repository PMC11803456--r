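# Electrode-level significance of movement-related high gamma: each
# electrode's per-trial window scores are tested against "resting trials"
# constructed by tiling the rest phases with pseudo-trials of the same
# length and scoring window as a movement trial.

#' Rest pseudo-trials
#'
#' Partitions every 12-s rest phase into contiguous pseudo-trials of
#' `trial_s` seconds (the length of one movement trial); a trailing
#' remainder shorter than one pseudo-trial is dropped. Each pseudo-trial is
#' scored with the identical 0.4-1.0 s evaluation window, giving the rest
#' condition of the electrode t-test.
#'
#' @param timeline An `hga_timeline`.
#' @param trial_s Pseudo-trial length (seconds).
#' @return Data frame with columns `block`, `pseudo_trial`, `onset_s`.
#' @export
rest_pseudotrials <- function(timeline, trial_s = 1.2) {
  rests <- timeline[timeline$label == "rest", , drop = FALSE]
  if (nrow(rests) == 0L)
    stop("rest_pseudotrials: timeline has no rest phases", call. = FALSE)
  if (any(rests$duration_s < trial_s))
    stop("rest_pseudotrials: rest phase shorter than one pseudo-trial",
         call. = FALSE)
  out <- lapply(seq_len(nrow(rests)), function(i) {
    k <- floor(rests$duration_s[i] / trial_s + 1e-9)
    data.frame(block = rests$block[i], pseudo_trial = seq_len(k),
               onset_s = round(rests$onset_s[i] + (seq_len(k) - 1) * trial_s, 9))
  })
  do.call(rbind, out)
}

#' Score rest pseudo-trials
#'
#' Window-mean z for every rest pseudo-trial, mirroring
#' [extract_trial_samples()] for the movement trials.
#'
#' @param z A [zscore_to_rest()] result.
#' @param timeline An `hga_timeline`.
#' @param window Scoring window (s, onset-relative).
#' @param trial_s Pseudo-trial length.
#' @return Matrix, channels x pseudo-trials, of window-mean z-scores.
#' @export
rest_trial_samples <- function(z, timeline, window = c(0.4, 1.0),
                               trial_s = 1.2) {
  stopifnot(inherits(z, "zscored_hga"))
  pt <- rest_pseudotrials(timeline, trial_s)
  out <- sapply(pt$onset_s, function(on) {
    idx <- evaluation_window(on, window = window, epoch_s = z$epoch_s,
                             n_epochs = nrow(z$z))
    colMeans(z$z[idx + 1L, , drop = FALSE])
  })
  out <- matrix(out, nrow = ncol(z$z), dimnames = list(z$channel_names, NULL))
  attr(out, "pseudotrials") <- pt
  out
}

#' Electrode-level significance of movement-related HGA
#'
#' Per electrode, a two-sided pooled-variance Student t-test compares the
#' window-mean z of all movement trials against the rest pseudo-trial
#' scores. P-values are Bonferroni-corrected by `correction_n` (by default
#' the number of recorded, non-excluded electrodes in the case). An
#' electrode is significant iff it lies inside the region of interest
#' (region PreCG or PostCG) and its corrected p is below `alpha`.
#'
#' @param trials A [extract_trial_samples()] result (movement condition).
#' @param rest Matrix from [rest_trial_samples()] (rest condition).
#' @param electrodes An [electrode_table()] aligned with the channels.
#' @param correction_n Bonferroni family size; default = number of
#'   non-excluded electrodes.
#' @param alpha Significance level after correction.
#' @param roi Region labels counted as inside the region of interest.
#' @return Data frame (one row per electrode): `name`, `region`, `in_roi`,
#'   `t`, `p`, `p_bonferroni`, `significant`, `n_move_samples`,
#'   `n_rest_samples`; attributes `correction_n` and `n_roi`.
#' @export
electrode_significance <- function(trials, rest, electrodes,
                                   correction_n = NULL, alpha = 0.05,
                                   roi = c("PreCG", "PostCG")) {
  stopifnot(inherits(trials, "trial_samples"))
  n_ch <- dim(trials$hga)[1]
  if (nrow(electrodes) != n_ch)
    stop("electrode table does not match channel count", call. = FALSE)
  included <- setdiff(seq_len(n_ch), trials$excluded_channels)
  if (is.null(correction_n)) correction_n <- length(included)
  res <- lapply(seq_len(n_ch), function(ch) {
    move <- as.numeric(trials$hga[ch, , ])
    rst <- as.numeric(rest[ch, ])
    tt <- pooled_t_test(move, rst)
    data.frame(name = electrodes$name[ch], region = electrodes$region[ch],
               t = tt$t, p = tt$p,
               n_move_samples = length(move), n_rest_samples = length(rst))
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * correction_n)
  res$in_roi <- res$region %in% roi & !(seq_len(n_ch) %in% trials$excluded_channels)
  res$significant <- res$in_roi & res$p_bonferroni < alpha
  res <- res[, c("name", "region", "in_roi", "t", "p", "p_bonferroni",
                 "significant", "n_move_samples", "n_rest_samples")]
  attr(res, "correction_n") <- correction_n
  attr(res, "n_roi") <- sum(res$in_roi)
  res
}
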