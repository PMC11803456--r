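# Quantifying repetition attenuation: cohort-level consecutive-position
# tests, per-electrode NR/R classification, temporal-dynamics curves and
# the rest-baseline drift check.

# pool one sample per (electrode, block) for a trial position, or per
# (electrode, trial) for a block, over the selected channels
pool_positions <- function(trials, by = c("trial", "block"),
                           channels = NULL) {
  by <- match.arg(by)
  stopifnot(inherits(trials, "trial_samples"))
  if (is.null(channels)) channels <- seq_len(dim(trials$hga)[1])
  h <- trials$hga[channels, , , drop = FALSE]
  if (by == "trial")
    lapply(seq_along(trials$trials), function(tr) as.numeric(h[, , tr]))
  else
    lapply(seq_along(trials$blocks), function(b) as.numeric(h[, b, ]))
}

#' Cohort-level consecutive-position attenuation test
#'
#' Pools one window-mean z sample per (electrode, block) for every trial
#' position (or per (electrode, trial) for every block), runs the
#' Kruskal-Wallis omnibus over the positions, and Dunn's post hoc test on
#' the family of consecutive pairs (1,2), (2,3), ..., Bonferroni-adjusted
#' by the family size (9 under the default paradigm).
#'
#' @param trials A [extract_trial_samples()] result.
#' @param by `"trial"` (short-term, across trial positions) or `"block"`
#'   (long-term, across blocks).
#' @param channels Channel indices to pool (typically the significant
#'   electrodes); default all.
#' @return List of class `rank_test_result`: `H`, `df`, `p_omnibus`,
#'   `pairs` (data frame i, j, z, p, p_adjusted), `n_per_group`, `by`.
#' @export
consecutive_position_test <- function(trials, by = c("trial", "block"),
                                      channels = NULL) {
  by <- match.arg(by)
  groups <- pool_positions(trials, by, channels)
  if (any(lengths(groups) == 0L) || any(vapply(groups, anyNA, logical(1))))
    stop("consecutive_position_test: missing samples at some position",
         call. = FALSE)
  k <- length(groups)
  omni <- kruskal_wallis(groups)
  fam <- lapply(seq_len(k - 1L), function(i) c(i, i + 1L))
  pairs <- dunn_posthoc(groups, pairs = fam, m = length(fam))
  structure(list(H = omni$H, df = omni$df, p_omnibus = omni$p,
                 pairs = pairs, n_per_group = lengths(groups), by = by),
            class = "rank_test_result")
}

group_stats <- function(v) {
  c(n = length(v), median = stats::median(v), mean = mean(v),
    sem = stats::sd(v) / sqrt(length(v)))
}

# per-electrode samples for NR (trial positions pooled into terciles across
# blocks) or R (blocks pooled into terciles across trials) groups; the 10th
# trial is excluded from both poolings (NA nr_group), the 10th block only
# from the R pools, so NR groups hold 3 x n_blocks and R groups
# 3 x (trials - 1) samples
grouped_samples <- function(trials, ch, which = c("nr", "r"),
                            spec = paradigm_spec()) {
  which <- match.arg(which)
  grid <- expand.grid(block = trials$blocks, trial = trials$trials)
  ga <- assign_groups(grid$block, grid$trial, spec)
  key <- if (which == "nr") ga$nr_group
         else ifelse(is.na(ga$nr_group), NA_integer_, ga$r_group)
  lapply(1:3, function(g) {
    sel <- which(!is.na(key) & key == g)
    vapply(sel, function(i) trials$hga[ch,
                                       match(ga$block[i], trials$blocks),
                                       match(ga$trial[i], trials$trials)],
           numeric(1))
  })
}

#' Per-electrode short/long-term attenuation classification
#'
#' For every electrode, trials are grouped into NR1-3 (trial positions
#' 1-3 / 4-6 / 7-9, all blocks; 30 samples each under the default paradigm)
#' and blocks into R1-3 (blocks 1-3 / 4-6 / 7-9, trials 1-9; 27 samples
#' each). A Kruskal-Wallis test over the three groups is followed by Dunn's
#' test on the pairs (1,2), (1,3), (2,3) with Bonferroni family size 3. An
#' electrode is classified attenuated iff the (1,3) comparison has adjusted
#' p below `alpha` and the mean rank of group 3 lies below that of group 1
#' (i.e. group 3 is significantly lower). Electrodes with completely tied
#' samples are classified not-attenuated and flagged `degenerate`.
#'
#' @param trials A [extract_trial_samples()] result.
#' @param channels Channel indices to classify; default all.
#' @param spec The [paradigm_spec()] defining the grouping.
#' @param alpha Significance level for the adjusted (1,3) comparison.
#' @return Data frame of class `attenuation_result`, one row per electrode:
#'   `name`, `nr_attenuated`, `r_attenuated`, group summaries
#'   (`nr<g>_n/median/mean/sem`, `r<g>_...`), adjusted p-values
#'   (`nr_p13_adj`, `r_p13_adj`), omnibus p-values and a `degenerate` flag.
#'   Attribute `samples_per_group` records the design-implied per-group
#'   sample counts.
#' @export
classify_attenuation <- function(trials, channels = NULL,
                                 spec = paradigm_spec(), alpha = 0.05) {
  stopifnot(inherits(trials, "trial_samples"))
  if (is.null(channels)) channels <- seq_len(dim(trials$hga)[1])
  fam3 <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  one_side <- function(groups) {
    if (length(unique(unlist(groups))) == 1L)
      return(list(att = FALSE, p13 = 1, p_omni = 1, degenerate = TRUE,
                  groups = groups))
    omni <- kruskal_wallis(groups)
    dp <- dunn_posthoc(groups, pairs = fam3, m = 3L)
    row13 <- dp[dp$i == 1L & dp$j == 3L, ]
    # group 3 significantly lower: adjusted p below alpha and rank(3) < rank(1)
    att <- row13$p_adjusted < alpha && row13$z > 0
    list(att = att, p13 = row13$p_adjusted, p_omni = omni$p,
         degenerate = FALSE, groups = groups)
  }
  rows <- lapply(channels, function(ch) {
    nr <- one_side(grouped_samples(trials, ch, "nr", spec))
    r <- one_side(grouped_samples(trials, ch, "r", spec))
    stats_row <- function(prefix, side) {
      s <- lapply(side$groups, group_stats)
      out <- unlist(lapply(1:3, function(g)
        stats::setNames(s[[g]], paste0(prefix, g, "_", names(s[[g]])))))
      as.data.frame(as.list(out))
    }
    cbind(data.frame(name = trials$channel_names[ch],
                     nr_attenuated = nr$att, r_attenuated = r$att,
                     nr_p13_adj = nr$p13, r_p13_adj = r$p13,
                     nr_p_omnibus = nr$p_omni, r_p_omnibus = r$p_omni,
                     degenerate = nr$degenerate || r$degenerate),
          stats_row("nr", nr), stats_row("r", r))
  })
  out <- do.call(rbind, rows)
  if (any(out$degenerate))
    warning("classify_attenuation: degenerate (all-tied) electrode(s): ",
            paste(out$name[out$degenerate], collapse = ", "), call. = FALSE)
  ga <- assign_groups(rep(trials$blocks, each = length(trials$trials)),
                      rep(trials$trials, times = length(trials$blocks)), spec)
  r_key <- ifelse(is.na(ga$nr_group), NA_integer_, ga$r_group)
  attr(out, "samples_per_group") <- list(
    nr = unname(table(ga$nr_group)), r = unname(table(r_key)),
    # one window-mean sample per trial gives the design-implied counts
    # (30/27 under the default paradigm)
    nr_design = sum(!is.na(ga$nr_group)) / 3L,
    r_design = sum(!is.na(r_key)) / 3L)
  class(out) <- c("attenuation_result", "data.frame")
  out
}

#' Temporal-dynamics curves
#'
#' Mean and two standard errors of the mean (2 SEM, sample SD based) of the
#' z-score in 100-ms steps relative to the close cue, from -0.2 s to
#' +1.2 s, pooled over (electrode x block) samples:
#' * `"trial"`: first vs ninth trial position (one sample per electrode and
#'   block per step),
#' * `"nr"`: merged NR1 vs NR3 trials,
#' * `"block"`: all trials of the first vs the last block.
#'
#' @param z A [zscore_to_rest()] result.
#' @param timeline An `hga_timeline`.
#' @param selection One of `"trial"`, `"nr"`, `"block"`.
#' @param channels Channels to pool (typically significant electrodes).
#' @param t_range Cue-relative time range (s) of the curve.
#' @param spec The [paradigm_spec()] (for NR grouping).
#' @return Data frame with columns `curve`, `time_s` (epoch start relative
#'   to cue), `mean`, `sem2`, `n`.
#' @export
temporal_dynamics <- function(z, timeline,
                              selection = c("trial", "nr", "block"),
                              channels = NULL, t_range = c(-0.2, 1.2),
                              spec = paradigm_spec()) {
  selection <- match.arg(selection)
  stopifnot(inherits(z, "zscored_hga"))
  if (is.null(channels)) channels <- seq_len(ncol(z$z))
  cues <- cue_events(timeline)
  steps <- seq(t_range[1], t_range[2] - z$epoch_s, by = z$epoch_s)
  ga <- assign_groups(cues$block, cues$trial, spec)
  sel_cues <- switch(selection,
    trial = list(trial1 = cues$trial == 1L, trial9 = cues$trial == 9L),
    nr = list(NR1 = !is.na(ga$nr_group) & ga$nr_group == 1L,
              NR3 = !is.na(ga$nr_group) & ga$nr_group == 3L),
    block = list(block1 = cues$block == min(cues$block),
                 block10 = cues$block == max(cues$block)))
  out <- lapply(names(sel_cues), function(nm) {
    ons <- cues$onset_s[sel_cues[[nm]]]
    vals <- lapply(steps, function(dt) {
      ep <- as.integer(round((ons + dt) / z$epoch_s))
      ep <- ep[ep >= 0 & ep < nrow(z$z)]
      as.numeric(z$z[ep + 1L, channels, drop = FALSE])
    })
    n <- lengths(vals)
    if (any(n <= 1L))
      stop("temporal_dynamics: n <= 1 at some step", call. = FALSE)
    data.frame(curve = nm, time_s = round(steps, 9),
               mean = vapply(vals, mean, numeric(1)),
               sem2 = vapply(vals, function(v)
                 2 * stats::sd(v) / sqrt(length(v)), numeric(1)),
               n = n)
  })
  do.call(rbind, out)
}

#' Rest-baseline drift test
#'
#' Pools the rest-phase z-score epochs of blocks 1-3 and blocks 7-9 and
#' compares them with the two-sided Mann-Whitney U test, probing whether
#' the resting baseline itself drifts over the session.
#'
#' @param z A [zscore_to_rest()] result.
#' @param timeline An `hga_timeline`.
#' @param channels Channels to pool; default all.
#' @param early_blocks,late_blocks Block index sets to compare.
#' @return List: `median_early`, `median_late`, `U`, `p`, `n_early`,
#'   `n_late`.
#' @export
baseline_drift_test <- function(z, timeline, channels = NULL,
                                early_blocks = 1:3, late_blocks = 7:9) {
  stopifnot(inherits(z, "zscored_hga"))
  if (is.null(channels)) channels <- seq_len(ncol(z$z))
  rests <- timeline[timeline$label == "rest", , drop = FALSE]
  pool <- function(blocks) {
    rr <- rests[rests$block %in% blocks, , drop = FALSE]
    if (nrow(rr) == 0L) stop("baseline_drift_test: empty block pool",
                             call. = FALSE)
    idx <- unlist(lapply(seq_len(nrow(rr)), function(i) {
      first <- ceiling(rr$onset_s[i] / z$epoch_s - 1e-9)
      last <- floor((rr$onset_s[i] + rr$duration_s[i]) / z$epoch_s + 1e-9) - 1
      seq(first, last)
    }))
    idx <- idx[idx >= 0 & idx < nrow(z$z)]
    as.numeric(z$z[idx + 1L, channels, drop = FALSE])
  }
  early <- pool(early_blocks); late <- pool(late_blocks)
  mw <- mann_whitney(early, late)
  list(median_early = stats::median(early), median_late = stats::median(late),
       U = mw$U, p = mw$p, n_early = length(early), n_late = length(late))
}
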