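#' Parametric paradigm specification
#'
#' Describes a block-design motor mapping session: a pre-session rest,
#' followed by `n_blocks` blocks, each a rest phase and a train of grasping
#' trials. One trial is a close cue immediately followed by an open cue;
#' trial timing is referenced to the close cue. The defaults reproduce a
#' 250-s session (10 s pre-rest, then 10 blocks of 12 s rest + 10 trials of
#' 0.6 s + 0.6 s).
#'
#' All durations are in seconds and must be positive multiples of the 100-ms
#' epoch grid so that cue onsets fall exactly on epoch boundaries.
#'
#' @param pre_rest_s Pre-session rest duration.
#' @param n_blocks Number of blocks.
#' @param rest_s Rest-phase duration per block.
#' @param trials_per_block Grasping trials per block.
#' @param close_s,open_s Close-cue and open-cue durations of one trial.
#' @return An object of class `paradigm_spec`.
#' @examples
#' spec <- paradigm_spec()
#' session_length(spec)  # 250
#' @export
paradigm_spec <- function(pre_rest_s = 10, n_blocks = 10, rest_s = 12,
                          trials_per_block = 10, close_s = 0.6, open_s = 0.6) {
  spec <- list(pre_rest_s = pre_rest_s, n_blocks = n_blocks, rest_s = rest_s,
               trials_per_block = trials_per_block, close_s = close_s,
               open_s = open_s)
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("paradigm_spec: '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  if (spec$n_blocks != round(spec$n_blocks) ||
      spec$trials_per_block != round(spec$trials_per_block))
    stop("paradigm_spec: counts must be whole numbers", call. = FALSE)
  # cue onsets must land on the 100-ms epoch grid
  on_grid <- function(x) abs(x / 0.1 - round(x / 0.1)) < 1e-9
  if (!all(vapply(spec[c("pre_rest_s", "rest_s", "close_s", "open_s")],
                  on_grid, logical(1))))
    stop("paradigm_spec: durations must be multiples of 0.1 s", call. = FALSE)
  structure(spec, class = "paradigm_spec")
}

#' @rdname paradigm_spec
#' @param spec A `paradigm_spec`.
#' @export
session_length <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  trial_s <- spec$close_s + spec$open_s
  spec$pre_rest_s + spec$n_blocks * (spec$rest_s + spec$trials_per_block * trial_s)
}

#' Build the experimental event timeline
#'
#' Expands a [paradigm_spec()] into the full ordered event list: one
#' `pre_rest` event, then per block a `rest` event followed by alternating
#' `close_cue` / `open_cue` events for each trial. Time origin is recording
#' start (0 s); rest phases and cue trains tile the session exactly.
#'
#' @param spec A [paradigm_spec()].
#' @return A data frame of class `hga_timeline` with columns `onset_s`,
#'   `duration_s`, `label` (one of pre_rest/rest/close_cue/open_cue),
#'   `block`, `trial` (`NA` where not applicable), carrying the spec as
#'   attribute `spec`.
#' @export
build_timeline <- function(spec = paradigm_spec()) {
  stopifnot(inherits(spec, "paradigm_spec"))
  rows <- vector("list", 1L + spec$n_blocks * (1L + 2L * spec$trials_per_block))
  rows[[1L]] <- data.frame(onset_s = 0, duration_s = spec$pre_rest_s,
                           label = "pre_rest", block = NA_integer_,
                           trial = NA_integer_)
  k <- 2L
  t0 <- spec$pre_rest_s
  for (b in seq_len(spec$n_blocks)) {
    rows[[k]] <- data.frame(onset_s = t0, duration_s = spec$rest_s,
                            label = "rest", block = b, trial = NA_integer_)
    k <- k + 1L
    t0 <- t0 + spec$rest_s
    for (tr in seq_len(spec$trials_per_block)) {
      rows[[k]] <- data.frame(onset_s = t0, duration_s = spec$close_s,
                              label = "close_cue", block = b, trial = tr)
      rows[[k + 1L]] <- data.frame(onset_s = t0 + spec$close_s,
                                   duration_s = spec$open_s,
                                   label = "open_cue", block = b, trial = tr)
      k <- k + 2L
      t0 <- t0 + spec$close_s + spec$open_s
    }
  }
  tl <- do.call(rbind, rows)
  # guard against floating-point creep on the grid
  tl$onset_s <- round(tl$onset_s, 9)
  stopifnot(abs(t0 - session_length(spec)) < 1e-9)
  structure(tl, class = c("hga_timeline", "data.frame"), spec = spec)
}

#' Assign trials and blocks to NR / R groups
#'
#' Short-term grouping (NR, "nonresting") splits trial positions 1-3 / 4-6 /
#' 7-9 into NR1-3; long-term grouping (R, "resting") splits blocks 1-3 / 4-6
#' / 7-9 into R1-3. The 10th trial of every block and the whole 10th block
#' are excluded (returned as `NA`) to balance the subgroups.
#'
#' @param block,trial Integer vectors (recycled) of 1-based block and trial
#'   indices.
#' @param spec A [paradigm_spec()] giving the valid index ranges.
#' @return Data frame with columns `block`, `trial`, `nr_group`, `r_group`;
#'   group columns are integers 1-3 or `NA` for excluded.
#' @examples
#' assign_groups(5, 10)  # NR excluded, R2
#' @export
assign_groups <- function(block, trial, spec = paradigm_spec()) {
  stopifnot(inherits(spec, "paradigm_spec"))
  n <- max(length(block), length(trial))
  block <- rep_len(as.integer(block), n)
  trial <- rep_len(as.integer(trial), n)
  if (any(is.na(block)) || any(is.na(trial)) ||
      any(block < 1L | block > spec$n_blocks) ||
      any(trial < 1L | trial > spec$trials_per_block))
    stop("assign_groups: block/trial index out of range", call. = FALSE)
  tercile <- function(i, n_excl) {
    # positions 1..(n_excl-1) in 3 equal groups; position n_excl excluded
    g <- ifelse(i == n_excl, NA_integer_, ((i - 1L) %/% ((n_excl - 1L) %/% 3L)) + 1L)
    ifelse(!is.na(g) & g > 3L, 3L, g)
  }
  data.frame(block = block, trial = trial,
             nr_group = tercile(trial, spec$trials_per_block),
             r_group = tercile(block, spec$n_blocks))
}

#' Epoch indices of the trial evaluation window
#'
#' High-gamma activity of one trial is scored over the 0.4-1.0 s window
#' after the close cue, i.e. six contiguous 100-ms epochs. Epoch indexing
#' is 0-based with half-open intervals: epoch `i` covers
#' `[i * 0.1, (i + 1) * 0.1)` seconds from recording start.
#'
#' @param cue_onset_s Cue onset in seconds; must lie on the 100-ms grid.
#' @param window Two-element window (seconds relative to cue), default
#'   `c(0.4, 1.0)`.
#' @param epoch_s Epoch length in seconds.
#' @param n_epochs Total number of epochs in the recording, if known; the
#'   window must fit inside it.
#' @return Integer vector of 0-based epoch indices (length
#'   `diff(window) / epoch_s`).
#' @examples
#' evaluation_window(0)     # 4:9
#' evaluation_window(22)    # epochs starting at 22.4 ... 22.9 s
#' @export
evaluation_window <- function(cue_onset_s, window = c(0.4, 1.0),
                              epoch_s = 0.1, n_epochs = NULL) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  grid <- c(cue_onset_s, window) / epoch_s
  if (any(abs(grid - round(grid)) > 1e-6))
    stop("evaluation_window: cue onset and window must align to the epoch grid",
         call. = FALSE)
  first <- as.integer(round((cue_onset_s + window[1]) / epoch_s))
  last <- as.integer(round((cue_onset_s + window[2]) / epoch_s)) - 1L
  idx <- first:last
  if (!is.null(n_epochs) && (first < 0L || last >= n_epochs))
    stop("evaluation_window: window [", cue_onset_s + window[1], ", ",
         cue_onset_s + window[2], ") s extends beyond the recording",
         call. = FALSE)
  idx
}

# close-cue rows of a timeline, ordered by (block, trial)
cue_events <- function(timeline) {
  stopifnot(inherits(timeline, "hga_timeline"))
  cues <- timeline[timeline$label == "close_cue", , drop = FALSE]
  if (nrow(cues) == 0L) stop("timeline contains no close_cue events", call. = FALSE)
  cues[order(cues$block, cues$trial), , drop = FALSE]
}

#' Serialize / read an event timeline
#'
#' Tab-separated, five columns (`onset_s`, `duration_s`, `label`, `block`,
#' `trial`), header row required. Empty block/trial fields are `NA`.
#'
#' @param timeline An `hga_timeline` (or compatible data frame).
#' @param path File path.
#' @return `read_events` returns an `hga_timeline` data frame.
#' @export
write_events <- function(timeline, path) {
  utils::write.table(as.data.frame(timeline)[, c("onset_s", "duration_s",
                                                 "label", "block", "trial")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tl <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label", "block", "trial")
  if (!all(need %in% names(tl)))
    stop("event table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tl$block <- as.integer(tl$block)
  tl$trial <- as.integer(tl$trial)
  if (is.unsorted(tl$onset_s, strictly = TRUE))
    stop("event onsets must be strictly increasing", call. = FALSE)
  structure(tl[, need], class = c("hga_timeline", "data.frame"))
}
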