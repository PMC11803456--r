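# File interfaces: recordings as a delimited matrix with a JSON sidecar
# header, events and electrode tables as TSV, ground truth and run reports
# as JSON, run configuration as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a continuous recording
#'
#' The signal is stored as a tab-separated matrix (samples in rows, one
#' column per channel, header row of channel names) next to a JSON sidecar
#' (`<path>.json`) recording the sampling rate, channel names, excluded
#' channels and sample count. Reading validates the sidecar against the
#' matrix and enforces the >= 1200 Hz acquisition floor.
#'
#' @param rec A [continuous_recording()].
#' @param path Path of the matrix file; the sidecar is written next to it.
#' @param digits Significant digits kept in the text matrix.
#' @return `read_recording` returns a [continuous_recording()].
#' @export
write_recording <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "continuous_recording"))
  m <- signif(rec$data, digits)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names,
         excluded_channels = rec$excluded_channels,
         n_samples = nrow(rec$data), unit = "uV"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path,
                               call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar header ", sc,
         " (required for delimited recordings)", call. = FALSE)
  hdr <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(hdr$fs) || hdr$fs < 1200)
    stop("recordings must be acquired at >= 1200 Hz (sidecar fs = ",
         hdr$fs, ")", call. = FALSE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  if (!is.null(hdr$n_samples) && nrow(m) != hdr$n_samples)
    stop("sidecar/sample-count mismatch: header says ", hdr$n_samples,
         ", file has ", nrow(m), call. = FALSE)
  if (length(hdr$channel_names) != ncol(m))
    stop("sidecar names ", length(hdr$channel_names),
         " channels but file has ", ncol(m), call. = FALSE)
  continuous_recording(m, hdr$fs, channel_names = hdr$channel_names,
                       excluded_channels = as.integer(hdr$excluded_channels))
}

#' Write / read ground truth
#'
#' @param truth A [ground_truth()] list.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$responsive <- as.logical(gt$responsive)
  gt$short_term_attenuated <- as.logical(gt$short_term_attenuated)
  gt$long_term_attenuated <- as.logical(gt$long_term_attenuated)
  gt
}

#' Write a z-score (or log-power) matrix with epoch-time header
#'
#' Tab-separated, one row per 100-ms epoch, first column `epoch_start_s`
#' (epochs are 0-based half-open intervals), then one column per channel;
#' a JSON sidecar stores the per-channel baseline mean/SD.
#'
#' @param z A [zscore_to_rest()] result.
#' @param path Output path.
#' @export
write_zscores <- function(z, path) {
  stopifnot(inherits(z, "zscored_hga"))
  df <- data.frame(epoch_start_s = z$epoch_start_s, z$z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(epoch_s = z$epoch_s, indexing = "0-based, half-open",
         baseline_mean = as.list(stats::setNames(z$baseline_mean,
                                                 z$channel_names)),
         baseline_sd = as.list(stats::setNames(z$baseline_sd,
                                               z$channel_names))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' Collects every knob of the pipeline under named keys. Either
#' `simulate = TRUE` (with `synthetic` holding [synthetic_config()]
#' arguments) or the three input paths must be given.
#'
#' @param simulate Generate the inputs with the synthetic module.
#' @param recording,events,electrodes Input paths (ignored when
#'   simulating).
#' @param output_dir Output directory; `NULL` keeps results in memory only.
#' @param paradigm Named list of [paradigm_spec()] overrides.
#' @param synthetic Named list of [synthetic_config()] overrides.
#' @param zero_phase Filtering convention (see [remove_drift()]).
#' @param window Trial evaluation window (s, cue-relative).
#' @param alpha Significance level.
#' @param correction_n Bonferroni family size policy: `"all"` (all
#'   non-excluded electrodes) or a number.
#' @param sigma_left,sigma_right Hand-knob reference points (MNI mm).
#' @param seed Seed forwarded to the generator.
#' @param stages Character subset of `c("map", "attenuate", "spatial")`;
#'   stages left out are skipped.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, recording = NULL, events = NULL,
                       electrodes = NULL, output_dir = NULL,
                       paradigm = list(), synthetic = list(),
                       zero_phase = FALSE, window = c(0.4, 1.0),
                       alpha = 0.05, correction_n = "all",
                       sigma_left = c(-36, -22, 54),
                       sigma_right = c(36, -22, 54),
                       seed = 1,
                       stages = c("map", "attenuate", "spatial")) {
  cfg <- list(simulate = isTRUE(simulate), recording = recording,
              events = events, electrodes = electrodes,
              output_dir = output_dir, paradigm = paradigm,
              synthetic = synthetic, zero_phase = isTRUE(zero_phase),
              window = window, alpha = alpha, correction_n = correction_n,
              sigma_left = sigma_left, sigma_right = sigma_right,
              seed = as.integer(seed), stages = stages)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!cfg$simulate) {
    missing <- c("recording", "events", "electrodes")[
      vapply(cfg[c("recording", "events", "electrodes")], is.null, logical(1))]
    if (length(missing))
      stop("run_config: need input path(s) ", paste(missing, collapse = ", "),
           " when simulate = FALSE", call. = FALSE)
  }
  if (length(cfg$window) != 2L || cfg$window[2] <= cfg$window[1])
    stop("run_config: invalid evaluation window", call. = FALSE)
  if (!(identical(cfg$correction_n, "all") ||
        (is.numeric(cfg$correction_n) && cfg$correction_n >= 1)))
    stop("run_config: correction_n must be \"all\" or a count", call. = FALSE)
  bad <- setdiff(cfg$stages, c("map", "attenuate", "spatial"))
  if (length(bad))
    stop("run_config: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (("attenuate" %in% cfg$stages || "spatial" %in% cfg$stages) &&
      !("map" %in% cfg$stages))
    stop("run_config: attenuate/spatial require the map stage", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the keys above.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("read_run_config: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}
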