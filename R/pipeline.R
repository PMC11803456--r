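# End-to-end driver: (simulate) -> preprocess -> map -> attenuate ->
# spatial, collecting a schema-versioned run report.

REPORT_SCHEMA <- "hgamapr-report/1"

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in fixed order and assembles a run
#' report. With `simulate = TRUE` the synthetic generator provides the
#' recording, timeline, electrode table and ground truth; otherwise the
#' three input files are read. Identical configuration (including seed)
#' yields a byte-identical report.
#'
#' @param config A [run_config()].
#' @return List of class `run_result`: `report` (serializable summary),
#'   `significance`, `attenuation`, `dynamics`, `spatial`, `trials`, `z`,
#'   `truth` (when simulated), `timeline`, `electrodes`, `warnings`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(unclass(config))
  warn <- character(0)
  note <- function(w) warn <<- c(warn, w)

  spec <- do.call(paradigm_spec, config$paradigm)
  if (config$simulate) {
    sim <- stage_try("simulate", {
      syn_args <- config$synthetic
      syn_args$seed <- config$seed
      generate_recording(do.call(synthetic_config, syn_args), spec)
    })
    rec <- sim$recording; timeline <- sim$timeline
    electrodes <- sim$electrodes; truth <- sim$truth
  } else {
    rec <- stage_try("read", read_recording(config$recording))
    timeline <- stage_try("read", read_events(config$events))
    electrodes <- stage_try("read", read_electrodes(config$electrodes))
    truth <- NULL
    if (nrow(electrodes) != ncol(rec$data))
      stop("stage 'read' failed: electrode table has ", nrow(electrodes),
           " rows but recording has ", ncol(rec$data), " channels (",
           paste(utils::head(setdiff(electrodes$name, rec$channel_names), 5),
                 collapse = ", "), ")", call. = FALSE)
    rec$excluded_channels <- sort(unique(c(rec$excluded_channels,
                                           which(electrodes$ground))))
  }

  pre <- stage_try("preprocess",
                   hga_preprocess(rec, timeline,
                                  zero_phase = config$zero_phase,
                                  window = config$window))
  z <- pre$z; trials <- pre$trials

  significance <- NULL; attenuation <- NULL; dynamics <- NULL
  spatial <- NULL; sig_idx <- integer(0)

  if ("map" %in% config$stages) {
    significance <- stage_try("map", {
      rest <- rest_trial_samples(z, timeline, window = config$window,
                                 trial_s = spec$close_s + spec$open_s)
      corr_n <- if (identical(config$correction_n, "all")) NULL
                else as.integer(config$correction_n)
      electrode_significance(trials, rest, electrodes,
                             correction_n = corr_n, alpha = config$alpha)
    })
    sig_idx <- which(significance$significant)
    if (length(sig_idx) == 0L) note("no significant electrodes")
  }

  if ("attenuate" %in% config$stages && length(sig_idx) > 0L) {
    attenuation <- stage_try("attenuate",
      withCallingHandlers(
        classify_attenuation(trials, channels = sig_idx, spec = spec,
                             alpha = config$alpha),
        warning = function(w) {
          note(conditionMessage(w)); invokeRestart("muffleWarning")
        }))
    dynamics <- stage_try("attenuate", {
      cohort <- list(
        by_trial = consecutive_position_test(trials, "trial", sig_idx),
        by_block = consecutive_position_test(trials, "block", sig_idx))
      curves <- do.call(rbind, lapply(c("trial", "nr", "block"),
        function(sel) temporal_dynamics(z, timeline, sel, sig_idx,
                                        spec = spec)))
      baseline <- baseline_drift_test(z, timeline, channels = sig_idx)
      list(cohort = cohort, curves = curves, baseline = baseline)
    })
  }

  if ("spatial" %in% config$stages && !is.null(attenuation)) {
    spatial <- stage_try("spatial", {
      sig_el <- electrodes[sig_idx, , drop = FALSE]
      dist <- withCallingHandlers(
        handknob_distances(sig_el, config$sigma_left, config$sigma_right),
        warning = function(w) {
          note(conditionMessage(w)); invokeRestart("muffleWarning")
        })
      one <- function(att) {
        res <- list(contingency = gyrus_contingency(att, sig_el$region))
        if (any(att) && any(!att))
          res$distance <- distance_attenuation_test(dist, att)
        else
          note("attenuation groups one-sided; distance test skipped")
        res
      }
      list(distances = dist, nr = one(attenuation$nr_attenuated),
           r = one(attenuation$r_attenuated))
    })
  }

  n_ch <- ncol(rec$data)
  report <- list(
    schema = REPORT_SCHEMA,
    config = config[c("simulate", "zero_phase", "window", "alpha",
                      "correction_n", "sigma_left", "sigma_right", "seed",
                      "stages")],
    paradigm = unclass(spec),
    session_s = session_length(spec),
    stages_run = c("preprocess", intersect(config$stages,
      c("map", if (!is.null(attenuation)) "attenuate",
        if (!is.null(spatial)) "spatial"))),
    stages_skipped = setdiff(c("map", "attenuate", "spatial"),
                             config$stages),
    counts = list(
      electrodes_total = n_ch,
      electrodes_excluded = length(rec$excluded_channels),
      electrodes_roi = if (is.null(significance)) NA_integer_
                       else attr(significance, "n_roi"),
      electrodes_significant = length(sig_idx),
      correction_n = if (is.null(significance)) NA_integer_
                     else attr(significance, "correction_n"),
      n_short_term_attenuated = if (is.null(attenuation)) NA_integer_
                                else sum(attenuation$nr_attenuated),
      n_long_term_attenuated = if (is.null(attenuation)) NA_integer_
                               else sum(attenuation$r_attenuated),
      pooled_samples_per_trial_position = if (is.null(attenuation)) NA_integer_
        else unname(dynamics$cohort$by_trial$n_per_group[1]),
      pooled_samples_per_block = if (is.null(attenuation)) NA_integer_
        else unname(dynamics$cohort$by_block$n_per_group[1]),
      samples_per_nr_group = if (is.null(attenuation)) NA_integer_
        else attr(attenuation, "samples_per_group")$nr_design,
      samples_per_r_group = if (is.null(attenuation)) NA_integer_
        else attr(attenuation, "samples_per_group")$r_design),
    warnings = warn)
  if (!is.null(truth))
    report$ground_truth_counts <- list(
      responsive = sum(truth$responsive),
      short_term_attenuated = sum(truth$short_term_attenuated),
      long_term_attenuated = sum(truth$long_term_attenuated))

  result <- structure(list(report = report, significance = significance,
                           attenuation = attenuation, dynamics = dynamics,
                           spatial = spatial, trials = trials, z = z,
                           truth = truth, timeline = timeline,
                           electrodes = electrodes, warnings = warn),
                      class = "run_result")
  if (!is.null(config$output_dir))
    write_results(result, config$output_dir, config = config)
  result
}

#' @export
print.run_result <- function(x, ...) {
  cat("<hgamapr run>\n")
  co <- x$report$counts
  cat(sprintf("  electrodes: %d total, %s in ROI, %s significant\n",
              co$electrodes_total, co$electrodes_roi,
              co$electrodes_significant))
  if (!is.na(co$n_short_term_attenuated))
    cat(sprintf("  attenuated: %d short-term, %d long-term (of %s significant)\n",
                co$n_short_term_attenuated, co$n_long_term_attenuated,
                co$electrodes_significant))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write pipeline results to an output directory
#'
#' Emits tab-separated tables with documented headers, a schema-versioned
#' JSON report, the fully-resolved configuration, ground truth (when
#' simulated) and a log of warnings.
#'
#' @param result A `run_result` from [run_pipeline()].
#' @param output_dir Directory (created if needed).
#' @param config Optional [run_config()] echoed as `config.yaml`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, output_dir, config = NULL) {
  stopifnot(inherits(result, "run_result"))
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                             showWarnings = FALSE)
  if (!ok || file.access(output_dir, 2) != 0)
    stop("write_results: cannot write to ", output_dir, call. = FALSE)
  paths <- character(0)
  emit <- function(df, file) {
    p <- file.path(output_dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  p_report <- file.path(output_dir, "report.json")
  jsonlite::write_json(result$report, p_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, p_report)
  write_events(result$timeline, file.path(output_dir, "events.tsv"))
  write_electrodes(result$electrodes, file.path(output_dir, "electrodes.tsv"))
  if (!is.null(result$significance))
    emit(result$significance, "significance.tsv")
  if (!is.null(result$attenuation))
    emit(as.data.frame(result$attenuation), "attenuation.tsv")
  if (!is.null(result$dynamics)) {
    emit(result$dynamics$curves, "dynamics_curves.tsv")
    for (by in c("by_trial", "by_block"))
      emit(result$dynamics$cohort[[by]]$pairs,
           paste0("consecutive_", by, ".tsv"))
  }
  if (!is.null(result$spatial))
    emit(data.frame(name = names(result$spatial$distances),
                    distance_mm = as.numeric(result$spatial$distances)),
         "handknob_distances.tsv")
  if (!is.null(result$truth))
    write_ground_truth(result$truth,
                       file.path(output_dir, "ground_truth.json"))
  if (!is.null(config))
    yaml::write_yaml(lapply(unclass(config), function(x)
      if (is.null(x)) NULL else x), file.path(output_dir, "config.yaml"))
  writeLines(c("hgamapr run log", paste0("warning: ", result$warnings)),
             file.path(output_dir, "log.txt"))
  invisible(paths)
}
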