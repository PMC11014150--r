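# End-to-end pipeline: trigger emulation -> non-wear -> epoch features ->
# reference tracking -> APE/posture -> day summaries -> participant decision,
# with a declarative config whose defaults are the published operating points.

#' Pipeline configuration
#'
#' Collects every tunable threshold with its published default. The config is
#' validated on construction and echoed into every run report.
#'
#' @param epoch_s Epoch length in seconds (6).
#' @param sb_gate_mg Sedentary gate on MAD in mg (22.5).
#' @param walking_mad MAD range for normal walking in mg (`c(150, 350)`).
#' @param walking_steps Step-count range per epoch (`c(8, 13)`).
#' @param walking_ratio_max Strict bound on MADxyz/MAD (1.6).
#' @param cutpoints Posture cut-points in degrees
#'   (`c(stand_sit = 11.6, sit_recline = 30, recline_lie = 73.9)`).
#' @param arm_threshold_mg,confirm_threshold_mg,confirm_window_s Trigger
#'   parameters (187.5 mg, 500 mg, 5 s).
#' @param nonwear_limit_min Non-wear limit in minutes (120).
#' @param wear_tolerance_min Minimum wear minutes for a complete day (1436).
#' @param min_settings Minimum daily reference settings (10).
#' @param min_valid_days Minimum valid days for inclusion (4).
#' @param backfill_reference Carry the first reference backwards (`FALSE`).
#' @param seed Optional integer seed recorded in the run report.
#' @return List of class `ape_config`.
#' @export
ape_config <- function(epoch_s = 6, sb_gate_mg = 22.5,
                       walking_mad = c(150, 350), walking_steps = c(8, 13),
                       walking_ratio_max = 1.6,
                       cutpoints = c(stand_sit = 11.6, sit_recline = 30,
                                     recline_lie = 73.9),
                       arm_threshold_mg = 187.5, confirm_threshold_mg = 500,
                       confirm_window_s = 5, nonwear_limit_min = 120,
                       wear_tolerance_min = 1436, min_settings = 10,
                       min_valid_days = 4, backfill_reference = FALSE,
                       seed = NULL) {
  cfg <- list(epoch_s = epoch_s, sb_gate_mg = sb_gate_mg,
              walking_mad = walking_mad, walking_steps = walking_steps,
              walking_ratio_max = walking_ratio_max, cutpoints = cutpoints,
              arm_threshold_mg = arm_threshold_mg,
              confirm_threshold_mg = confirm_threshold_mg,
              confirm_window_s = confirm_window_s,
              nonwear_limit_min = nonwear_limit_min,
              wear_tolerance_min = wear_tolerance_min,
              min_settings = min_settings, min_valid_days = min_valid_days,
              backfill_reference = backfill_reference, seed = seed)
  for (nm in c("epoch_s", "sb_gate_mg", "walking_ratio_max",
               "arm_threshold_mg", "confirm_threshold_mg", "confirm_window_s",
               "nonwear_limit_min", "wear_tolerance_min")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_config(nm, " must be a single positive number")
  }
  if (length(cfg$walking_mad) != 2L || diff(cfg$walking_mad) <= 0)
    stop_config("walking_mad must be an increasing range")
  if (length(cfg$walking_steps) != 2L || diff(cfg$walking_steps) < 0)
    stop_config("walking_steps must be a non-decreasing range")
  if (length(cfg$cutpoints) != 3L || is.unsorted(cfg$cutpoints, strictly = TRUE))
    stop_config("cutpoints must be three increasing angles")
  structure(cfg, class = "ape_config")
}

#' Process one raw recording through the full pipeline
#'
#' Runs trigger emulation, non-wear detection, epoch feature extraction,
#' reference-vector tracking, APE/posture annotation and day summaries, and
#' takes the participant-inclusion decision.
#'
#' @param rec A [raw_recording()] (or a path readable by
#'   [read_raw_recording()]).
#' @param sleep Optional [sleep_log()] (or a path readable by
#'   [read_sleep_log()]).
#' @param config An [ape_config()].
#' @return List with `epochs`, `wear`, `days`, `participant`, `settings_log`
#'   and `config`.
#' @export
process_recording <- function(rec, sleep = NULL, config = ape_config()) {
  stopifnot(inherits(config, "ape_config"))
  if (is.character(rec)) rec <- read_raw_recording(rec)
  if (is.character(sleep)) sleep <- read_sleep_log(sleep)
  mask <- emulate_trigger(rec, arm_threshold_mg = config$arm_threshold_mg,
                          confirm_threshold_mg = config$confirm_threshold_mg,
                          confirm_window_s = config$confirm_window_s)
  wear <- detect_nonwear(mask, limit_min = config$nonwear_limit_min)
  epochs <- compute_epochs(rec, wear = wear, epoch_s = config$epoch_s)
  epochs <- track_reference(epochs, mad_range = config$walking_mad,
                            step_range = config$walking_steps,
                            ratio_max = config$walking_ratio_max,
                            backfill = config$backfill_reference)
  settings_log <- attr(epochs, "settings_log")
  epochs <- annotate_postures(epochs, sb_gate_mg = config$sb_gate_mg,
                              cutpoints = config$cutpoints)
  days <- summarize_days(epochs, sleep = sleep,
                         wear_tolerance_min = config$wear_tolerance_min,
                         min_settings = config$min_settings,
                         epoch_s = config$epoch_s)
  participant <- select_participant(days, min_valid_days = config$min_valid_days)
  list(epochs = epochs, wear = wear, days = days, participant = participant,
       settings_log = settings_log, config = config)
}

#' Run the pipeline and write its output tables and run report
#'
#' Writes the epoch table, wear segments, day summaries and a JSON run report
#' (package version, config echo and hash, per-day settings counts, exclusion
#' reasons) under `out_dir`. Deterministic given config and seed.
#'
#' @inheritParams process_recording
#' @param out_dir Output directory (created if missing); `NULL` skips writing.
#' @return The [process_recording()] result, with `report` added, invisibly.
#' @export
run_pipeline <- function(rec, sleep = NULL, out_dir = NULL,
                         config = ape_config()) {
  stopifnot(inherits(config, "ape_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- process_recording(rec, sleep = sleep, config = config)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               null = "null")
  excl <- character(0)
  if (!res$participant$included) {
    excl <- sprintf("only %d valid days (minimum %d)",
                    res$participant$n_valid_days, config$min_valid_days)
  }
  report <- list(
    package = "madape",
    version = as.character(utils::packageVersion("madape")),
    config = unclass(config),
    config_hash = sum(utf8ToInt(as.character(cfg_json))),
    days = data.frame(date = as.character(res$days$date),
                      wear_min = res$days$wear_min,
                      settings = res$days$settings, valid = res$days$valid),
    included = res$participant$included,
    exclusion_reasons = excl)
  res$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_epoch_table(res$epochs, file.path(out_dir, "epochs.csv"))
    write_wear_segments(res$wear, file.path(out_dir, "wear_segments.csv"))
    days_out <- res$days
    days_out$date <- as.character(days_out$date)
    write.csv(days_out, file.path(out_dir, "day_summaries.csv"),
              row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(res)
}
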