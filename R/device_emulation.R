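# Software re-creation of the device's trigger/quiescence behavior. The
# device arms when any-axis acceleration departs more than 187.5 mg from its
# running reference and confirms activity if a 500 mg departure follows within
# 5 s; otherwise it returns to quiescence. Here the same state machine is run
# over continuously recorded files so that non-wear (a quiescent run longer
# than 120 min) can be derived offline.

#' Emulate the device trigger and derive a quiescence mask
#'
#' Runs the trigger state machine over every sample and returns a per-sample
#' active/quiescent mask, down-sampled to per-second resolution for
#' segmentation. The per-axis reference initializes to the first sample and is
#' updated with the coincident values whenever either threshold is exceeded;
#' all threshold comparisons are strict, so a deviation of exactly the
#' threshold does not trigger. A confirmed activation is marked active from
#' the arming sample onward; an unconfirmed arming leaves its samples
#' quiescent. Activity ends once `quiet_timeout_s` pass without an arm-level
#' deviation, with the quiescent run starting right after the last deviation.
#'
#' @param rec A [raw_recording()].
#' @param arm_threshold_mg Arming threshold in mg (default 187.5).
#' @param confirm_threshold_mg Confirmation threshold in mg (default 500).
#' @param confirm_window_s Confirmation window in seconds (default 5).
#' @param quiet_timeout_s Seconds without an arm-level deviation after which
#'   the active state ends (default: same 5 s window).
#' @return An object of class `quiescence_mask`: list with per-sample logical
#'   `active`, per-second logical `active_s` (a second is active if any of its
#'   samples is), `sampling_rate` and `start_time`.
#' @export
emulate_trigger <- function(rec, arm_threshold_mg = 187.5,
                            confirm_threshold_mg = 500,
                            confirm_window_s = 5, quiet_timeout_s = 5) {
  stopifnot(inherits(rec, "raw_recording"))
  if (arm_threshold_mg <= 0 || confirm_threshold_mg <= 0 ||
      confirm_window_s <= 0 || quiet_timeout_s <= 0)
    stop_config("trigger thresholds and windows must be positive")
  window <- as.integer(round(confirm_window_s * rec$sampling_rate))
  quiet <- as.integer(round(quiet_timeout_s * rec$sampling_rate))
  active <- trigger_machine_cpp(rec$data, arm_threshold_mg / 1000,
                                confirm_threshold_mg / 1000, window, quiet)
  n <- length(active)
  sec <- floor((seq_len(n) - 1) / rec$sampling_rate)
  active_s <- as.logical(tapply(active, sec, any))
  structure(list(active = active, active_s = unname(active_s),
                 sampling_rate = rec$sampling_rate,
                 start_time = rec$start_time),
            class = "quiescence_mask")
}

#' @export
print.quiescence_mask <- function(x, ...) {
  cat(sprintf("<quiescence_mask> %d s, %.1f%% active\n",
              length(x$active_s), 100 * mean(x$active_s)))
  invisible(x)
}

#' Segment a quiescence mask into alternating runs
#'
#' @param mask A `quiescence_mask`.
#' @return Data frame with `start`, `end` (`POSIXct`), `duration_s` and
#'   `active`; the segments partition the recording.
#' @export
mask_segments <- function(mask) {
  stopifnot(inherits(mask, "quiescence_mask"))
  r <- rle(mask$active_s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = mask$start_time + starts,
             end = mask$start_time + ends,
             duration_s = r$lengths,
             active = r$values)
}

#' Detect non-wear time from a quiescence mask
#'
#' A quiescent run strictly longer than `limit_min` minutes is classified as
#' non-wear; all other time is wear. A run of exactly `limit_min` minutes
#' therefore remains wear.
#'
#' @param mask A `quiescence_mask` from [emulate_trigger()].
#' @param limit_min Non-wear limit in minutes (default 120).
#' @return Data frame of contiguous segments with `start`, `end`,
#'   `duration_s` and logical `wear`, covering the full recording.
#' @export
detect_nonwear <- function(mask, limit_min = 120) {
  stopifnot(inherits(mask, "quiescence_mask"))
  if (limit_min <= 0) stop_config("limit_min must be positive")
  seg <- mask_segments(mask)
  seg$wear <- seg$active | seg$duration_s <= limit_min * 60
  # merge adjacent segments with equal wear state
  if (nrow(seg) > 1) {
    grp <- cumsum(c(TRUE, diff(seg$wear) != 0))
  } else grp <- rep(1L, nrow(seg))
  out <- do.call(rbind, lapply(split(seg, grp), function(s) {
    data.frame(start = s$start[1], end = s$end[nrow(s)],
               duration_s = sum(s$duration_s), wear = s$wear[1])
  }))
  rownames(out) <- NULL
  out
}

#' Write wear segments as a three-column delimited table
#' @param segments Output of [detect_nonwear()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wear_segments <- function(segments, path) {
  df <- data.frame(start = format(segments$start, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
                   end = format(segments$end, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
                   wear = segments$wear)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
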