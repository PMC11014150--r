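# Day-level validity rules and behavior summaries. A valid day has complete
# 24 h wear (>= 1436 of 1440 min by default) and at least 10 reference-vector
# settings; participants need at least four valid days for inclusion.
# Sleep-log intervals are excluded from all behavior summaries because the
# device moves to the wrist in bed.

.met_breaks <- c(-Inf, seq(1.5, 12, by = 1.5), Inf)
.met_category <- c("stationary", "light", "moderate", "moderate",
                   "vigorous", "vigorous", "very_vigorous", "very_vigorous",
                   "very_vigorous")

# TRUE where a time falls inside any sleep interval.
in_sleep <- function(times, sleep) {
  if (is.null(sleep) || nrow(sleep) == 0L) return(rep(FALSE, length(times)))
  tn <- as.numeric(times)
  asleep <- rep(FALSE, length(times))
  for (i in seq_len(nrow(sleep))) {
    asleep <- asleep | (tn >= as.numeric(sleep$start[i]) &
                          tn < as.numeric(sleep$end[i]))
  }
  asleep
}

#' MET histogram over awake wear epochs
#'
#' Nine equally wide 1.5 MET bins from below 1.5 to above 12 METs. The lowest
#' bin corresponds to stationary behavior, the second to light activity, bins
#' 3-4 to moderate, 5-6 to vigorous and 7-9 to very vigorous activity. Each
#' 6 s epoch contributes 0.1 min, so the bins sum to awake wear time.
#'
#' @param epochs Epoch data frame with `met` and `wear`.
#' @param sleep Optional [sleep_log()]; epochs starting inside an interval are
#'   excluded.
#' @param epoch_s Epoch length in seconds (default 6).
#' @return Data frame with `met_low`, `met_high`, `category`, `minutes`.
#' @export
build_met_histogram <- function(epochs, sleep = NULL, epoch_s = 6) {
  keep <- epochs$wear & !is.na(epochs$met) &
    !in_sleep(epochs$start_time, sleep)
  met <- epochs$met[keep]
  counts <- if (length(met)) {
    tabulate(findInterval(met, .met_breaks[-c(1, length(.met_breaks))]) + 1L,
             nbins = 9L)
  } else rep(0L, 9L)
  data.frame(met_low = .met_breaks[-length(.met_breaks)],
             met_high = .met_breaks[-1],
             category = .met_category,
             minutes = counts * epoch_s / 60)
}

#' Summarize and validity-check one day of epochs
#'
#' A day is valid when its wear time reaches `wear_tolerance_min` (default
#' 1436 of 1440 min, i.e. complete 24 h wear with a small tolerance) and the
#' reference vector was set at least `min_settings` times.
#'
#' @param day_epochs Annotated epochs of one calendar day.
#' @param sleep Optional [sleep_log()].
#' @param settings Number of reference settings that day; counted from the
#'   `is_reference` column when `NULL`.
#' @param wear_tolerance_min Minimum wear minutes for a complete day (default 1436).
#' @param min_settings Minimum daily reference settings (default 10).
#' @param epoch_s Epoch length in seconds (default 6).
#' @return One-row data frame: `date`, `wear_min`, `settings`, `valid`,
#'   `stationary_min`, `met_min_1..9`, `ape_min_1..18`, and minutes per
#'   posture (`standing_min`, `sitting_min`, `reclining_min`, `lying_min`).
#' @export
assess_day_validity <- function(day_epochs, sleep = NULL, settings = NULL,
                                wear_tolerance_min = 1436, min_settings = 10,
                                epoch_s = 6) {
  wear_min <- sum(day_epochs$wear) * epoch_s / 60
  if (is.null(settings)) {
    settings <- if ("is_reference" %in% names(day_epochs))
      sum(day_epochs$is_reference, na.rm = TRUE) else 0L
  }
  awake <- day_epochs[!in_sleep(day_epochs$start_time, sleep), , drop = FALSE]
  met_h <- build_met_histogram(awake, sleep = NULL, epoch_s = epoch_s)
  if (all(c("ape_deg", "posture", "stationary") %in% names(day_epochs))) {
    ape_h <- build_ape_histogram(awake, epoch_s = epoch_s)
    post <- awake$posture[awake$stationary & !is.na(awake$ape_deg)]
    post_min <- table(factor(post, levels = c("standing", "sitting",
                                              "reclining", "lying"))) * epoch_s / 60
  } else {
    ape_h <- data.frame(minutes = rep(0, 18))
    post_min <- stats::setNames(rep(0, 4), c("standing", "sitting",
                                             "reclining", "lying"))
  }
  out <- data.frame(date = as.Date(day_epochs$start_time[1], tz = "UTC"),
                    wear_min = wear_min, settings = settings,
                    valid = wear_min >= wear_tolerance_min &
                      settings >= min_settings,
                    stationary_min = sum(ape_h$minutes))
  met_cols <- as.data.frame(as.list(stats::setNames(met_h$minutes,
                                                    paste0("met_min_", 1:9))))
  ape_cols <- as.data.frame(as.list(stats::setNames(ape_h$minutes,
                                                    paste0("ape_min_", 1:18))))
  pm <- as.data.frame(as.list(stats::setNames(as.numeric(post_min),
                                              paste0(names(post_min), "_min"))))
  cbind(out, met_cols, ape_cols, pm)
}

#' Per-day summaries for a whole recording
#'
#' Splits an annotated epoch table by calendar date and applies
#' [assess_day_validity()] to each day.
#'
#' @param epochs Annotated epoch data frame ([annotate_postures()]).
#' @param sleep Optional [sleep_log()].
#' @param wear_tolerance_min,min_settings,epoch_s See [assess_day_validity()].
#' @return Data frame with one row per calendar day.
#' @export
summarize_days <- function(epochs, sleep = NULL, wear_tolerance_min = 1436,
                           min_settings = 10, epoch_s = 6) {
  if (nrow(epochs) == 0L) stop_data("no epochs to summarize")
  dates <- as.Date(epochs$start_time, tz = "UTC")
  out <- do.call(rbind, lapply(split(epochs, dates), assess_day_validity,
                               sleep = sleep,
                               wear_tolerance_min = wear_tolerance_min,
                               min_settings = min_settings, epoch_s = epoch_s))
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Participant-level inclusion decision and mean daily minutes
#'
#' A participant is included when at least `min_valid_days` days are valid;
#' per-bin mean daily minutes are taken over the valid days only.
#'
#' @param days Day-summary data frame from [summarize_days()].
#' @param min_valid_days Minimum number of valid days (default 4).
#' @return List with `included`, `n_valid_days`, `n_days` and `mean_minutes`
#'   (named numeric vector of per-bin/per-posture daily means; `NA` when no
#'   valid days).
#' @export
select_participant <- function(days, min_valid_days = 4) {
  valid <- days[days$valid, , drop = FALSE]
  num_cols <- setdiff(names(days)[vapply(days, is.numeric, logical(1))],
                      c("settings"))
  means <- if (nrow(valid)) colMeans(valid[, num_cols, drop = FALSE])
  else stats::setNames(rep(NA_real_, length(num_cols)), num_cols)
  list(included = nrow(valid) >= min_valid_days,
       n_valid_days = nrow(valid), n_days = nrow(days),
       mean_minutes = means)
}

#' Hour-by-hour stationary profile
#'
#' Accumulates stationary minutes per clock hour, split into APE below 30
#' degrees (standing and sitting) versus at least 30 degrees (reclining and
#' lying), averaged over the selected days of the requested day type.
#' Weekend days are Saturday and Sunday by the local calendar.
#'
#' @param epochs Annotated epoch data frame.
#' @param sleep Optional [sleep_log()].
#' @param dates Dates (class `Date`) to include, typically the valid days;
#'   all days present when `NULL`.
#' @param weekend `FALSE` for weekdays (default), `TRUE` for weekend days.
#' @param split_deg APE split in degrees (default 30; the boundary value
#'   counts as the upper split).
#' @param epoch_s Epoch length in seconds (default 6).
#' @return Data frame with `hour` (0-23), `lt_min` and `ge_min`: mean minutes
#'   per day below/at-or-above the split. Zero rows of data give a zero
#'   profile.
#' @export
hourly_stationary_profile <- function(epochs, sleep = NULL, dates = NULL,
                                      weekend = FALSE, split_deg = 30,
                                      epoch_s = 6) {
  d <- as.Date(epochs$start_time, tz = "UTC")
  if (is.null(dates)) dates <- unique(d)
  is_we <- format(dates, "%u") %in% c("6", "7")
  dates <- dates[is_we == weekend]
  out <- data.frame(hour = 0:23, lt_min = 0, ge_min = 0)
  if (!length(dates)) return(out)
  keep <- d %in% dates & (epochs$stationary %||% FALSE) &
    !is.na(epochs$ape_deg) & !in_sleep(epochs$start_time, sleep)
  e <- epochs[keep, , drop = FALSE]
  if (nrow(e)) {
    hr <- as.integer(format(e$start_time, "%H", tz = "UTC"))
    lt <- e$ape_deg < split_deg
    for (h in 0:23) {
      out$lt_min[h + 1] <- sum(hr == h & lt) * epoch_s / 60 / length(dates)
      out$ge_min[h + 1] <- sum(hr == h & !lt) * epoch_s / 60 / length(dates)
    }
  }
  out
}
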