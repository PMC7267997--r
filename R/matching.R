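# Matching each completed EMA survey to its accelerometer pre-period and
# building the standardized analysis table.

#' Validate EMA response days
#'
#' A participant-day is a valid response day when at least
#' `min_completed` of its (at most four) signal-contingent surveys were
#' completed. Surveys on invalid days are excluded from matching.
#'
#' @param surveys survey table (`participant_id`, `date`, `completed`, ...)
#'   as produced by [simulate_ema_schedule()].
#' @param min_completed completed surveys required for a valid day.
#' @return data.frame per participant-day: `n_prompted`, `n_completed`,
#'   `valid`.
#' @export
validate_response_days <- function(surveys, min_completed = 2L) {
  stopifnot(all(c("participant_id", "date", "completed") %in% names(surveys)))
  key <- paste(surveys$participant_id, surveys$date, sep = "\r")
  n_prompted <- as.vector(rowsum(rep(1L, nrow(surveys)), key))
  if (any(n_prompted > 4L))
    stop("more than 4 surveys on a participant-day", call. = FALSE)
  n_completed <- as.vector(rowsum(as.integer(surveys$completed), key))
  ks <- sort(unique(key))
  data.frame(
    participant_id = sub("\r.*", "", ks),
    date = as.Date(sub(".*\r", "", ks)),
    n_prompted = n_prompted,
    n_completed = n_completed,
    valid = n_completed >= min_completed,
    stringsAsFactors = FALSE
  )
}

#' Build hour-resolution pre-period windows for one participant-day
#'
#' Each completed survey's window ends at the top of its completion hour
#' (a survey answered at 10:23 covers accelerometer time through 9:59).
#' The day's first completed survey starts at the first worn hour of the
#' day; each later one starts one hour after the top of the previous
#' completed survey's completion hour, so consecutive windows never share
#' a clock hour (no accelerometer minute is counted twice). A survey whose
#' window is empty (start >= end) yields no observation, but still anchors
#' the start of the next window.
#'
#' @param day_surveys completed surveys of one participant-day, any order.
#' @param first_worn_minute POSIXct of the day's first worn minute, or `NA`
#'   if the device was never worn that day.
#' @return `day_surveys` ordered by completion time with `window_start`
#'   and `window_end` columns (`NA` for empty windows).
#' @export
build_pre_period_windows <- function(day_surveys, first_worn_minute) {
  s <- day_surveys[day_surveys$completed, , drop = FALSE]
  s <- s[order(s$completion_time), , drop = FALSE]
  n <- nrow(s)
  s$window_start <- as.POSIXct(rep(NA_real_, n), tz = .tz,
                               origin = "1970-01-01")
  s$window_end <- s$window_start
  if (n == 0L) return(s)
  for (i in seq_len(n)) {
    end <- floor_hour(s$completion_time[i])
    start <- if (i == 1L) {
      if (is.na(first_worn_minute)) end  # forces an empty window
      else floor_hour(first_worn_minute)
    } else {
      floor_hour(s$completion_time[i - 1L]) + 3600
    }
    if (start < end) {
      s$window_start[i] <- start
      s$window_end[i] <- end
    }
  }
  s
}

#' Sum worn and class minutes inside a pre-period window
#'
#' @param window_start,window_end POSIXct bounds of the half-open window
#'   `[start, end)`.
#' @param series classified, wear-flagged `minute_series` of the same
#'   participant.
#' @return one-row data.frame `wear_min`, `st_min`, `lpa_min`, `mvpa_min`,
#'   or `NULL` when no worn minute falls in the window (observation
#'   dropped).
#' @export
match_accelerometer <- function(window_start, window_end, series) {
  inw <- series$minute >= window_start & series$minute < window_end &
    series$wear
  if (!any(inw)) return(NULL)
  cls <- series$class[inw]
  data.frame(wear_min = sum(inw),
             st_min = sum(cls == "ST"),
             lpa_min = sum(cls == "LPA"),
             mvpa_min = sum(cls == "MVPA"))
}

#' Standardize window minutes to minutes per worn hour
#'
#' Places unequal pre-periods on a common scale: each intensity outcome is
#' `60 * class_minutes / wear_minutes`, so the three outcomes always sum
#' to 60 when the classes partition worn time.
#'
#' @param st_min,lpa_min,mvpa_min class minutes in the window.
#' @param wear_min worn minutes in the window (> 0).
#' @return named numeric vector `st_mph`, `lpa_mph`, `mvpa_mph`.
#' @examples
#' standardize_outcomes(76, 40, 4, 120)
#' @export
standardize_outcomes <- function(st_min, lpa_min, mvpa_min, wear_min) {
  if (any(wear_min <= 0))
    stop("wear minutes must be positive (zero-wear windows are dropped ",
         "before standardization)", call. = FALSE)
  c(st_mph = 60 * st_min / wear_min,
    lpa_mph = 60 * lpa_min / wear_min,
    mvpa_mph = 60 * mvpa_min / wear_min)
}

#' Assemble the survey-level analysis table
#'
#' Joins every qualifying completed survey to its accelerometer
#' pre-period. A survey qualifies when its participant meets the wear-time
#' eligibility rule, its day is both a valid response day (>= 2 completed
#' surveys) and a valid wear day, its pre-period window is nonempty, and
#' the window contains at least one worn minute.
#'
#' @param surveys survey table including response columns `pa_response`
#'   and `sb_response` for completed surveys.
#' @param series classified, wear-flagged `minute_series` for all
#'   participants.
#' @param cohort covariate table from [simulate_cohort()] (or equivalent:
#'   `participant_id`, `sex`, `race_ethnicity`, `weight_status`, `income`,
#'   `season`, `age`).
#' @param criteria a [validity_criteria()].
#' @param min_completed completed surveys required for a valid response day.
#' @return the analysis table: one row per matched survey with exposures,
#'   weekend flag, wear minutes, the three minutes-per-hour outcomes, and
#'   covariates.
#' @export
assemble_analysis_table <- function(surveys, series, cohort,
                                    criteria = validity_criteria(),
                                    min_completed = 2L) {
  need <- c("participant_id", "sex", "race_ethnicity", "weight_status",
            "income", "season", "age")
  if (!all(need %in% names(cohort)))
    stop("cohort table lacks required covariate columns", call. = FALSE)
  if (nrow(surveys) == 0L) return(.empty_analysis_table())

  day_sum <- summarize_days(series)
  val <- filter_valid_participants(day_sum, criteria)
  valid_wear_days <- val$days[val$days$valid,
                              c("participant_id", "date"), drop = FALSE]
  resp <- validate_response_days(surveys, min_completed)
  valid_resp_days <- resp[resp$valid, c("participant_id", "date"),
                          drop = FALSE]
  keyify <- function(d) paste(d$participant_id, d$date)
  good_days <- intersect(keyify(valid_wear_days), keyify(valid_resp_days))

  surveys <- surveys[surveys$participant_id %in% val$eligible &
                       keyify(surveys) %in% good_days, , drop = FALSE]
  if (nrow(surveys) == 0L) return(.empty_analysis_table())

  missing_cov <- setdiff(unique(surveys$participant_id),
                         cohort$participant_id)
  if (length(missing_cov))
    stop("no covariates for participant(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)

  rows <- list()
  for (key in unique(keyify(surveys))) {
    day <- surveys[keyify(surveys) == key, , drop = FALSE]
    pid <- day$participant_id[1]
    ser <- series[series$participant_id == pid &
                    series$date == day$date[1], , drop = FALSE]
    worn_minutes <- ser$minute[ser$wear]
    first_worn <- if (length(worn_minutes)) min(worn_minutes)
                  else as.POSIXct(NA, tz = .tz)
    win <- build_pre_period_windows(day, first_worn)
    for (i in seq_len(nrow(win))) {
      if (is.na(win$window_start[i])) next
      m <- match_accelerometer(win$window_start[i], win$window_end[i], ser)
      if (is.null(m)) next
      mph <- standardize_outcomes(m$st_min, m$lpa_min, m$mvpa_min, m$wear_min)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid,
        date = win$date[i],
        survey_order = i,
        window_index = win$window_index[i],
        completion_time = win$completion_time[i],
        weekend = is_weekend(win$date[i]),
        pa_reported = win$pa_response[i],
        sb_reported = win$sb_response[i],
        wear_min = m$wear_min,
        st_mph = mph[["st_mph"]],
        lpa_mph = mph[["lpa_mph"]],
        mvpa_mph = mph[["mvpa_mph"]],
        window_start = win$window_start[i],
        window_end = win$window_end[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(.empty_analysis_table())
  tab <- do.call(rbind, rows)
  covs <- cohort[, need, drop = FALSE]
  out <- merge(tab, covs, by = "participant_id", sort = FALSE)
  if (anyNA(out[, c("pa_reported", "sb_reported")]))
    stop("completed surveys must carry pa/sb responses", call. = FALSE)
  out[order(out$participant_id, out$completion_time), , drop = FALSE]
}

.empty_analysis_table <- function() {
  data.frame(participant_id = character(0), date = as.Date(character(0)),
             survey_order = integer(0), window_index = integer(0),
             completion_time = as.POSIXct(character(0), tz = .tz),
             weekend = logical(0), pa_reported = integer(0),
             sb_reported = integer(0), wear_min = integer(0),
             st_mph = numeric(0), lpa_mph = numeric(0),
             mvpa_mph = numeric(0),
             window_start = as.POSIXct(character(0), tz = .tz),
             window_end = as.POSIXct(character(0), tz = .tz),
             sex = character(0), race_ethnicity = character(0),
             weight_status = character(0), income = character(0),
             season = character(0), age = numeric(0))
}
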