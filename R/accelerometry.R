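# Epoch reintegration, cutpoint classification, nonwear detection and
# wear-time validity filtering.

#' Evenson child cutpoints
#'
#' Counts-per-minute thresholds separating sedentary time (0-100), light
#' physical activity (101-2295) and moderate-to-vigorous physical activity
#' (>= 2296) in children.
#'
#' @param st_max upper bound (inclusive) of the sedentary band.
#' @param lpa_max upper bound (inclusive) of the light band.
#' @param name label carried for provenance.
#' @return an object of class `cutpoint_set`.
#' @examples
#' evenson_cutpoints()
#' @export
evenson_cutpoints <- function(st_max = 100L, lpa_max = 2295L,
                              name = "Evenson (children)") {
  if (!(0 <= st_max && st_max < lpa_max))
    stop("cutpoints must satisfy 0 <= st_max < lpa_max", call. = FALSE)
  structure(list(st_max = as.integer(st_max), lpa_max = as.integer(lpa_max),
                 name = name),
            class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat(sprintf("<cutpoint_set> %s: ST <= %d, LPA %d-%d, MVPA >= %d cpm\n",
              x$name, x$st_max, x$st_max + 1, x$lpa_max, x$lpa_max + 1))
  invisible(x)
}

#' Wear-time validity criteria
#'
#' A day is valid when it has at least `min_hours_per_day` worn hours; a
#' participant is eligible when they have at least `min_days` valid days
#' including at least `min_weekdays` weekdays and `min_weekend_days`
#' weekend days. Nonwear is any run of strictly more than
#' `nonwear_run_minutes` consecutive zero-count minutes. Defaults are the
#' 4-day / 3-weekday / 1-weekend-day / 4-hour rule with the 60-minute
#' nonwear run; set `min_hours_per_day = 8` for the stricter sensitivity
#' criterion.
#'
#' @param min_days,min_weekdays,min_weekend_days day-count requirements.
#' @param min_hours_per_day minimum worn hours for a valid day.
#' @param nonwear_run_minutes zero-run length that must be exceeded for
#'   nonwear (strictly greater-than).
#' @return an object of class `validity_criteria`.
#' @examples
#' validity_criteria()
#' validity_criteria(min_hours_per_day = 8)
#' @export
validity_criteria <- function(min_days = 4L, min_weekdays = 3L,
                              min_weekend_days = 1L, min_hours_per_day = 4,
                              nonwear_run_minutes = 60L) {
  vals <- c(min_days, min_weekdays, min_weekend_days, min_hours_per_day,
            nonwear_run_minutes)
  if (any(vals <= 0)) stop("all criteria must be positive", call. = FALSE)
  if (min_weekdays + min_weekend_days > min_days)
    stop("min_weekdays + min_weekend_days must not exceed min_days",
         call. = FALSE)
  structure(list(min_days = as.integer(min_days),
                 min_weekdays = as.integer(min_weekdays),
                 min_weekend_days = as.integer(min_weekend_days),
                 min_hours_per_day = min_hours_per_day,
                 nonwear_run_minutes = as.integer(nonwear_run_minutes)),
            class = "validity_criteria")
}

#' Reintegrate 15-second epochs to counts per minute
#'
#' Sums each clock minute's four epochs. Partial minutes at the stream
#' edges are dropped; a duplicated or missing epoch in the interior of the
#' record is a data-integrity error (device exports are gap-free within a
#' recording block; only multi-hour gaps, e.g. overnight, are allowed and
#' treated as block boundaries).
#'
#' @param stream an `epoch_stream` or data.frame with `timestamp`
#'   (POSIXct, 15-s grid) and `counts`.
#' @param participant_id identifier; defaults to the stream attribute.
#' @return a `minute_series` data.frame: `participant_id`, `minute`
#'   (POSIXct), `date`, `counts`. Wear flags and intensity classes are
#'   added by [detect_nonwear()] and [classify_minutes()].
#' @examples
#' st <- simulate_activity_stream("P001", as.Date("2017-05-01"), 1,
#'                                activity_params(), seed = 1)
#' ms <- aggregate_epochs_to_minutes(st)
#' head(ms)
#' @export
aggregate_epochs_to_minutes <- function(stream,
                                        participant_id =
                                          attr(stream, "participant_id")) {
  stopifnot(is.data.frame(stream), all(c("timestamp", "counts") %in%
                                         names(stream)))
  if (any(stream$counts < 0)) stop("negative epoch counts", call. = FALSE)
  ts <- stream$timestamp
  d <- as.numeric(diff(ts), units = "secs")
  if (any(d <= 0)) stop("duplicated or non-increasing epochs", call. = FALSE)
  # gaps must be whole multiples of 15 s; a short interior gap (< 1 h)
  # means missing epochs
  if (any(d %% 15 != 0)) stop("timestamps are off the 15-s grid",
                              call. = FALSE)
  if (any(d > 15 & d < 3600))
    stop("missing interior epochs detected", call. = FALSE)
  minute <- floor_minute(ts)
  n_per <- table(minute)
  keep <- names(n_per)[n_per == 4L]
  if (any(n_per > 4L)) stop("more than four epochs in a minute",
                            call. = FALSE)
  sums <- rowsum(stream$counts, group = as.character(minute))
  sums <- sums[rownames(sums) %in% keep, , drop = FALSE]
  minute_out <- as.POSIXct(rownames(sums), tz = .tz)
  o <- order(minute_out)
  out <- data.frame(
    participant_id = participant_id %||% NA_character_,
    minute = minute_out[o],
    date = as.Date(minute_out[o], tz = .tz),
    counts = as.integer(sums[o, 1]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("minute_series", "data.frame")
  out
}

#' Classify counts per minute into intensity classes
#'
#' Total deterministic partition of nonnegative counts: `ST` for
#' `cpm <= st_max`, `LPA` for `st_max < cpm <= lpa_max`, `MVPA` above.
#' Boundaries are inclusive as the cutpoints are printed (100 is ST, 101
#' and 2295 are LPA, 2296 is MVPA).
#'
#' @param cpm nonnegative counts-per-minute vector.
#' @param cutpoints a [evenson_cutpoints()].
#' @return character vector over `"ST"`, `"LPA"`, `"MVPA"`.
#' @examples
#' classify_intensity(c(0, 100, 101, 2295, 2296))
#' @export
classify_intensity <- function(cpm, cutpoints = evenson_cutpoints()) {
  stopifnot(inherits(cutpoints, "cutpoint_set"))
  if (any(cpm < 0, na.rm = TRUE))
    stop("counts per minute must be nonnegative", call. = FALSE)
  out <- rep(NA_character_, length(cpm))
  out[cpm <= cutpoints$st_max] <- "ST"
  out[cpm > cutpoints$st_max & cpm <= cutpoints$lpa_max] <- "LPA"
  out[cpm > cutpoints$lpa_max] <- "MVPA"
  out
}

#' Flag nonwear minutes
#'
#' Marks every maximal run of zero-count minutes longer than
#' `criteria$nonwear_run_minutes` (strictly: a 60-minute run is worn, a
#' 61-minute run is nonwear under the default) as off-body. Runs are
#' evaluated within a participant-day; a run spanning midnight is split at
#' the day boundary first, because days are the analysis unit. The flag is
#' idempotent: re-running on an already-flagged series changes nothing.
#'
#' @param series a `minute_series` from [aggregate_epochs_to_minutes()].
#' @param criteria a [validity_criteria()].
#' @return the series with a logical `wear` column.
#' @export
detect_nonwear <- function(series, criteria = validity_criteria()) {
  stopifnot(is.data.frame(series),
            all(c("participant_id", "date", "counts") %in% names(series)))
  run_max <- criteria$nonwear_run_minutes
  key <- paste(series$participant_id, series$date)
  wear <- rep(TRUE, nrow(series))
  for (idx in split(seq_len(nrow(series)), key)) {
    z <- series$counts[idx] == 0L
    r <- rle(z)
    flag <- rep(r$values & r$lengths > run_max, r$lengths)
    wear[idx][flag] <- FALSE
  }
  series$wear <- wear
  series
}

#' Attach intensity classes to worn minutes
#'
#' @param series a `minute_series` with wear flags.
#' @param cutpoints a [evenson_cutpoints()].
#' @return the series with a `class` column (`NA` for nonwear minutes).
#' @export
classify_minutes <- function(series, cutpoints = evenson_cutpoints()) {
  stopifnot("wear" %in% names(series))
  cls <- classify_intensity(series$counts, cutpoints)
  cls[!series$wear] <- NA_character_
  series$class <- cls
  series
}

#' Per-day wear and intensity summaries
#'
#' @param series a classified, wear-flagged `minute_series`.
#' @return data.frame per participant-day: `wear_hours`, `st_min`,
#'   `lpa_min`, `mvpa_min`, `weekend`. Class minutes partition worn
#'   minutes exactly.
#' @export
summarize_days <- function(series) {
  stopifnot(all(c("wear", "class") %in% names(series)))
  key <- paste(series$participant_id, series$date, sep = "\r")
  agg <- function(x) as.vector(rowsum(as.numeric(x), key))  # sorted by key
  worn <- agg(series$wear)
  ks <- sort(unique(key))
  out <- data.frame(
    participant_id = sub("\r.*", "", ks),
    date = as.Date(sub(".*\r", "", ks)),
    wear_hours = worn / 60,
    st_min = agg(series$wear & series$class %in% "ST"),
    lpa_min = agg(series$wear & series$class %in% "LPA"),
    mvpa_min = agg(series$wear & series$class %in% "MVPA"),
    stringsAsFactors = FALSE
  )
  out$weekend <- is_weekend(out$date)
  out[order(out$participant_id, out$date), , drop = FALSE]
}

#' Apply wear-time validity criteria
#'
#' Flags each day as valid when its worn time reaches
#' `criteria$min_hours_per_day`, then keeps participants meeting the
#' day-count rule (>= `min_days` valid days of which >= `min_weekdays`
#' weekdays and >= `min_weekend_days` weekend days).
#'
#' @param day_summaries output of [summarize_days()].
#' @param criteria a [validity_criteria()].
#' @return list with `days` (the summaries plus a `valid` flag) and
#'   `eligible` (character vector of participant ids).
#' @export
filter_valid_participants <- function(day_summaries,
                                      criteria = validity_criteria()) {
  d <- day_summaries
  d$valid <- d$wear_hours >= criteria$min_hours_per_day
  ok <- vapply(split(d, d$participant_id), function(x) {
    v <- x$valid
    sum(v) >= criteria$min_days &&
      sum(v & !x$weekend) >= criteria$min_weekdays &&
      sum(v & x$weekend) >= criteria$min_weekend_days
  }, logical(1))
  list(days = d, eligible = names(ok)[ok])
}
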