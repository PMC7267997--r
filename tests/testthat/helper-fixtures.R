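# Small in-code fixtures shared across tests.

# minute series straight from a counts vector, one participant-day
make_minute_series <- function(counts, date = as.Date("2017-05-01"),
                               participant_id = "P001", start_hour = 7) {
  n <- length(counts)
  minute <- as.POSIXct(paste(date, sprintf("%02d:00:00", start_hour)),
                       tz = "UTC") + 60 * (seq_len(n) - 1)
  structure(
    data.frame(participant_id = participant_id, minute = minute,
               date = as.Date(minute, tz = "UTC"),
               counts = as.integer(counts), stringsAsFactors = FALSE),
    class = c("minute_series", "data.frame"))
}

# epoch stream from raw epoch counts on the 15-s grid
make_epoch_stream <- function(epochs, participant_id = "P001",
                              start = as.POSIXct("2017-05-01 07:00:00",
                                                 tz = "UTC")) {
  structure(
    data.frame(timestamp = start + 15 * (seq_along(epochs) - 1),
               counts = as.integer(epochs)),
    participant_id = participant_id,
    class = c("epoch_stream", "data.frame"))
}

# day summaries with prescribed wear hours over consecutive dates
make_day_summaries <- function(wear_hours,
                               start = as.Date("2017-05-01"),  # a Monday
                               participant_id = "P001") {
  dates <- start + seq_along(wear_hours) - 1
  data.frame(participant_id = participant_id, date = dates,
             wear_hours = wear_hours,
             st_min = wear_hours * 40, lpa_min = wear_hours * 17,
             mvpa_min = wear_hours * 3,
             weekend = emaccel::is_weekend(dates),
             stringsAsFactors = FALSE)
}

# a small but complete pipeline run, cached per test file
small_pipeline <- local({
  cache <- NULL
  function(n_dyads = 16, seed = 404) {
    if (is.null(cache)) {
      cfg <- pipeline_config(cohort = cohort_config(n_dyads = n_dyads,
                                                    seed = seed))
      cache <<- suppressMessages(run_pipeline(cfg))
    }
    cache
  }
})
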