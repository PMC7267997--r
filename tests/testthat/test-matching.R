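# Response-day validation, pre-period window construction, accelerometer
# matching and the analysis table.

.mk_surveys <- function(completion_hms, date = as.Date("2017-05-01"),
                        participant_id = "P001") {
  n <- length(completion_hms)
  ct <- as.POSIXct(paste(date, completion_hms), tz = "UTC")
  data.frame(participant_id = participant_id, date = date,
             window_index = seq_len(n), prompt_time = ct - 600,
             completed = !is.na(completion_hms), completion_time = ct,
             pa_response = rep(1L, n), sb_response = rep(0L, n),
             stringsAsFactors = FALSE)
}

test_that("a response day is valid with at least two completed surveys", {
  two <- .mk_surveys(c("08:00:00", "13:00:00", NA, NA))
  expect_true(validate_response_days(two)$valid)
  one <- .mk_surveys(c("08:00:00", NA, NA, NA))
  expect_false(validate_response_days(one)$valid)
  four <- .mk_surveys(c("08:00:00", "13:00:00", "16:00:00", "20:00:00"))
  expect_true(validate_response_days(four)$valid)
  five <- rbind(four, four[1, ])
  expect_error(validate_response_days(five), "more than 4")
})

test_that("windows end at the top of the completion hour", {
  sv <- .mk_surveys("10:23:00")
  w <- build_pre_period_windows(sv,
    first_worn_minute = as.POSIXct("2017-05-01 07:12:00", tz = "UTC"))
  expect_equal(w$window_end,
               as.POSIXct("2017-05-01 10:00:00", tz = "UTC"))
  expect_equal(w$window_start,
               as.POSIXct("2017-05-01 07:00:00", tz = "UTC"))
})

test_that("a later window starts one hour after the previous completion
           hour", {
  sv <- .mk_surveys(c("09:45:00", "13:10:00"))
  w <- build_pre_period_windows(sv,
    first_worn_minute = as.POSIXct("2017-05-01 07:00:00", tz = "UTC"))
  expect_equal(w$window_start[2],
               as.POSIXct("2017-05-01 10:00:00", tz = "UTC"))
  expect_equal(w$window_end[2],
               as.POSIXct("2017-05-01 13:00:00", tz = "UTC"))
})

test_that("same-hour or inverted windows are empty but still anchor the
           next one", {
  sv <- .mk_surveys(c("09:05:00", "09:45:00", "12:30:00"))
  w <- build_pre_period_windows(sv,
    first_worn_minute = as.POSIXct("2017-05-01 07:00:00", tz = "UTC"))
  expect_true(is.na(w$window_start[2]))  # same clock hour as previous
  # third window starts after the *second* survey's completion hour
  expect_equal(w$window_start[3],
               as.POSIXct("2017-05-01 10:00:00", tz = "UTC"))
  expect_equal(w$window_end[3],
               as.POSIXct("2017-05-01 12:00:00", tz = "UTC"))
})

test_that("windows within a day never overlap", {
  set.seed(61)
  for (r in 1:40) {
    hms <- sprintf("%02d:%02d:00", sort(sample(8:21, 4)), sample(0:59, 4))
    sv <- .mk_surveys(hms)
    w <- build_pre_period_windows(sv,
      first_worn_minute = as.POSIXct("2017-05-01 07:30:00", tz = "UTC"))
    done <- w[!is.na(w$window_start), ]
    if (nrow(done) > 1)
      for (i in 2:nrow(done))
        expect_gte(as.numeric(done$window_start[i]),
                   as.numeric(done$window_end[i - 1]))
  }
})

test_that("matching sums worn minutes only and drops empty windows", {
  # two hours: first worn with 76 ST minutes, second 44 ST + 14 LPA + 2 MVPA
  counts <- c(rep(10, 76), rep(500, 14), rep(3000, 2), rep(10, 28))
  ms <- classify_minutes(detect_nonwear(make_minute_series(counts)))
  res <- match_accelerometer(
    as.POSIXct("2017-05-01 07:00:00", tz = "UTC"),
    as.POSIXct("2017-05-01 09:00:00", tz = "UTC"), ms)
  expect_equal(res$wear_min, 120)
  expect_equal(res$st_min, 104)
  expect_equal(res$lpa_min, 14)
  expect_equal(res$mvpa_min, 2)

  ms$wear <- FALSE
  expect_null(match_accelerometer(
    as.POSIXct("2017-05-01 07:00:00", tz = "UTC"),
    as.POSIXct("2017-05-01 09:00:00", tz = "UTC"), ms))
})

test_that("window sums agree with a naive per-minute loop", {
  set.seed(72)
  counts <- as.integer(sample(c(0, 30, 800, 2500), 300, replace = TRUE))
  ms <- classify_minutes(detect_nonwear(make_minute_series(counts)))
  a <- as.POSIXct("2017-05-01 08:00:00", tz = "UTC")
  b <- as.POSIXct("2017-05-01 11:00:00", tz = "UTC")
  res <- match_accelerometer(a, b, ms)
  brute <- c(0, 0, 0, 0)
  for (i in seq_len(nrow(ms))) {
    if (ms$minute[i] >= a && ms$minute[i] < b && ms$wear[i]) {
      brute[1] <- brute[1] + 1
      brute[2] <- brute[2] + (ms$class[i] == "ST")
      brute[3] <- brute[3] + (ms$class[i] == "LPA")
      brute[4] <- brute[4] + (ms$class[i] == "MVPA")
    }
  }
  expect_equal(unlist(res), c(wear_min = brute[1], st_min = brute[2],
                              lpa_min = brute[3], mvpa_min = brute[4]))
})

test_that("standardization is minutes per worn hour and sums to 60", {
  out <- standardize_outcomes(76, 40, 4, 120)
  expect_equal(out[["st_mph"]], 38)
  expect_equal(sum(out), 60)
  all_st <- standardize_outcomes(90, 0, 0, 90)
  expect_equal(unname(all_st), c(60, 0, 0))
  expect_error(standardize_outcomes(10, 0, 0, 0), "positive")
})

test_that("the analysis table counts exactly the qualifying surveys", {
  res <- small_pipeline()
  tab <- res$analysis
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$st_mph >= 0 & tab$st_mph <= 60))
  expect_equal(tab$st_mph + tab$lpa_mph + tab$mvpa_mph,
               rep(60, nrow(tab)), tolerance = 1e-12)

  # independent recount: eligible participant, valid wear + response day,
  # nonempty window with worn minutes
  ds <- res$day_summaries
  good_wear <- paste(ds$participant_id, ds$date)[ds$valid]
  resp <- validate_response_days(res$surveys)
  good_resp <- paste(resp$participant_id, resp$date)[resp$valid]
  n_expected <- 0L
  sv <- res$surveys
  keys <- unique(paste(sv$participant_id, sv$date))
  for (key in keys) {
    rows <- sv[paste(sv$participant_id, sv$date) == key, ]
    pid <- rows$participant_id[1]
    if (!(pid %in% res$eligible)) next
    if (!(key %in% good_wear) || !(key %in% good_resp)) next
    ser <- res$minutes[res$minutes$participant_id == pid &
                         res$minutes$date == rows$date[1], ]
    worn <- ser$minute[ser$wear]
    fw <- if (length(worn)) min(worn) else as.POSIXct(NA)
    w <- build_pre_period_windows(rows, fw)
    for (i in seq_len(nrow(w))) {
      if (is.na(w$window_start[i])) next
      if (!is.null(match_accelerometer(w$window_start[i], w$window_end[i],
                                       ser)))
        n_expected <- n_expected + 1L
    }
  }
  expect_equal(nrow(tab), n_expected)
})

test_that("empty survey input yields an empty analysis table", {
  res <- small_pipeline()
  empty <- assemble_analysis_table(res$surveys[0, ], res$minutes,
                                   res$cohort)
  expect_equal(nrow(empty), 0)
})

test_that("a participant without covariates is a data-integrity error", {
  res <- small_pipeline()
  cohort_miss <- res$cohort[-1, ]
  expect_error(assemble_analysis_table(res$surveys, res$minutes,
                                       cohort_miss),
               "no covariates")
})

test_that("masking nonwear before matching equals matching then masking", {
  set.seed(83)
  counts <- as.integer(sample(c(0, 50, 1000), 240, replace = TRUE))
  counts[30:100] <- 0L  # a real nonwear block
  ms <- classify_minutes(detect_nonwear(make_minute_series(counts)))
  a <- as.POSIXct("2017-05-01 07:30:00", tz = "UTC")
  b <- as.POSIXct("2017-05-01 10:30:00", tz = "UTC")
  direct <- match_accelerometer(a, b, ms)
  pre_masked <- ms[ms$wear, ]
  masked <- match_accelerometer(a, b, pre_masked)
  expect_identical(direct, masked)
})
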