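# Generative model for child accelerometer data: a minute-level Markov
# chain over worn intensity states, overlaid off-body episodes, and
# count emission into the Evenson cutpoint bands, written out as four
# 15-second epochs per minute.

.states_worn <- c("sedentary", "light", "mvpa")

#' Activity ground-truth parameters
#'
#' Parameters of the synthetic accelerometer generator. A child's waking
#' day (`wake_hour` to `sleep_hour`) is a first-order Markov chain over
#' sedentary / light / MVPA minutes; each worn minute emits a
#' counts-per-minute value inside its state's cutpoint band, split into
#' four 15-second epochs. Device removals (off-body episodes) are overlaid
#' as blocks of zero counts.
#'
#' @param transition 3x3 row-stochastic matrix over
#'   (sedentary, light, mvpa), or a function(hour) returning such a matrix
#'   for time-of-day dependence.
#' @param sedentary_range,light_range integer cpm emission bounds; must lie
#'   inside the cutpoint bands (sedentary within 0-100, light within
#'   101-2295) or construction fails.
#' @param mvpa_min,mvpa_mean_excess MVPA emission: `mvpa_min` plus a
#'   geometric excess with the given mean. `mvpa_min` must be >= 2296.
#' @param nonwear_rate expected off-body episodes per day (Poisson).
#' @param nonwear_min_minutes,nonwear_mean_excess off-body episode duration:
#'   minimum plus geometric excess. The default minimum of 61 min makes
#'   every generated episode detectable by the >60-min zero-run rule.
#' @param wake_hour,sleep_hour simulated waking span (clock hours); the
#'   device records only within it.
#' @param emission_noise probability that a worn minute emits from a
#'   uniformly chosen wrong band (default 0: emission is band-faithful).
#' @param initial named probability vector over the worn states for the
#'   first minute of each day.
#' @return an object of class `activity_params`.
#' @examples
#' p <- activity_params()
#' rowSums(p$transition)
#' @export
activity_params <- function(transition = NULL,
                            sedentary_range = c(0L, 100L),
                            light_range = c(101L, 2295L),
                            mvpa_min = 2296L,
                            mvpa_mean_excess = 900,
                            nonwear_rate = 3.5,
                            nonwear_min_minutes = 61L,
                            nonwear_mean_excess = 130,
                            wake_hour = 7L,
                            sleep_hour = 22L,
                            emission_noise = 0,
                            initial = c(sedentary = 0.7, light = 0.25,
                                        mvpa = 0.05)) {
  if (is.null(transition)) {
    transition <- matrix(c(0.970, 0.026, 0.004,
                           0.055, 0.928, 0.017,
                           0.025, 0.145, 0.830),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(.states_worn, .states_worn))
  }
  check_tm <- function(m) {
    if (!is.matrix(m) || any(dim(m) != 3) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9))
      stop("transition must be a 3x3 row-stochastic matrix", call. = FALSE)
  }
  if (is.function(transition)) check_tm(transition(12)) else check_tm(transition)
  cp <- evenson_cutpoints()
  if (sedentary_range[1] < 0 || sedentary_range[2] > cp$st_max)
    stop("sedentary emission support must lie within [0, ", cp$st_max, "]",
         call. = FALSE)
  if (light_range[1] <= cp$st_max || light_range[2] > cp$lpa_max)
    stop("light emission support must lie within [", cp$st_max + 1, ", ",
         cp$lpa_max, "]", call. = FALSE)
  if (mvpa_min <= cp$lpa_max)
    stop("mvpa emission must start at or above ", cp$lpa_max + 1,
         call. = FALSE)
  check_prob_vector(initial, "initial state")
  stopifnot(wake_hour < sleep_hour, emission_noise >= 0, emission_noise <= 1,
            nonwear_rate >= 0, nonwear_min_minutes >= 1)
  structure(list(transition = transition,
                 sedentary_range = as.integer(sedentary_range),
                 light_range = as.integer(light_range),
                 mvpa_min = as.integer(mvpa_min),
                 mvpa_mean_excess = mvpa_mean_excess,
                 nonwear_rate = nonwear_rate,
                 nonwear_min_minutes = as.integer(nonwear_min_minutes),
                 nonwear_mean_excess = nonwear_mean_excess,
                 wake_hour = as.integer(wake_hour),
                 sleep_hour = as.integer(sleep_hour),
                 emission_noise = emission_noise,
                 initial = initial),
            class = "activity_params")
}

# simulate one day's minute states over the worn chain
.simulate_chain <- function(n_min, params, wake_hour) {
  tm_of <- if (is.function(params$transition)) params$transition
           else function(hour) params$transition
  s <- integer(n_min)
  s[1] <- sample.int(3, 1, prob = params$initial)
  # pre-draw uniforms, step through with the (possibly hourly) matrix
  u <- stats::runif(n_min)
  cur_hour <- -1L
  tm <- NULL
  for (i in 2:n_min) {
    h <- wake_hour + (i - 1) %/% 60
    if (h != cur_hour) { tm <- tm_of(h); cur_hour <- h }
    s[i] <- findInterval(u[i], cumsum(tm[s[i - 1], ]), left.open = TRUE) + 1L
  }
  s
}

# emit cpm for a vector of state indices (1 sed, 2 light, 3 mvpa)
.emit_cpm <- function(state, params) {
  n <- length(state)
  if (params$emission_noise > 0) {
    flip <- stats::runif(n) < params$emission_noise
    wrong <- vapply(state[flip], function(s)
      sample(setdiff(1:3, s), 1), integer(1))
    state[flip] <- wrong
  }
  cpm <- integer(n)
  i <- state == 1L
  cpm[i] <- sample(params$sedentary_range[1]:params$sedentary_range[2],
                   sum(i), replace = TRUE)
  i <- state == 2L
  cpm[i] <- sample(params$light_range[1]:params$light_range[2],
                   sum(i), replace = TRUE)
  i <- state == 3L
  cpm[i] <- params$mvpa_min +
    stats::rgeom(sum(i), 1 / (1 + params$mvpa_mean_excess))
  cpm
}

# split counts-per-minute into four 15-s epochs summing exactly to cpm,
# via sequential binomial thinning (vectorised over minutes)
.split_epochs <- function(cpm) {
  n <- length(cpm)
  e1 <- stats::rbinom(n, cpm, 1 / 4)
  e2 <- stats::rbinom(n, cpm - e1, 1 / 3)
  e3 <- stats::rbinom(n, cpm - e1 - e2, 1 / 2)
  e4 <- cpm - e1 - e2 - e3
  rbind(e1, e2, e3, e4)
}

#' Simulate an epoch-level accelerometer stream with ground truth
#'
#' Generates one child's device record over `study_days` consecutive days:
#' minute-level truth states from the Markov chain in `params`, off-body
#' episodes overlaid as zero-count blocks, and counts emitted inside each
#' state's cutpoint band, written as four 15-second epochs per minute on a
#' uniform grid.
#'
#' @param participant_id identifier carried on the stream.
#' @param start_date first study day (Date).
#' @param study_days number of consecutive days.
#' @param params an [activity_params()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [run_pipeline()], which seeds per dyad).
#' @return an `epoch_stream`: data.frame (`timestamp`, `counts`) at 15-s
#'   resolution, with attributes `participant_id` and `truth` (data.frame
#'   `minute`, `state` over off_body/sedentary/light/mvpa).
#' @examples
#' st <- simulate_activity_stream("P001", as.Date("2017-05-01"), 1,
#'                                activity_params(), seed = 7)
#' head(st)
#' head(activity_truth(st))
#' @export
simulate_activity_stream <- function(participant_id, start_date, study_days,
                                     params = activity_params(),
                                     seed = NULL) {
  stopifnot(inherits(params, "activity_params"), study_days >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  start_date <- as.Date(start_date)
  mins_per_day <- (params$sleep_hour - params$wake_hour) * 60L

  state_all <- integer(0)
  minute_all <- as.POSIXct(character(0), tz = .tz)
  for (d in seq_len(study_days)) {
    s <- .simulate_chain(mins_per_day, params, params$wake_hour)
    # overlay off-body episodes (state 0)
    n_ep <- stats::rpois(1, params$nonwear_rate)
    if (n_ep > 0) {
      for (k in seq_len(n_ep)) {
        dur <- params$nonwear_min_minutes +
          stats::rgeom(1, 1 / (1 + params$nonwear_mean_excess))
        # uniform over all placements overlapping the day, so removals can
        # span the day edges (e.g. device put on late after waking)
        at <- sample.int(mins_per_day + dur - 1L, 1) - dur + 1L
        idx <- max(1L, at):min(mins_per_day, at + dur - 1L)
        s[idx] <- 0L
      }
    }
    day0 <- as.POSIXct(paste(start_date + d - 1L,
                             sprintf("%02d:00:00", params$wake_hour)),
                       tz = .tz)
    minute_all <- c(minute_all, day0 + 60 * (seq_len(mins_per_day) - 1L))
    state_all <- c(state_all, s)
  }

  cpm <- integer(length(state_all))
  worn <- state_all > 0L
  cpm[worn] <- .emit_cpm(state_all[worn], params)
  ep <- .split_epochs(cpm)

  ts <- rep(minute_all, each = 4L) + rep(c(0, 15, 30, 45), length(minute_all))
  stream <- data.frame(timestamp = ts, counts = as.integer(ep))
  truth <- data.frame(
    minute = minute_all,
    state = c("off_body", .states_worn)[state_all + 1L],
    stringsAsFactors = FALSE
  )
  structure(stream, participant_id = participant_id, truth = truth,
            class = c("epoch_stream", "data.frame"))
}

#' Ground-truth minute states of a simulated stream
#'
#' @param stream an `epoch_stream` from [simulate_activity_stream()].
#' @return data.frame (`minute`, `state`), or `NULL` for real data.
#' @export
activity_truth <- function(stream) attr(stream, "truth")

#' @export
print.epoch_stream <- function(x, ...) {
  cat(sprintf("<epoch_stream> participant %s: %d epochs, %s to %s\n",
              attr(x, "participant_id") %||% "?", nrow(x),
              format(min(x$timestamp)), format(max(x$timestamp))))
  invisible(x)
}

#' Stationary distribution of a worn-state transition matrix
#'
#' Left eigenvector of the transition matrix with eigenvalue 1, normalised
#' to a probability vector. Used to predict long-run state occupancy of
#' the activity chain.
#'
#' @param transition a row-stochastic matrix.
#' @return named numeric probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(transition))
}
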