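# Signal-contingent EMA schedule simulation and the parent-report model.

# prompt windows (clock hours, [start, end)): 7-10 am, 12-2 pm, 3-6 pm,
# 7-10 pm
.default_ema_windows <- list(c(7, 10), c(12, 14), c(15, 18), c(19, 22))

#' Simulate one day's signal-contingent EMA schedule
#'
#' Four surveys are prompted at uniformly random times, one inside each of
#' the daily windows (7-10 am, 12-2 pm, 3-6 pm, 7-10 pm). Each prompt is
#' answered with probability `compliance`; a completed survey's response
#' time is uniform within the 60-minute link expiry. Responses themselves
#' (the parent's yes/no items) are attached later by
#' [simulate_parent_reports()].
#'
#' @param participant_id identifier.
#' @param date the study day (Date).
#' @param compliance per-prompt completion probability.
#' @param windows list of `c(start_hour, end_hour)` prompt windows.
#' @param expiry_minutes survey link lifetime after the prompt.
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @return data.frame with one row per prompt: `participant_id`, `date`,
#'   `window_index`, `prompt_time`, `completed`, `completion_time` (`NA`
#'   when missed).
#' @examples
#' simulate_ema_schedule("P001", as.Date("2017-05-01"), seed = 3)
#' @export
simulate_ema_schedule <- function(participant_id, date,
                                  compliance = 0.83,
                                  windows = .default_ema_windows,
                                  expiry_minutes = 60,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(compliance >= 0, compliance <= 1)
  date <- as.Date(date)
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = .tz)
  k <- length(windows)
  prompt <- vapply(windows, function(w)
    stats::runif(1, w[1] * 3600, w[2] * 3600), numeric(1))
  completed <- stats::runif(k) < compliance
  delay <- stats::runif(k, 0, expiry_minutes * 60)
  completion <- ifelse(completed, prompt + delay, NA_real_)
  data.frame(
    participant_id = participant_id,
    date = date,
    window_index = seq_len(k),
    prompt_time = day0 + prompt,
    completed = completed,
    completion_time = day0 + completion,
    stringsAsFactors = FALSE
  )
}

#' Parent-report model parameters
#'
#' The parent's yes/no report of the child's physical activity (PA) and
#' screen-based sedentary behavior (SB) is modelled as an imperfect
#' classifier of a latent true state: report = 1 with probability
#' `sensitivity` when the true state is 1, and 0 with probability
#' `specificity` when it is 0. The true state is 1 when the child
#' accumulated more than `*_threshold_min` minutes of the relevant
#' behavior (LPA+MVPA for PA; sedentary time as a screen-time proxy for
#' SB) in the recall window. `modifier_*` entries shift both accuracy
#' probabilities additively on the log-odds scale, e.g. a positive
#' `modifier_weekend` makes weekend reports more accurate (a parent at
#' home observes the child more directly).
#'
#' @param pa_sensitivity,pa_specificity,sb_sensitivity,sb_specificity
#'   accuracy probabilities in \[0, 1\].
#' @param pa_threshold_min,sb_threshold_min minutes of true behavior in the
#'   recall window above which (strictly) the true binary state is 1.
#' @param modifier_weekend,modifier_boy,modifier_summer log-odds shifts of
#'   both sensitivity and specificity.
#' @return an object of class `reporting_params`.
#' @export
reporting_params <- function(pa_sensitivity = 0.85, pa_specificity = 0.75,
                             sb_sensitivity = 0.80, sb_specificity = 0.70,
                             pa_threshold_min = 30, sb_threshold_min = 60,
                             modifier_weekend = 0.9,
                             modifier_boy = 0,
                             modifier_summer = 0) {
  probs <- c(pa_sensitivity, pa_specificity, sb_sensitivity, sb_specificity)
  if (any(probs < 0 | probs > 1))
    stop("sensitivities/specificities must be probabilities in [0, 1]",
         call. = FALSE)
  structure(list(pa_sensitivity = pa_sensitivity,
                 pa_specificity = pa_specificity,
                 sb_sensitivity = sb_sensitivity,
                 sb_specificity = sb_specificity,
                 pa_threshold_min = pa_threshold_min,
                 sb_threshold_min = sb_threshold_min,
                 modifier_weekend = modifier_weekend,
                 modifier_boy = modifier_boy,
                 modifier_summer = modifier_summer),
            class = "reporting_params")
}

.shift_prob <- function(p, shift) {
  if (all(shift == 0)) return(rep_len(p, length(shift)))
  stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + shift)
}

#' Simulate parent EMA responses given ground truth
#'
#' Draws the yes/no PA and SB responses for a set of completed surveys
#' from the sensitivity/specificity model in [reporting_params()],
#' vectorised over surveys.
#'
#' @param active_min minutes of true LPA+MVPA in each survey's recall
#'   window.
#' @param sedentary_min minutes of true sedentary time in each recall
#'   window.
#' @param params a [reporting_params()].
#' @param weekend,boy,summer logical vectors (recycled) switching the
#'   corresponding log-odds accuracy modifiers on.
#' @param seed optional integer seed.
#' @return data.frame (`pa_true`, `sb_true`, `pa_response`, `sb_response`),
#'   responses as 0/1 integers.
#' @examples
#' simulate_parent_reports(active_min = c(0, 45), sedentary_min = c(50, 5),
#'                         params = reporting_params(), seed = 1)
#' @export
simulate_parent_reports <- function(active_min, sedentary_min,
                                    params = reporting_params(),
                                    weekend = FALSE, boy = FALSE,
                                    summer = FALSE, seed = NULL) {
  stopifnot(inherits(params, "reporting_params"),
            length(active_min) == length(sedentary_min))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(active_min)
  shift <- params$modifier_weekend * rep_len(as.numeric(weekend), n) +
    params$modifier_boy * rep_len(as.numeric(boy), n) +
    params$modifier_summer * rep_len(as.numeric(summer), n)

  pa_true <- as.integer(active_min > params$pa_threshold_min)
  sb_true <- as.integer(sedentary_min > params$sb_threshold_min)

  draw <- function(truth, sens, spec) {
    p_yes <- ifelse(truth == 1L, .shift_prob(sens, shift),
                    1 - .shift_prob(spec, shift))
    as.integer(stats::runif(n) < p_yes)
  }
  data.frame(pa_true = pa_true, sb_true = sb_true,
             pa_response = draw(pa_true, params$pa_sensitivity,
                                params$pa_specificity),
             sb_response = draw(sb_true, params$sb_sensitivity,
                                params$sb_specificity))
}
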