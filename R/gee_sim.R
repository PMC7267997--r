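# Semi-synthetic clustered outcomes: a dyad/day/survey design with
# outcomes drawn from a known linear model plus participant-level random
# effects, for estimator calibration (parameter recovery, type-I error).

#' Simulate clustered survey outcomes from a known linear model
#'
#' Builds a study-shaped design -- `n_dyads` participants observed over
#' `study_days` consecutive days starting on random weekdays, with 2-4
#' completed surveys per day and a Bernoulli(1/2) dummy exposure per
#' survey -- and draws each outcome from
#' \deqn{y = \beta_0 + \beta_e \cdot exposure + \beta_w \cdot weekend +
#'       \beta_{ew} \cdot exposure \cdot weekend + b_i + \epsilon,}
#' with participant random effects `b_i ~ N(0, sd_cluster^2)` and residual
#' noise `N(0, sd_resid^2)`. Because the generating coefficients are
#' known, the marginal-model estimator can be checked for bias and its
#' interaction test for size.
#'
#' @param n_dyads number of participants (clusters).
#' @param study_days days per participant.
#' @param beta named vector `c(intercept, exposure, weekend,
#'   exposure_weekend)` of true coefficients (minutes-per-hour scale).
#' @param sd_cluster,sd_resid random-effect and residual SDs (min/hr).
#' @param surveys_per_day range of completed surveys per day (inclusive).
#' @param seed optional integer seed.
#' @return data.frame `participant_id`, `day`, `weekend`, `exposure`, `y`.
#' @examples
#' d <- simulate_clustered_outcomes(10, 4, seed = 1)
#' head(d)
#' @export
simulate_clustered_outcomes <- function(n_dyads = 140, study_days = 8,
                                        beta = c(intercept = 35,
                                                 exposure = -4,
                                                 weekend = 1,
                                                 exposure_weekend = -2),
                                        sd_cluster = 4, sd_resid = 9,
                                        surveys_per_day = c(2L, 4L),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(n_dyads >= 2, study_days >= 1, length(beta) == 4)
  start_dow <- sample.int(7, n_dyads, replace = TRUE)  # 1 = Monday
  b <- stats::rnorm(n_dyads, 0, sd_cluster)
  rows <- vector("list", n_dyads)
  for (i in seq_len(n_dyads)) {
    dow <- ((start_dow[i] + seq_len(study_days) - 2L) %% 7L) + 1L
    weekend_day <- dow >= 6L
    k <- sample(seq(surveys_per_day[1], surveys_per_day[2]),
                study_days, replace = TRUE)
    day <- rep(seq_len(study_days), k)
    weekend <- rep(weekend_day, k)
    n_i <- length(day)
    exposure <- stats::rbinom(n_i, 1, 0.5)
    mu <- beta[[1]] + beta[[2]] * exposure + beta[[3]] * weekend +
      beta[[4]] * exposure * weekend
    rows[[i]] <- data.frame(
      participant_id = sprintf("P%03d", i),
      day = day, weekend = weekend, exposure = exposure,
      y = mu + b[i] + stats::rnorm(n_i, 0, sd_resid),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Fit the exposure-by-weekend model to simulated clustered outcomes
#'
#' Helper around [fit_gee_independence()] for data from
#' [simulate_clustered_outcomes()]: fits
#' `y ~ exposure * weekend` with participant clusters.
#'
#' @param data output of [simulate_clustered_outcomes()].
#' @param df_correction see [fit_gee_independence()].
#' @return a `gee_fit`; coefficients are named `(Intercept)`, `exposure`,
#'   `weekendTRUE`, `exposure:weekendTRUE`.
#' @export
fit_clustered_outcomes <- function(data, df_correction = FALSE) {
  X <- cbind("(Intercept)" = 1, exposure = data$exposure,
             weekendTRUE = as.numeric(data$weekend),
             "exposure:weekendTRUE" = data$exposure * as.numeric(data$weekend))
  fit <- fit_gee_independence(data$y, X, data$participant_id, df_correction)
  fit$spec <- design_spec("st_mph", "pa_reported", modifier = "weekend")
  fit$spec$exposure <- "exposure"
  fit$spec$modifier <- "weekend"
  fit$modifier_levels <- c("FALSE", "TRUE")
  fit
}
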