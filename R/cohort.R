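# Dyad cohort simulation: covariate profiles for parent-child pairs.

#' Cohort simulation settings
#'
#' Describes a cohort of parent-child dyads to simulate: its size, the
#' number of consecutive observation days, and the categorical covariate
#' distributions. Defaults reproduce the composition of a diverse urban
#' sample of 5-7-year-olds: six racial/ethnic groups, roughly even sex
#' split, about half the children overweight, and a predominantly
#' low-income sample observed over 8 days.
#'
#' @param n_dyads number of parent-child dyads (>= 1).
#' @param study_days consecutive observation days per dyad.
#' @param seed integer seed; the whole cohort (including every dyad's
#'   activity stream and survey schedule downstream) is reproducible from it.
#' @param sex,race_ethnicity,weight_status,income,season named probability
#'   vectors over category labels; each must sum to 1.
#' @param age_mean,age_sd child age distribution in years (normal, truncated
#'   to 4-9).
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_dyads = 10, seed = 1)
#' cfg$n_dyads
#' @export
cohort_config <- function(n_dyads = 140,
                          study_days = 8,
                          seed = 1,
                          sex = c(girl = 66 / 140, boy = 74 / 140),
                          race_ethnicity = c(african_american = 21 / 140,
                                             american_indian = 24 / 140,
                                             hispanic_latino = 25 / 140,
                                             hmong = 24 / 140,
                                             somali = 22 / 140,
                                             white = 24 / 140),
                          weight_status = c(normal = 73 / 140,
                                            overweight = 67 / 140),
                          income = c(low = 0.70, higher = 0.30),
                          season = c(school_year = 0.75, summer = 0.25),
                          age_mean = 6.4,
                          age_sd = 0.8) {
  if (!is.numeric(n_dyads) || n_dyads < 1 || n_dyads != round(n_dyads))
    stop("n_dyads must be a positive integer", call. = FALSE)
  if (!is.numeric(study_days) || study_days < 1)
    stop("study_days must be a positive integer", call. = FALSE)
  covs <- list(sex = sex, race_ethnicity = race_ethnicity,
               weight_status = weight_status, income = income,
               season = season)
  for (nm in names(covs)) check_prob_vector(covs[[nm]], nm)
  structure(list(n_dyads = as.integer(n_dyads),
                 study_days = as.integer(study_days),
                 seed = as.integer(seed),
                 covariates = covs,
                 age_mean = age_mean, age_sd = age_sd),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d dyads x %d days, seed %d\n",
              x$n_dyads, x$study_days, x$seed))
  invisible(x)
}

# draw a study start date consistent with the dyad's season label;
# windows keep the whole 8-day block inside one season
.sample_start_date <- function(season, n) {
  summer <- seq(as.Date("2017-06-05"), as.Date("2017-08-10"), by = "day")
  school <- c(seq(as.Date("2017-01-09"), as.Date("2017-05-15"), by = "day"),
              seq(as.Date("2017-09-11"), as.Date("2017-12-01"), by = "day"))
  out <- as.Date(rep(NA, n))
  is_sum <- season == "summer"
  out[is_sum] <- sample(summer, sum(is_sum), replace = TRUE)
  out[!is_sum] <- sample(school, sum(!is_sum), replace = TRUE)
  out
}

#' Simulate a dyad cohort
#'
#' Draws one covariate profile per dyad from the distributions in the
#' config, plus a study start date consistent with the dyad's season (so
#' each dyad's observation block has its own weekday/weekend calendar).
#'
#' @param config a [cohort_config()].
#' @return a data.frame with one row per dyad: `participant_id`, `sex`,
#'   `race_ethnicity`, `weight_status`, `income`, `season`, `age`,
#'   `start_date`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_dyads = 5, seed = 42))
#' cohort$sex
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_dyads
  draw <- function(p) names(p)[sample.int(length(p), n, replace = TRUE,
                                          prob = p)]
  season <- draw(config$covariates$season)
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 4), 9)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    sex = draw(config$covariates$sex),
    race_ethnicity = draw(config$covariates$race_ethnicity),
    weight_status = draw(config$covariates$weight_status),
    income = draw(config$covariates$income),
    season = season,
    age = round(age, 1),
    start_date = .sample_start_date(season, n),
    stringsAsFactors = FALSE
  )
}
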