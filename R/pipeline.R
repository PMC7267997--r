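# Orchestration: simulate -> process -> match -> fit -> report, from one
# config, with per-stage record counts and deterministic outputs.

#' Pipeline configuration
#'
#' Bundles every stage's settings. Defaults reproduce the study design:
#' 140 dyads over 8 days, four signal-contingent surveys per day with
#' per-prompt compliance 0.83, the 4-day/3-weekday/1-weekend/4-hour
#' validity rule, and the six moderation models (PA and SB exposure by
#' weekend modifier on the three intensity outcomes), plus sex- and
#' season-modified variants.
#'
#' @param cohort a [cohort_config()].
#' @param activity an [activity_params()].
#' @param reporting a [reporting_params()].
#' @param criteria a [validity_criteria()].
#' @param compliance per-prompt survey completion probability.
#' @param designs list of [design_spec()]s to fit.
#' @param min_completed completed surveys needed for a valid response day.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            activity = activity_params(),
                            reporting = reporting_params(),
                            criteria = validity_criteria(),
                            compliance = 0.83,
                            designs = default_design_specs(),
                            min_completed = 2L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(activity, "activity_params"),
            inherits(reporting, "reporting_params"),
            inherits(criteria, "validity_criteria"),
            compliance >= 0, compliance <= 1)
  structure(list(cohort = cohort, activity = activity,
                 reporting = reporting, criteria = criteria,
                 compliance = compliance, designs = designs,
                 min_completed = as.integer(min_completed)),
            class = "pipeline_config")
}

#' The default moderation model set
#'
#' Both exposures (parent-reported PA, parent-reported SB) on all three
#' outcomes, each moderated by day-of-week (weekend); the analogous sex-
#' and season-moderated models can be added with `modifiers`.
#'
#' @param modifiers modifiers to cross with every exposure/outcome pair.
#' @return list of [design_spec()]s.
#' @export
default_design_specs <- function(modifiers = "weekend") {
  specs <- list()
  for (m in modifiers)
    for (ex in c("pa_reported", "sb_reported"))
      for (out in c("st_mph", "lpa_mph", "mvpa_mph"))
        specs[[length(specs) + 1]] <- design_spec(out, ex, modifier = m)
  specs
}

#' Run the full synthetic study pipeline
#'
#' Simulates the cohort, each child's accelerometer stream and each
#' parent's EMA schedule and responses; processes epochs to classified,
#' wear-flagged minutes; applies validity filtering; matches completed
#' surveys to hour-resolution pre-periods; and fits the configured
#' moderation models. Stage-level record counts are logged via
#' `message()` so attrition is auditable. Deterministic given
#' `config$cohort$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all artifacts (CSV
#'   tables, JSON results, a manifest) are written there.
#' @param write_epochs also write per-participant epoch-level CSVs
#'   (voluminous; off by default).
#' @return invisibly, a list: `cohort`, `minutes`, `day_summaries`,
#'   `eligible`, `surveys`, `analysis`, `fits`, `compliance`, `table1`,
#'   `moderation`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         write_epochs = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cc <- config$cohort
  cohort <- simulate_cohort(cc)
  message(sprintf("[simulate] cohort: %d dyads x %d days",
                  nrow(cohort), cc$study_days))
  seeds <- derive_seeds(cc$seed, nrow(cohort))

  minutes_list <- vector("list", nrow(cohort))
  surveys_list <- vector("list", nrow(cohort))
  streams <- if (write_epochs) vector("list", nrow(cohort)) else NULL

  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$participant_id[i]
    set.seed(seeds[i])
    stream <- simulate_activity_stream(pid, cohort$start_date[i],
                                       cc$study_days, config$activity)
    truth <- activity_truth(stream)
    ms <- aggregate_epochs_to_minutes(stream)
    ms <- detect_nonwear(ms, config$criteria)
    ms <- classify_minutes(ms)
    minutes_list[[i]] <- ms
    if (write_epochs) streams[[i]] <- stream

    days <- sort(unique(as.Date(truth$minute, tz = .tz)))
    sv <- do.call(rbind, lapply(days, function(d)
      simulate_ema_schedule(pid, d, config$compliance)))
    sv <- .attach_reports(sv, truth, config$reporting,
                          boy = cohort$sex[i] == "boy",
                          summer = cohort$season[i] == "summer",
                          wake_hour = config$activity$wake_hour)
    surveys_list[[i]] <- sv
  }
  minutes <- do.call(rbind, minutes_list)
  surveys <- do.call(rbind, surveys_list)
  message(sprintf("[process-accel] %d minutes (%d worn)",
                  nrow(minutes), sum(minutes$wear)))
  message(sprintf("[ema] %d prompts, %d completed",
                  nrow(surveys), sum(surveys$completed)))

  day_summaries <- summarize_days(minutes)
  val <- filter_valid_participants(day_summaries, config$criteria)
  message(sprintf("[validity] %d of %d participants eligible; %d valid days",
                  length(val$eligible), nrow(cohort), sum(val$days$valid)))

  analysis <- assemble_analysis_table(surveys, minutes, cohort,
                                      config$criteria, config$min_completed)
  message(sprintf("[match] %d matched observations on %d days",
                  nrow(analysis),
                  nrow(unique(analysis[, c("participant_id", "date")]))))

  fits <- lapply(config$designs, function(sp) {
    fit <- fit_model(analysis, sp)
    list(spec = sp, fit = fit,
         interaction = if (!is.null(sp$modifier)) interaction_wald(fit),
         strata = if (!is.null(sp$modifier)) stratum_estimates(fit))
  })
  message(sprintf("[fit] %d models", length(fits)))

  compliance <- compliance_report(surveys, val$days, analysis)
  table1 <- descriptive_table1(analysis)
  moderation <- moderation_report(fits)

  res <- list(cohort = cohort, minutes = minutes,
              day_summaries = val$days, eligible = val$eligible,
              surveys = surveys, analysis = analysis, fits = fits,
              compliance = compliance, table1 = table1,
              moderation = moderation)
  if (!is.null(out_dir)) .write_pipeline_artifacts(res, config, out_dir,
                                                   streams)
  invisible(res)
}

# compute truth minutes in each completed survey's recall window (previous
# completed survey, else waking, through completion) and draw responses
.attach_reports <- function(surveys, truth, reporting, boy, summer,
                            wake_hour) {
  surveys$pa_response <- NA_integer_
  surveys$sb_response <- NA_integer_
  truth_min <- truth$minute
  for (d in as.character(unique(surveys$date))) {
    di <- which(surveys$date == as.Date(d) & surveys$completed)
    if (!length(di)) next
    di <- di[order(surveys$completion_time[di])]
    day0 <- as.POSIXct(paste(d, sprintf("%02d:00:00", wake_hour)), tz = .tz)
    prev <- day0
    for (j in di) {
      upto <- surveys$completion_time[j]
      inw <- truth_min >= prev & truth_min < upto
      st <- truth$state[inw]
      rep_j <- simulate_parent_reports(
        active_min = sum(st %in% c("light", "mvpa")),
        sedentary_min = sum(st == "sedentary"),
        params = reporting,
        weekend = is_weekend(d), boy = boy, summer = summer)
      surveys$pa_response[j] <- rep_j$pa_response
      surveys$sb_response[j] <- rep_j$sb_response
      prev <- upto
    }
  }
  surveys
}

.write_pipeline_artifacts <- function(res, config, out_dir, streams) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$cohort, "covariates.csv")
  wcsv(res$minutes, "minutes.csv")
  wcsv(res$day_summaries, "day_summaries.csv")
  wcsv(res$surveys, "surveys.csv")
  wcsv(res$analysis, "analysis_table.csv")
  wcsv(res$moderation$terms, "results.csv")
  wcsv(res$table1, "table1.csv")
  if (!is.null(streams)) {
    dir.create(file.path(out_dir, "epochs"), showWarnings = FALSE)
    for (s in streams)
      write_actigraph_csv(s, file.path(out_dir, "epochs",
        paste0(attr(s, "participant_id"), ".csv")))
  }
  bundle <- list(compliance = unclass(res$compliance),
                 moderation = res$moderation$blocks)
  jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "emaccel",
    version = as.character(utils::packageVersion("emaccel")),
    seed = config$cohort$seed,
    n_dyads = config$cohort$n_dyads,
    study_days = config$cohort$study_days,
    n_eligible = length(res$eligible),
    n_analysis_rows = nrow(res$analysis),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
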