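# Compliance statistics, descriptive (Table-1-style) summaries and
# journal-style formatting of the moderation results.

#' Compliance percentage from raw counts
#'
#' `100 * completed / delivered`, rounded half-up to one decimal (so
#' 3127 of 3776 gives 82.8).
#'
#' @param completed,delivered survey counts; `delivered` must be positive.
#' @return percentage, one decimal.
#' @examples
#' compliance_percent(3127, 3776)
#' @export
compliance_percent <- function(completed, delivered) {
  if (any(delivered <= 0))
    stop("delivered survey count must be positive", call. = FALSE)
  round_half_up(100 * completed / delivered, 1)
}

#' EMA compliance and wear-time report
#'
#' Summarizes survey engagement over the analysis day set: completed and
#' delivered prompts (four per analysis day), the compliance percentage,
#' the share of respondents who completed on average at least three
#' surveys per analysis day, and mean daily wear hours over those days.
#' When `analysis` is `NULL`, all prompted surveys form the denominator.
#'
#' @param surveys prompt-level survey table with `completed`.
#' @param day_summaries per-day wear summaries ([summarize_days()]); used
#'   for mean wear hours (optional).
#' @param analysis analysis table; restricts the day set to matched
#'   participant-days (optional).
#' @return an object of class `compliance_report`.
#' @export
compliance_report <- function(surveys, day_summaries = NULL,
                              analysis = NULL) {
  keyify <- function(d) paste(d$participant_id, d$date)
  sv <- surveys
  if (!is.null(analysis) && nrow(analysis) > 0) {
    keep <- keyify(sv) %in% unique(keyify(analysis))
    sv <- sv[keep, , drop = FALSE]
  }
  delivered <- nrow(sv)
  if (delivered == 0)
    stop("no delivered surveys in the report day set", call. = FALSE)
  completed <- sum(sv$completed)

  per_day <- stats::aggregate(completed ~ participant_id + date,
                              data = transform(sv, completed =
                                                 as.integer(completed)),
                              FUN = sum)
  per_part <- stats::aggregate(completed ~ participant_id, data = per_day,
                               FUN = mean)
  pct_ge3 <- round_half_up(100 * mean(per_part$completed >= 3), 1)

  mean_wear <- NA_real_
  if (!is.null(day_summaries)) {
    ds <- day_summaries
    if (!is.null(analysis) && nrow(analysis) > 0)
      ds <- ds[keyify(ds) %in% unique(keyify(analysis)), , drop = FALSE]
    if (nrow(ds)) mean_wear <- round_half_up(mean(ds$wear_hours), 1)
  }
  structure(list(surveys_completed = completed,
                 surveys_delivered = delivered,
                 percent_compliant = compliance_percent(completed, delivered),
                 percent_ge3_per_day = pct_ge3,
                 mean_daily_wear_hours = mean_wear,
                 n_respondents = length(unique(sv$participant_id)),
                 n_days = nrow(per_day)),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf(
    "EMA compliance: %.1f%% (%d/%d) over %d days; %.1f%% of %d respondents\n",
    x$percent_compliant, x$surveys_completed, x$surveys_delivered,
    x$n_days, x$percent_ge3_per_day, x$n_respondents))
  cat(sprintf("averaged >= 3 completed surveys/day; mean wear %.1f h/day\n",
              x$mean_daily_wear_hours))
  invisible(x)
}

#' Descriptive summary by daily survey order
#'
#' For each within-day completion order (first to fourth answered survey):
#' mean completion clock time, mean pre-period wear hours, and mean ST /
#' LPA / MVPA minutes per hour with their integer percentage shares of the
#' worn hour. Orders with no observations are emitted with missing
#' markers.
#'
#' @param analysis the analysis table.
#' @param max_order number of rows to emit.
#' @return data.frame with one row per survey order.
#' @export
descriptive_table1 <- function(analysis, max_order = 4L) {
  out <- data.frame(survey_order = seq_len(max_order),
                    n = 0L, mean_completion_time = NA_character_,
                    mean_wear_hours = NA_real_,
                    st_mph = NA_real_, st_pct = NA_real_,
                    lpa_mph = NA_real_, lpa_pct = NA_real_,
                    mvpa_mph = NA_real_, mvpa_pct = NA_real_)
  if (nrow(analysis) == 0) return(out)
  for (k in seq_len(max_order)) {
    rows <- analysis[analysis$survey_order == k, , drop = FALSE]
    if (!nrow(rows)) next
    secs <- as.numeric(rows$completion_time) -
      as.numeric(as.POSIXct(paste(rows$date, "00:00:00"), tz = .tz))
    mt <- mean(secs)
    out$n[k] <- nrow(rows)
    out$mean_completion_time[k] <- format(
      as.POSIXct(mt, origin = as.Date("1970-01-01"), tz = .tz), "%I:%M %p")
    out$mean_wear_hours[k] <- round_half_up(mean(rows$wear_min) / 60, 1)
    out$st_mph[k] <- round_half_up(mean(rows$st_mph), 0)
    out$lpa_mph[k] <- round_half_up(mean(rows$lpa_mph), 0)
    out$mvpa_mph[k] <- round_half_up(mean(rows$mvpa_mph), 0)
    out$st_pct[k] <- round_half_up(100 * mean(rows$st_mph) / 60, 0)
    out$lpa_pct[k] <- round_half_up(100 * mean(rows$lpa_mph) / 60, 0)
    out$mvpa_pct[k] <- round_half_up(100 * mean(rows$mvpa_mph) / 60, 0)
  }
  out
}

#' Journal-style P value rendering
#'
#' `"<.001"` below 0.001; three decimals below 0.01; otherwise two
#' decimals; always without the leading zero (0.02 renders as `".02"`).
#'
#' @param p numeric vector of P values.
#' @return character vector.
#' @examples
#' format_p_value(c(0.0004, 0.005, 0.02, 0.37))
#' @export
format_p_value <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- character(length(p))
  out[p < 0.001] <- "<.001"
  i <- p >= 0.001 & p < 0.01
  out[i] <- sub("^0", "", sprintf("%.3f", p[i]))
  i <- p >= 0.01
  out[i] <- sub("^0", "", sprintf("%.2f", p[i]))
  out
}

#' Format an estimate with its 95% CI
#'
#' Renders `estimate (95% CI low to high)` at one decimal, the CI computed
#' as estimate +/- 1.96 SE (e.g. -5.12 with SE 0.918 gives
#' `"-5.1 (95% CI -6.9 to -3.3)"`).
#'
#' @param estimate point estimate.
#' @param se robust standard error.
#' @return character scalar.
#' @export
format_estimate_ci <- function(estimate, se) {
  lo <- estimate - 1.96 * se
  hi <- estimate + 1.96 * se
  f <- function(x) sprintf("%.1f", round_half_up(x, 1))
  sprintf("%s (95%% CI %s to %s)", f(estimate), f(lo), f(hi))
}

#' Formatted moderation results
#'
#' One block per fitted (exposure, outcome, modifier) model: the
#' interaction Wald P (journal-rendered) and the per-stratum exposure
#' estimates with 95% CIs; plus a long `terms` table with raw values.
#'
#' @param fits the `fits` element of a [run_pipeline()] result (list of
#'   `list(spec, fit, interaction, strata)`).
#' @return list with `blocks` (formatted, one entry per model) and `terms`
#'   (data.frame of raw coefficient-level results).
#' @export
moderation_report <- function(fits) {
  blocks <- list()
  terms <- list()
  for (f in fits) {
    sp <- f$spec
    label <- paste(sp$exposure, "->", sp$outcome,
                   if (!is.null(sp$modifier)) paste("by", sp$modifier))
    se <- sqrt(diag(f$fit$robust_cov))
    terms[[length(terms) + 1]] <- data.frame(
      model = label, term = names(f$fit$beta),
      estimate = unname(f$fit$beta), robust_se = unname(se),
      ci_low = unname(f$fit$beta - 1.96 * se),
      ci_high = unname(f$fit$beta + 1.96 * se),
      stringsAsFactors = FALSE)
    bl <- list(exposure = sp$exposure, outcome = sp$outcome,
               modifier = sp$modifier)
    if (!is.null(f$interaction)) {
      bl$wald_chisq <- f$interaction$statistic
      bl$df <- f$interaction$df
      bl$p_interaction <- f$interaction$p_value
      bl$p_rendered <- format_p_value(f$interaction$p_value)
    }
    if (!is.null(f$strata)) {
      bl$strata <- lapply(seq_len(nrow(f$strata)), function(i)
        list(level = f$strata$level[i],
             estimate = f$strata$estimate[i],
             ci_low = f$strata$ci_low[i],
             ci_high = f$strata$ci_high[i],
             rendered = format_estimate_ci(f$strata$estimate[i],
                                           f$strata$se[i])))
    }
    blocks[[label]] <- bl
  }
  list(blocks = blocks, terms = do.call(rbind, terms))
}
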