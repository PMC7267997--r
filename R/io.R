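# Plain-text I/O for the device-export dialect and config documents.

#' Write an epoch stream as a device-style CSV
#'
#' Plain-text export dialect: a short metadata header (participant, epoch
#' length, start time) followed by `timestamp,counts` rows at 15-second
#' resolution.
#'
#' @param stream an `epoch_stream`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_actigraph_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "--- ActiGraph-style epoch export ---",
    paste0("Participant: ", attr(stream, "participant_id") %||% "NA"),
    "Epoch: 15 sec",
    paste0("Start: ", format(min(stream$timestamp), "%Y-%m-%d %H:%M:%S")),
    "------------------------------------",
    "timestamp,counts"), con)
  writeLines(sprintf("%s,%d",
                     format(stream$timestamp, "%Y-%m-%d %H:%M:%S"),
                     stream$counts), con)
  invisible(path)
}

#' Read a device-style epoch CSV
#'
#' @param path file written by [write_actigraph_csv()] (or matching the
#'   dialect).
#' @return an `epoch_stream` data.frame with the participant id attribute.
#' @export
read_actigraph_csv <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^timestamp,counts$", lines)
  if (!length(hdr)) stop("not a recognized epoch CSV: ", path, call. = FALSE)
  pid_line <- grep("^Participant:", lines, value = TRUE)
  pid <- if (length(pid_line)) trimws(sub("^Participant:", "", pid_line[1]))
         else NA_character_
  df <- utils::read.csv(path, skip = hdr[1] - 1, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = .tz)
  structure(df, participant_id = pid,
            class = c("epoch_stream", "data.frame"))
}

#' Build a pipeline configuration from a JSON document
#'
#' Reads a JSON config with optional top-level sections `cohort`,
#' `activity`, `reporting`, `criteria`, `designs`, and scalars
#' `compliance`, `min_completed`; unknown keys are an error, missing ones
#' take package defaults. Each section's keys are passed to the matching
#' constructor, which performs validation. `designs` is an array of
#' objects with [design_spec()] fields; alternatively `modifiers` names
#' the modifiers for [default_design_specs()].
#'
#' @param path JSON file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  allowed <- c("cohort", "activity", "reporting", "criteria", "compliance",
               "min_completed", "modifiers", "designs")
  bad <- setdiff(names(doc), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  build <- function(fn, args) do.call(fn, as.list(args %||% list()))
  designs <- if (!is.null(doc$designs))
    lapply(doc$designs, function(d) build(design_spec, d))
  else default_design_specs(doc$modifiers %||% "weekend")
  pipeline_config(
    cohort = build(cohort_config, doc$cohort),
    activity = build(activity_params, doc$activity),
    reporting = build(reporting_params, doc$reporting),
    criteria = build(validity_criteria, doc$criteria),
    compliance = doc$compliance %||% 0.83,
    designs = designs,
    min_completed = doc$min_completed %||% 2L
  )
}
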