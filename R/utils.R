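#' @keywords internal
"_PACKAGE"

# All clock arithmetic in the package uses a fixed UTC representation of
# local study time, so hour/day boundaries never shift under DST.
.tz <- "UTC"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used in
#' the journal-style reports), unlike [round()], which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(82.8125, 1)  # 82.8
#' round_half_up(70.5, 0)     # 71
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate a time to the start of its clock hour
#'
#' @param t a POSIXct vector.
#' @return POSIXct vector at whole hours.
#' @examples
#' floor_hour(as.POSIXct("2017-05-01 10:23:00", tz = "UTC"))
#' @export
floor_hour <- function(t) {
  as.POSIXct(trunc(t, units = "hours"))
}

floor_minute <- function(t) {
  as.POSIXct(trunc(t, units = "mins"))
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent stream
#' seeds (e.g. one per participant), each below 2^31.
#'
#' @param master_seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed), n >= 0)
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' Saturday/Sunday weekend flag
#'
#' @param date a Date vector.
#' @return logical vector, `TRUE` on Saturdays and Sundays.
#' @export
is_weekend <- function(date) {
  format(as.Date(date), "%u") %in% c("6", "7")
}

# validate that a named probability vector sums to one
check_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(sprintf("probabilities for '%s' must be nonnegative and sum to 1",
                 what), call. = FALSE)
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop(sprintf("probabilities for '%s' must be named", what), call. = FALSE)
  invisible(p)
}
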