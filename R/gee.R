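# Marginal linear models for clustered survey-level outcomes:
# independence working correlation (point estimates = least squares) with
# Huber-White cluster-robust covariance, Wald tests and stratum estimates.

#' Model specification for a moderation analysis
#'
#' Describes one marginal model: an intensity outcome regressed on a
#' dummy-coded parent-report exposure, adjusted for covariates, optionally
#' with an exposure-by-modifier interaction. The modifier always enters as
#' a main effect too. Reference levels are chosen so the printed contrasts
#' (weekend, boy, summer) are the non-reference strata.
#'
#' @param outcome one of `"st_mph"`, `"lpa_mph"`, `"mvpa_mph"`.
#' @param exposure `"pa_reported"` or `"sb_reported"`.
#' @param covariates adjustment variables present in the analysis table.
#' @param modifier `NULL` or one of `"weekend"`, `"sex"`, `"season"`.
#' @param references named list of reference levels for categorical terms.
#' @return an object of class `design_spec`.
#' @examples
#' design_spec("st_mph", "pa_reported", modifier = "weekend")
#' @export
design_spec <- function(outcome,
                        exposure = c("pa_reported", "sb_reported"),
                        covariates = c("race_ethnicity", "weight_status",
                                       "weekend", "sex", "age", "season",
                                       "income"),
                        modifier = NULL,
                        references = list(weekend = "FALSE", sex = "girl",
                                          season = "school_year",
                                          race_ethnicity = "white",
                                          weight_status = "normal",
                                          income = "higher")) {
  exposure <- match.arg(exposure)
  if (!is.null(modifier)) {
    modifier <- match.arg(modifier, c("weekend", "sex", "season"))
    covariates <- union(covariates, modifier)  # modifier main effect
  }
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, modifier = modifier,
                 references = references),
            class = "design_spec")
}

#' Build the design matrix for a specification
#'
#' Expands categoricals to treatment-coded indicators against the
#' specification's reference levels, adds the intercept and, when a
#' modifier is present, the exposure-by-modifier product column(s).
#'
#' @param table analysis table (see [assemble_analysis_table()]).
#' @param spec a [design_spec()].
#' @return list `y` (outcome vector), `X` (design matrix), `clusters`
#'   (participant ids), `spec`.
#' @export
build_design_matrix <- function(table, spec) {
  stopifnot(inherits(spec, "design_spec"))
  used <- unique(c(spec$outcome, spec$exposure, spec$covariates,
                   spec$modifier, "participant_id"))
  miss <- setdiff(used, names(table))
  if (length(miss))
    stop("analysis table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(table[, used]))
    stop("missing values in model columns", call. = FALSE)

  df <- table[, used, drop = FALSE]
  for (v in setdiff(used, c(spec$outcome, "participant_id"))) {
    if (is.character(df[[v]]) || is.logical(df[[v]]) || is.factor(df[[v]])) {
      f <- factor(as.character(df[[v]]))
      ref <- spec$references[[v]]
      if (!is.null(ref) && ref %in% levels(f)) f <- stats::relevel(f, ref)
      df[[v]] <- f
    }
  }
  rhs <- c(spec$exposure, setdiff(spec$covariates, spec$exposure))
  if (!is.null(spec$modifier))
    rhs <- c(rhs, paste0(spec$exposure, ":", spec$modifier))
  fml <- stats::reformulate(rhs)
  X <- stats::model.matrix(fml, data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(y = df[[spec$outcome]], X = X,
       clusters = table$participant_id, spec = spec)
}

#' Fit a marginal linear model with cluster-robust variance
#'
#' Under a Gaussian working model with identity link and independence
#' working correlation, the estimating equations reduce to the
#' least-squares normal equations; the coefficient covariance is the
#' Huber-White cluster sandwich
#' \deqn{V = (X'X)^{-1} \left(\sum_c X_c' r_c r_c' X_c\right) (X'X)^{-1},}
#' with residual vectors \eqn{r_c} summed within clusters (participants).
#' By default no small-sample correction is applied; `df_correction = TRUE`
#' multiplies the sandwich by \eqn{G/(G-1) \cdot (n-1)/(n-p)}.
#'
#' @param y numeric outcome vector.
#' @param X design matrix (full column rank, intercept included).
#' @param clusters cluster identifiers, one per row of `X`.
#' @param df_correction apply the finite-cluster degrees-of-freedom factor.
#' @return an object of class `gee_fit` with elements `beta`,
#'   `robust_cov`, `n_clusters`, `n_obs`, `residuals`, `df_correction`.
#' @examples
#' fit <- fit_gee_independence(c(1, 2, 3, 4),
#'                             cbind(1, c(0, 0, 1, 1)),
#'                             clusters = c("A", "A", "B", "B"))
#' coef(fit)
#' @export
fit_gee_independence <- function(y, X, clusters, df_correction = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(clusters) == n)
  G <- length(unique(clusters))
  if (G < 2L) stop("at least two clusters are required", call. = FALSE)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e)
    stop("singular X'X: design is not full rank", call. = FALSE))
  bread <- chol2inv(ch)
  beta <- drop(bread %*% crossprod(X, y))
  names(beta) <- colnames(X)
  r <- y - drop(X %*% beta)
  # meat: sum over clusters of (X_c' r_c)(X_c' r_c)'
  S <- rowsum(X * r, group = clusters)
  meat <- crossprod(S)
  V <- bread %*% meat %*% bread
  if (df_correction) V <- V * (G / (G - 1)) * ((n - 1) / (n - p))
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, robust_cov = V, n_clusters = G, n_obs = n,
                 residuals = r, df_correction = df_correction),
            class = "gee_fit")
}

#' Fit a specified moderation model on an analysis table
#'
#' Convenience wrapper: builds the design for `spec`, fits the
#' independence-GEE, and attaches the specification.
#'
#' @param table analysis table.
#' @param spec a [design_spec()].
#' @param df_correction see [fit_gee_independence()].
#' @return a `gee_fit` with a `spec` element.
#' @export
fit_model <- function(table, spec, df_correction = FALSE) {
  d <- build_design_matrix(table, spec)
  fit <- fit_gee_independence(d$y, d$X, d$clusters, df_correction)
  fit$spec <- spec
  fit$modifier_levels <- if (!is.null(spec$modifier))
    levels(factor(as.character(table[[spec$modifier]]))) else NULL
  fit
}

#' @export
coef.gee_fit <- function(object, ...) object$beta

#' @export
vcov.gee_fit <- function(object, ...) object$robust_cov

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "<gee_fit> independence working correlation, %d obs in %d clusters\n",
    x$n_obs, x$n_clusters))
  se <- sqrt(diag(x$robust_cov))
  z <- x$beta / se
  tab <- data.frame(estimate = x$beta, robust_se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, 4))
  invisible(x)
}

#' Wald chi-square test of a linear hypothesis
#'
#' Tests `L beta = 0` with the cluster-robust covariance:
#' statistic \eqn{(L\hat\beta)' (L V L')^{-1} (L\hat\beta)} on `nrow(L)`
#' degrees of freedom. `L` may also be the name (or index) of a single
#' coefficient.
#'
#' @param fit a `gee_fit`.
#' @param L contrast matrix (rows = hypotheses), or a coefficient
#'   name/index for a single-df test.
#' @return list (`statistic`, `df`, `p_value`) of class `wald_result`.
#' @export
wald_test <- function(fit, L) {
  stopifnot(inherits(fit, "gee_fit"))
  p <- length(fit$beta)
  if (is.character(L) || (is.numeric(L) && is.null(dim(L)) &&
                          length(L) == 1)) {
    j <- if (is.character(L)) match(L, names(fit$beta)) else as.integer(L)
    if (is.na(j) || j < 1 || j > p)
      stop("unknown coefficient: ", L, call. = FALSE)
    L <- matrix(0, 1, p); L[1, j] <- 1
  }
  L <- rbind(L)
  if (ncol(L) != p)
    stop("contrast matrix has wrong number of columns", call. = FALSE)
  lb <- drop(L %*% fit$beta)
  if (all(L == 0)) {
    out <- list(statistic = 0, df = nrow(L), p_value = 1)
  } else {
    if (qr(L)$rank < nrow(L))
      stop("contrast matrix must have full row rank", call. = FALSE)
    M <- L %*% fit$robust_cov %*% t(L)
    ch <- tryCatch(chol(M), error = function(e)
      stop("singular contrast covariance L V L'", call. = FALSE))
    stat <- drop(crossprod(lb, chol2inv(ch) %*% lb))
    out <- list(statistic = stat, df = nrow(L),
                p_value = stats::pchisq(stat, nrow(L), lower.tail = FALSE))
  }
  class(out) <- "wald_result"
  out
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Exposure effect within each modifier stratum
#'
#' For a fit containing exposure, modifier and product terms, returns the
#' exposure contrast in each modifier stratum: the exposure coefficient in
#' the reference stratum, and exposure + product in the other stratum,
#' with standard errors from \eqn{a' V a} and 95% CIs at +/- 1.96 SE.
#'
#' @param fit a `gee_fit` from [fit_model()] with a modifier.
#' @param conf_level confidence level (normal quantile).
#' @return data.frame (`level`, `estimate`, `se`, `ci_low`, `ci_high`).
#' @export
stratum_estimates <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "gee_fit"))
  spec <- fit$spec
  if (is.null(spec) || is.null(spec$modifier))
    stop("fit has no modifier; stratum estimates are undefined",
         call. = FALSE)
  nm <- names(fit$beta)
  e_idx <- match(spec$exposure, nm)
  if (is.na(e_idx)) stop("exposure term not found in fit", call. = FALSE)
  prod_idx <- grep(paste0("^", spec$exposure, ":", spec$modifier),
                   nm)
  if (!length(prod_idx))
    stop("interaction term not found in fit", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lv <- fit$modifier_levels %||%
    c("reference", sub(paste0("^", spec$exposure, ":", spec$modifier), "",
                       nm[prod_idx]))
  rows <- list()
  a <- numeric(length(nm)); a[e_idx] <- 1
  est <- sum(a * fit$beta); se <- sqrt(drop(t(a) %*% fit$robust_cov %*% a))
  rows[[1]] <- data.frame(level = lv[1], estimate = est, se = se,
                          ci_low = est - z * se, ci_high = est + z * se)
  for (k in seq_along(prod_idx)) {
    a <- numeric(length(nm)); a[e_idx] <- 1; a[prod_idx[k]] <- 1
    est <- sum(a * fit$beta)
    se <- sqrt(drop(t(a) %*% fit$robust_cov %*% a))
    rows[[k + 1]] <- data.frame(
      level = sub(paste0("^", spec$exposure, ":", spec$modifier), "",
                  nm[prod_idx[k]]),
      estimate = est, se = se,
      ci_low = est - z * se, ci_high = est + z * se)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interaction Wald test of a moderated fit
#'
#' Single- (binary modifier) or multi-row Wald chi-square test that all
#' exposure-by-modifier product coefficients are zero.
#'
#' @param fit a `gee_fit` from [fit_model()] with a modifier.
#' @return a `wald_result`.
#' @export
interaction_wald <- function(fit) {
  spec <- fit$spec
  if (is.null(spec) || is.null(spec$modifier))
    stop("fit has no modifier", call. = FALSE)
  nm <- names(fit$beta)
  idx <- grep(paste0("^", spec$exposure, ":", spec$modifier), nm)
  if (!length(idx)) stop("interaction term not found", call. = FALSE)
  L <- matrix(0, length(idx), length(nm))
  L[cbind(seq_along(idx), idx)] <- 1
  wald_test(fit, L)
}
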