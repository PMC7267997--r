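# Independence-GEE point estimates, cluster sandwich covariance, Wald
# tests and stratum estimates.

test_that("two-group design recovers the group means", {
  fit <- fit_gee_independence(c(1, 2, 3, 4), cbind(1, c(0, 0, 1, 1)),
                              clusters = c("A", "A", "B", "B"))
  expect_equal(unname(coef(fit)), c(1.5, 2.0))
})

test_that("the cluster sandwich matches explicit matrix arithmetic", {
  y <- c(1, 2, 3, 4)
  X <- cbind(1, c(0, 0, 1, 1))
  fit <- fit_gee_independence(y, X, clusters = c("A", "A", "B", "B"))
  # hand computation: bread = (X'X)^-1, meat = sum_c (X_c' r_c)(X_c' r_c)'
  bread <- solve(t(X) %*% X)
  r <- y - X %*% matrix(c(1.5, 2.0))
  meat <- matrix(0, 2, 2)
  for (cl in list(1:2, 3:4)) {
    s <- t(X[cl, , drop = FALSE]) %*% r[cl, , drop = FALSE]
    meat <- meat + s %*% t(s)
  }
  expect_equal(unname(fit$robust_cov), bread %*% meat %*% bread,
               tolerance = 1e-12)
})

test_that("one observation per cluster reduces to HC0", {
  set.seed(101)
  n <- 40
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- X %*% c(1, 2, -1) + rnorm(n)
  fit <- fit_gee_independence(y, X, clusters = seq_len(n))
  lmfit <- lm(y ~ X - 1)
  hc0 <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_equal(unname(fit$robust_cov), unname(hc0), tolerance = 1e-10)
})

test_that("cluster sandwich agrees with an established implementation", {
  set.seed(113)
  n <- 120
  cl <- rep(1:20, each = 6)
  df <- data.frame(x = rnorm(n), g = factor(rbinom(n, 1, 0.4)),
                   id = cl)
  df$y <- 1 + 0.5 * df$x + (df$g == "1") + rnorm(20)[cl] + rnorm(n)
  lmfit <- lm(y ~ x + g, data = df)
  X <- model.matrix(lmfit)
  fit <- fit_gee_independence(df$y, X, df$id)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-10)
  vcl <- sandwich::vcovCL(lmfit, cluster = df$id, type = "HC0",
                          cadjust = FALSE)
  expect_equal(unname(fit$robust_cov), unname(vcl), tolerance = 1e-10)
})

test_that("estimates are invariant to cluster and row ordering", {
  set.seed(127)
  n <- 90
  cl <- sample(rep(1:15, each = 6))
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- X %*% c(2, 1, -0.5) + rnorm(15)[cl] + rnorm(n)
  fit <- fit_gee_independence(y, X, cl)
  perm <- sample(n)
  fit2 <- fit_gee_independence(y[perm], X[perm, ], cl[perm])
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-12)
  expect_equal(fit$robust_cov, fit2$robust_cov, tolerance = 1e-12)
})

test_that("degenerate fits raise estimation errors", {
  expect_error(fit_gee_independence(1:4, cbind(1, c(1, 1, 1, 1)),
                                    c("A", "A", "B", "B")), "singular")
  expect_error(fit_gee_independence(1:4, cbind(1, 0:3), rep("A", 4)),
               "two clusters")
})

test_that("design construction expands factors against reference levels", {
  res <- small_pipeline()
  tab <- res$analysis

  sp0 <- design_spec("st_mph", "pa_reported", covariates = character(0))
  d0 <- build_design_matrix(tab, sp0)
  expect_identical(colnames(d0$X), c("(Intercept)", "pa_reported"))

  sp1 <- design_spec("st_mph", "pa_reported", covariates = character(0),
                     modifier = "weekend")
  d1 <- build_design_matrix(tab, sp1)
  expect_true(all(c("weekendTRUE", "pa_reported:weekendTRUE") %in%
                    colnames(d1$X)))

  if (length(unique(tab$race_ethnicity)) == 6) {
    sp2 <- design_spec("st_mph", "pa_reported",
                       covariates = "race_ethnicity")
    d2 <- build_design_matrix(tab, sp2)
    expect_equal(sum(grepl("^race_ethnicity", colnames(d2$X))), 5)
    expect_false("race_ethnicitywhite" %in% colnames(d2$X))  # reference
  }
})

test_that("collinear designs are reported with the offending column", {
  res <- small_pipeline()
  tab <- res$analysis
  tab$dup <- tab$pa_reported
  sp <- design_spec("st_mph", "pa_reported", covariates = "dup")
  expect_error(build_design_matrix(tab, sp), "rank deficient.*dup")

  tab2 <- res$analysis
  tab2$st_mph[1] <- NA
  expect_error(build_design_matrix(tab2, design_spec("st_mph",
                                                     "pa_reported")),
               "missing values")
})

test_that("Wald tests reduce to the scalar case and match brute force", {
  set.seed(131)
  n <- 60
  cl <- rep(1:12, each = 5)
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x", "z")
  y <- X %*% c(1, 0.5, 0) + rnorm(12)[cl] + rnorm(n)
  fit <- fit_gee_independence(y, X, cl)

  w1 <- wald_test(fit, "x")
  se <- sqrt(fit$robust_cov["x", "x"])
  expect_equal(w1$statistic, (coef(fit)[["x"]] / se)^2, tolerance = 1e-12)
  expect_equal(w1$df, 1)

  w0 <- wald_test(fit, matrix(0, 1, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  L <- rbind(c(0, 1, 0), c(0, 0, 1))
  w2 <- wald_test(fit, L)
  lb <- L %*% coef(fit)
  direct <- t(lb) %*% solve(L %*% fit$robust_cov %*% t(L)) %*% lb
  expect_equal(w2$statistic, as.numeric(direct), tolerance = 1e-12)
  expect_equal(w2$p_value, pchisq(as.numeric(direct), 2, lower.tail = FALSE))

  expect_error(wald_test(fit, rbind(c(0, 1, 0), c(0, 2, 0))), "row rank")
})

test_that("stratum CIs reproduce printed-style arithmetic", {
  # an estimate of -5.1 with contrast SE 0.918 prints as (-6.9, -3.3)
  est <- -5.1; se <- 0.918
  expect_equal(round_half_up(est - 1.96 * se, 1), -6.9)
  expect_equal(round_half_up(est + 1.96 * se, 1), -3.3)
  expect_equal(format_estimate_ci(est, se),
               "-5.1 (95% CI -6.9 to -3.3)")
})

test_that("stratum estimates equal direct contrast expansion", {
  set.seed(139)
  d <- simulate_clustered_outcomes(30, 6, beta = c(30, -4, 1, -2))
  fit <- fit_clustered_outcomes(d)
  st <- stratum_estimates(fit)
  b <- coef(fit); V <- fit$robust_cov
  # reference stratum: exposure alone
  expect_equal(st$estimate[1], b[["exposure"]])
  a <- c(0, 1, 0, 0)
  expect_equal(st$se[1], sqrt(drop(t(a) %*% V %*% a)), tolerance = 1e-12)
  # weekend stratum: exposure + product
  a2 <- c(0, 1, 0, 1)
  expect_equal(st$estimate[2],
               b[["exposure"]] + b[["exposure:weekendTRUE"]])
  expect_equal(st$se[2], sqrt(drop(t(a2) %*% V %*% a2)), tolerance = 1e-12)
  expect_true(all(st$ci_low <= st$estimate & st$estimate <= st$ci_high))
})

test_that("a zero product coefficient gives equal stratum estimates", {
  fit <- fit_gee_independence(
    y = c(1, 2, 3, 5, 2, 4),
    X = cbind("(Intercept)" = 1, exposure = c(0, 1, 0, 1, 0, 1),
              weekendTRUE = c(0, 0, 1, 1, 0, 0),
              "exposure:weekendTRUE" = c(0, 0, 0, 1, 0, 0)),
    clusters = c(1, 1, 2, 2, 3, 3))
  fit$beta[["exposure:weekendTRUE"]] <- 0  # impose the null contrast
  fit$spec <- design_spec("st_mph", "pa_reported", modifier = "weekend")
  fit$spec$exposure <- "exposure"
  fit$modifier_levels <- c("FALSE", "TRUE")
  st <- stratum_estimates(fit)
  expect_equal(st$estimate[1], st$estimate[2])
})

test_that("sandwich variance shrinks with the number of clusters", {
  set.seed(149)
  var_at <- function(G) {
    mean(replicate(25, {
      d <- simulate_clustered_outcomes(G, 4, beta = c(30, -4, 1, 0))
      fit <- fit_clustered_outcomes(d)
      fit$robust_cov["exposure", "exposure"]
    }))
  }
  v20 <- var_at(20); v80 <- var_at(80)
  expect_lt(v80 / v20, 0.5)  # ~ O(1/G): expect about 0.25
})
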