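test_that("quadratic fit to the published series reproduces its table", {
  reg <- l50_age_fit(age_l50_points)
  co <- coef(reg)
  expect_equal(co[["Intercept"]], 2.403749, tolerance = 1e-6 / 2.4)
  expect_lt(abs(co[["B1"]] - -0.403234), 1e-6)
  expect_lt(abs(co[["B2"]] - 0.016114), 1e-6)
  expect_equal(reg$rss, 0.096720, tolerance = 1e-5)
  expect_equal(reg$r_squared, 0.98036, tolerance = 1e-4)
  expect_equal(round(reg$aic, 2), -23.97)
  expect_equal(round(reg$bic, 2), -24.14)
})

test_that("quadratic least squares matches a normal-equations oracle", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- sort(runif(n, 0, 20))
    y <- abs(2 + runif(1, -1, 1) * x + 0.05 * x^2 + rnorm(n, 0, 0.3))
    reg <- l50_age_fit(data.frame(age = x, l50 = y))
    X <- cbind(1, x, x^2)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(coef(reg)), as.numeric(beta), tolerance = 1e-10)
  }
})

test_that("regression is invariant to point order and exact on exact data", {
  x <- c(0, 1, 3, 4, 5, 6)
  y <- 2 - 0.4 * x + 0.016 * x^2
  reg <- l50_age_fit(data.frame(age = x, l50 = y))
  expect_equal(unname(coef(reg)), c(2, -0.4, 0.016), tolerance = 1e-10)
  expect_lt(reg$rss, 1e-20)
  shuffled <- age_l50_points[c(4, 1, 7, 3, 6, 2, 5), ]
  expect_equal(coef(l50_age_fit(shuffled)),
               coef(l50_age_fit(age_l50_points)), tolerance = 1e-12)
})

test_that("insufficient points are refused with the minimum named", {
  expect_error(l50_age_fit(data.frame(age = 0:2, l50 = c(2, 1, 0.5))),
               "at least 4")
  expect_error(l50_age_fit(age_l50_points[1:4, ], form = "weibull4"),
               "at least 5")
})

test_that("fixed published curves evaluate correctly on the series", {
  w4 <- as_l50_regression(c(15.040215, 23.463344, 17.811551, 2.368872),
                          "weibull4")
  ev <- evaluate_l50_regression(w4, age_l50_points)
  expect_equal(round(ev$rss, 2), 0.31)
  expect_equal(round(ev$aic, 2), -13.81)
  expect_equal(round(ev$bic, 2), -14.02)
  quad <- as_l50_regression(c(2.403749, -0.403234, 0.016114), "quadratic")
  expect_equal(evaluate_l50_regression(quad, age_l50_points)$rss,
               0.0967, tolerance = 1e-3)
  # a curve scored on its own noise-free samples has zero residual
  pts <- data.frame(age = 0:6, l50 = predict(quad, 0:6))
  expect_lt(sum((pts$l50 - predict(quad, pts))^2), 1e-20)
})

test_that("fitted four-parameter age curve beats or meets the fixed one", {
  regw <- l50_age_fit(age_l50_points, form = "weibull4")
  expect_lte(regw$rss, 0.3106016 + 1e-6)
  regq <- l50_age_fit(age_l50_points)
  expect_lt(regq$aic, regw$aic)  # quadratic wins on this series
})

test_that("longevity bound returns both roots of the quadratic", {
  reg <- l50_age_fit(age_l50_points)
  b <- longevity_bound(reg)
  expect_true(b$crossing)
  expect_equal(b$root_small, 9.79, tolerance = 0.02 / 9.79)
  expect_equal(b$root_large, 15.23, tolerance = 0.02 / 15.23)
  expect_equal(b$bound, b$root_small)
  # each root really is a zero of the polynomial
  expect_lt(abs(predict(reg, b$root_small)), 1e-8)
  expect_lt(abs(predict(reg, b$root_large)), 1e-8)
})

test_that("linear and non-crossing quadratics are handled", {
  lin <- as_l50_regression(c(1, -1, 0), "quadratic")
  expect_equal(longevity_bound(lin)$root_small, 1)
  none <- as_l50_regression(c(1, 0, 1), "quadratic")
  expect_false(longevity_bound(none)$crossing)
  expect_error(longevity_bound(as_l50_regression(c(1, 0, 0), "quadratic")),
               "no age dependence")
})

test_that("equivalent age inverts the quadratic on its falling branch", {
  reg <- l50_age_fit(age_l50_points)
  co <- coef(reg)
  expect_equal(equivalent_age(reg, co[["Intercept"]]), 0)
  # round trip at an interior age
  l3 <- predict(reg, 3)
  expect_equal(equivalent_age(reg, l3), 3, tolerance = 1e-8)
  # habitat inversion; expected value frozen from a bisection oracle on
  # the published coefficients
  pub <- as_l50_regression(c(2.403749, -0.403234, 0.016114), "quadratic")
  oracle <- uniroot(function(x) predict(pub, x) - 1.59, c(0, 9.79),
                    tol = 1e-12)$root
  expect_equal(oracle, 2.2139, tolerance = 1e-4)
  expect_equal(equivalent_age(pub, 1.59), oracle, tolerance = 1e-8)
  # forward evaluation reproduces the inverted input
  expect_equal(predict(pub, equivalent_age(pub, 1.2)), 1.2,
               tolerance = 1e-8)
  expect_error(equivalent_age(reg, 5), "fresher")
})

test_that("one-way ANOVA matches definitional sums of squares", {
  set.seed(19)
  for (i in 1:15) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:6, 1),
                                                   mean = j / 2))
    res <- anova_oneway(groups)
    y <- unlist(groups); gm <- mean(y)
    means <- vapply(groups, mean, numeric(1))
    sizes <- vapply(groups, length, integer(1))
    ssb <- sum(sizes * (means - gm)^2)
    ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
    f_oracle <- (ssb / (k - 1)) / (ssw / (length(y) - k))
    expect_equal(res$F, f_oracle, tolerance = 1e-10)
    expect_equal(res$ss_between, ssb, tolerance = 1e-10)
    expect_equal(res$ss_within, ssw, tolerance = 1e-10)
    expect_equal(res$p, stats::pf(f_oracle, k - 1, length(y) - k,
                                  lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(29)
  for (i in 1:10) {
    g1 <- rnorm(5); g2 <- rnorm(6, 0.5)
    res <- anova_oneway(list(g1, g2))
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA edge cases: identical means and degenerate variance", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  flat <- anova_oneway(list(c(1, 1, 1), c(1, 1, 1)))
  expect_true(flat$undefined)
  expect_error(anova_oneway(list(1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(1:3, 2)), ">= 2 values")
})

test_that("germination summary reproduces the published cohort means", {
  g <- germination_summary(germ_reps)
  expect_equal(g$mean[g$cohort == "2008"], 0)
  expect_equal(g$sd[g$cohort == "2008"], 0)
  expect_equal(round(g$mean[g$cohort == "2015"], 2), 10.56)
  # replicate mean is exactly 86.665; the published table prints 86.67
  expect_equal(g$mean[g$cohort == "2023"], 86.67, tolerance = 1e-4)
  # mean and sd recompute exactly from the replicate lists
  expect_equal(g$mean[g$cohort == "2015"], mean(germ_reps$`2015`))
  expect_equal(g$sd[g$cohort == "2015"], sd(germ_reps$`2015`))
})

test_that("Tukey letters separate clearly different cohorts", {
  g <- germination_summary(germ_reps)
  # the near-dead cohorts and the fresh cohort never share a letter
  l08 <- g$letter[g$cohort == "2008"]
  l23 <- g$letter[g$cohort == "2023"]
  expect_false(any(strsplit(l08, "")[[1]] %in% strsplit(l23, "")[[1]]))
  # statistically indistinguishable cohorts share a letter
  set.seed(37)
  same <- list(a = rnorm(6, 50, 5), b = rnorm(6, 50, 5),
               far = rnorm(6, 95, 2))
  gs <- germination_summary(same)
  expect_true(any(strsplit(gs$letter[gs$cohort == "a"], "")[[1]] %in%
                  strsplit(gs$letter[gs$cohort == "b"], "")[[1]]))
  expect_error(germination_summary(list(a = 1)), ">= 2 replicates")
  expect_error(germination_summary(list(a = c(5, 200), b = c(1, 2))),
               "\\[0, 100\\]")
})

test_that("data-frame germination input matches the list interface", {
  df <- solanum_germination()
  g1 <- germination_summary(df)
  g2 <- germination_summary(split(df$percent_germinated, df$cohort))
  expect_equal(g1$mean, g2$mean)
  expect_equal(g1$letter, g2$letter)
})

test_that("bootstrap L50 estimate is deterministic and ordered", {
  a <- simulate_assay(c(2, 4, -0.3), rng_seed = 5)
  e1 <- l50_with_ci(a, b_boot = 50, rng_seed = 11)
  e2 <- l50_with_ci(a, b_boot = 50, rng_seed = 11)
  expect_identical(e1$l50, e2$l50)
  expect_identical(e1$ci_low, e2$ci_low)
  expect_identical(e1$ci_high, e2$ci_high)
  expect_lte(e1$ci_low, e1$l50)
  expect_gte(e1$ci_high, e1$l50)
})

test_that("noise-free assays give a collapsed bootstrap interval", {
  a <- noise_free_assay(gy_params)
  e <- l50_with_ci(a, b_boot = 30, rng_seed = 2)
  expect_equal(e$l50, 1.5449, tolerance = 1e-3)
  expect_equal(e$ci_high - e$ci_low, 0, tolerance = 1e-4)
})

test_that("single-replicate assays return a point estimate with a flag", {
  tt <- 0:4
  a <- viability_assay(tt, rep(1, 5),
                       viability = decay_viability(tt, c(2, 4, -0.3)))
  e <- l50_with_ci(a, b_boot = 20, rng_seed = 1)
  expect_true(e$single_replicate)
  expect_false(is.finite(e$ci_low))
  expect_gt(e$l50, 0)
})
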