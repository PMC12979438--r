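test_that("viability CSV loads counts, percentages and metadata", {
  d <- expand.grid(replicate = 1:3, time_days = 0:4,
                   lot_id = c("A", "B"))
  d$n_tested <- 50
  d$n_viable <- pmin(50, round(50 * exp(-(d$time_days / 2)^3)))
  d$collection_year <- ifelse(d$lot_id == "A", 2021, 2022)
  path <- write_temp_csv(d)
  assays <- read_viability_csv(path)
  expect_named(assays, c("A", "B"))
  expect_equal(nrow(assays$A), 15)
  expect_equal(attr(assays$B, "collection_year"), 2022)
  # observations arrive sorted by (time, replicate)
  expect_false(is.unsorted(assays$A$time))

  p <- data.frame(lot_id = "C", time_days = c(0, 1, 2),
                  replicate = 1, percent_viable = c(100, 50, 0))
  pc <- read_viability_csv(write_temp_csv(p))
  expect_equal(pc$C$viability, c(1, 0.5, 0))
})

test_that("malformed viability CSVs fail naming the offending row", {
  bad <- data.frame(lot_id = "A", time_days = 0:2, replicate = 1,
                    n_tested = 50, n_viable = c(50, 51, 10))
  expect_error(read_viability_csv(write_temp_csv(bad)), "row 2")
  neg <- data.frame(lot_id = "A", time_days = c(0, -1, 2), replicate = 1,
                    n_tested = 50, n_viable = 10)
  expect_error(read_viability_csv(write_temp_csv(neg)), "row 2")
  expect_error(
    read_viability_csv(write_temp_csv(data.frame(lot_id = "A", x = 1))),
    "missing column")
})

test_that("assay CSV round-trips through write and read", {
  a <- simulate_assay(c(2, 4, -0.3), rng_seed = 7, lot_id = "rt",
                      collection_year = 2020L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_viability_csv(a, path)
  back <- read_viability_csv(path)$rt
  expect_equal(back$time, a$time)
  expect_equal(back$n_viable, a$n_viable)
  expect_equal(attr(back, "collection_year"), 2020L)
})

test_that("information criteria reproduce the published convention", {
  ic <- information_criteria(0.096720, 7, 3)
  expect_equal(round(ic[["aic"]], 2), -23.97)
  expect_equal(round(ic[["bic"]], 2), -24.14)
  # the 4-parameter age curve on the same data
  expect_equal(round(information_criteria(0.3106016, 7, 4)[["aic"]], 2),
               -13.81)
  # ln(1) = 0 anchor
  expect_equal(unname(information_criteria(12, 12, 0)), c(0, 0))
  expect_error(information_criteria(0, 10, 2), "perfect fit")
  expect_error(information_criteria(1, 3, 3), "n > p")
})

test_that("criteria increase in p and obey the bic - aic identity", {
  set.seed(5)
  for (i in 1:20) {
    rss <- runif(1, 1e-4, 10); n <- sample(5:50, 1)
    p <- sample(0:(n - 2), 2)
    ic1 <- information_criteria(rss, n, min(p))
    ic2 <- information_criteria(rss, n, max(p))
    if (min(p) < max(p)) expect_lt(ic1[["aic"]], ic2[["aic"]])
    expect_equal(ic2[["bic"]] - ic2[["aic"]], max(p) * (log(n) - 2))
  }
})

test_that("fitting a noise-free published curve recovers its L50", {
  a <- noise_free_assay(gy_params)
  f <- fit_decay(a)
  expect_equal(l50(f)$l50, 1.5448947, tolerance = 0.02 / 1.54)
  expect_lt(f$rss, 1e-8)
  # the parameter triple may wander the ridge; the curve may not
  expect_equal(predict(f, 0:4), decay_viability(0:4, gy_params),
               tolerance = 1e-4)
})

test_that("fit recovers L50 from a binomially noisy assay", {
  a <- simulate_assay(c(2, 4, -0.3), rng_seed = 42)
  f <- fit_decay(a)
  expect_true(f$converged)
  expect_equal(l50(f)$l50, attr(a, "true_l50"), tolerance = 0.15 / 1.5)
})

test_that("refusal and degeneracy errors are explicit", {
  dead <- viability_assay(rep(0:4, each = 3), rep(1:3, 5),
                          n_tested = 50, n_viable = 0)
  expect_error(fit_decay(dead), "degenerate assay")
  two_tp <- viability_assay(rep(0:1, each = 3), rep(1:3, 2),
                            n_tested = 50, n_viable = c(rep(50, 3),
                                                        rep(10, 3)))
  expect_error(fit_decay(two_tp), "fewer than 3 distinct timepoints")
})

test_that("ridge-degenerate published-style fits are flagged, not altered", {
  a <- noise_free_assay(c(216.71, 551.84, -215.10), lot_id = "TY")
  f <- fit_decay(a)
  expect_true(f$condition_flag)
  expect_equal(l50(f)$l50, l50_closed_form(c(216.71, 551.84, -215.10))$l50,
               tolerance = 0.02)
})

test_that("refitting a fit's own predictions reproduces its L50", {
  a <- simulate_assay(c(2.2, 5, -0.4), rng_seed = 9)
  f <- fit_decay(a)
  clean <- viability_assay(a$time, a$replicate,
                           viability = predict(f), lot_id = "self")
  f2 <- fit_decay(clean)
  expect_equal(l50(f2)$l50, l50(f)$l50, tolerance = 1e-3)
})

test_that("three-parameter Weibull RSS never exceeds two-parameter RSS", {
  for (i in 1:12) {
    a <- simulate_assay(c(2 + 0.1 * i, 3 + (i %% 4), -0.5),
                        rng_seed = 100 + i)
    f3 <- fit_decay(a, "weibull3")
    f2 <- fit_decay(a, "weibull2")
    expect_lte(f3$rss, f2$rss)
  }
})

test_that("model comparison ranks by AIC with flagged failures", {
  a <- simulate_assay(c(2, 4, -0.5), rng_seed = 17)
  cmp <- compare_decay_models(a)
  expect_s3_class(cmp, "decay_comparison")
  expect_equal(nrow(cmp), 4)
  expect_true(all(is.finite(cmp$aic)))
  expect_false(is.unsorted(cmp$aic))
  expect_equal(cmp$delta_aic[1], 0)
  w3 <- cmp[cmp$family == "weibull3", ]
  w2 <- cmp[cmp$family == "weibull2", ]
  expect_lte(w3$rss, w2$rss)
  expect_error(compare_decay_models(a, "weibull3"), ">= 2 families")
})

test_that("best fits agree with a brute-force grid-search refit", {
  # dense grid over (L50, k, c) as an independent oracle for the minimum
  a <- simulate_assay(c(2, 4, -0.3), rng_seed = 23)
  grid <- expand.grid(l50 = seq(1.2, 1.8, by = 0.01),
                      k = c(2, 3, 4, 5, 6, 8, 12, 20, 50),
                      c = seq(-1.2, 0, by = 0.1))
  rss_grid <- min(vapply(seq_len(nrow(grid)), function(i) {
    lam <- lambda_for_l50(grid$l50[i], grid$k[i], grid$c[i])
    if (lam <= 0) return(Inf)
    v <- decay_viability(a$time, c(lam, grid$k[i], grid$c[i]))
    sum((a$viability - v)^2)
  }, numeric(1)))
  f <- fit_decay(a)
  expect_lte(f$rss, rss_grid + 1e-8)
})

test_that("means-level and weighted options fit plausibly", {
  a <- simulate_assay(c(2, 4, -0.3), rng_seed = 31)
  fm <- fit_decay(a, level = "means")
  expect_equal(fm$n_obs, 5)
  expect_equal(l50(fm)$l50, attr(a, "true_l50"), tolerance = 0.15)
  fw <- fit_decay(a, weights = "binomial")
  expect_equal(l50(fw)$l50, attr(a, "true_l50"), tolerance = 0.2)
})

test_that("decay_fit methods are coherent", {
  a <- simulate_assay(c(2, 4, -0.3), rng_seed = 3)
  f <- fit_decay(a)
  expect_named(coef(f), c("lambda", "k", "c"))
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-10)
  expect_equal(information_criteria(f$rss, f$n_obs, 3),
               c(aic = f$aic, bic = f$bic))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "viability_assay")
  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("RSS", out)))
})
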