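#' Median viability time of a fitted or given decay curve
#'
#' Generic accessor: for a `decay_fit` it returns the closed-form L50 of
#' the fitted curve; for a bare numeric parameter vector it dispatches to
#' [l50_closed_form()].
#'
#' @param x A `decay_fit` or numeric parameter vector.
#' @param ... `family` for the numeric method.
#' @return A list with `l50` (days) and `estimable` (logical).
#' @export
l50 <- function(x, ...) UseMethod("l50")

#' @export
l50.decay_fit <- function(x, ...) l50_closed_form(x$par, x$family)

#' @export
l50.numeric <- function(x, family = "weibull3", ...) {
  l50_closed_form(x, family)
}

#' L50 with a case-resampling bootstrap interval
#'
#' Point estimate is the closed-form L50 of the full-data fit. The 95\%
#' interval comes from a case-resampling bootstrap: within each timepoint
#' the replicate observations are resampled with replacement, the curve is
#' refit to each resampled dataset (warm-started from the full-data
#' solution), and an interval is built from the quantiles of the resulting
#' L50 values. Resamples whose fitted curve is already below 50\%
#' viability at time zero contribute an L50 of 0, matching the clamping
#' convention for not-estimable lots.
#'
#' Two constructions are offered. The default `"basic"` interval is the
#' reversed-percentile interval rescaled by the small-stratum factor
#' \eqn{\sqrt{m/(m-1)}} (m = replicates per timepoint): with only three
#' replicates per timepoint, case resampling deflates the bootstrap
#' variance by \eqn{(m-1)/m} and plain percentiles re-centre on the
#' estimator's small-sample bias, which together push coverage of a
#' nominal 95\% interval down to roughly 80\%; the basic construction
#' cancels the bias term to first order and the rescaling restores the
#' deflated variance. `"percentile"` gives the plain 2.5/97.5 percentile
#' interval. The interval is widened, if needed, to contain the point
#' estimate.
#'
#' @inheritParams fit_decay
#' @param b_boot Number of bootstrap resamples.
#' @param rng_seed Seed controlling the resampling.
#' @param conf Interval coverage (default 0.95).
#' @param interval Interval construction, `"basic"` (default) or
#'   `"percentile"`.
#' @return An object of class `"l50_estimate"`: list with `l50`,
#'   `estimable`, `ci_low`, `ci_high`, `b_boot`, `rng_seed`, `fit` and
#'   `single_replicate` (TRUE when no interval could be formed).
#' @export
l50_with_ci <- function(assay, family = "weibull3", b_boot = 1000,
                        rng_seed = 0, conf = 0.95, multistart = 32,
                        start_seed = 0,
                        interval = c("basic", "percentile")) {
  interval <- match.arg(interval)
  fit <- fit_decay(assay, family, multistart = multistart,
                   start_seed = start_seed)
  pt <- l50(fit)
  by_time <- split(seq_len(nrow(assay)), assay$time)
  single_rep <- any(vapply(by_time, length, integer(1)) < 2)
  ci <- c(NA_real_, NA_real_)
  if (!single_rep && b_boot > 0) {
    bounds <- .param_bounds(fit$family, assay$time)
    draws <- with_seed(rng_seed, {
      vapply(seq_len(b_boot), function(b) {
        idx <- unlist(lapply(by_time, function(i) {
          i[sample.int(length(i), length(i), replace = TRUE)]
        }), use.names = FALSE)
        tb <- assay$time[idx]
        vb <- assay$viability[idx]
        if (stats::sd(vb) == 0) {
          return(if (mean(vb) >= 0.5) NA_real_ else 0)
        }
        res <- .lm_one(fit$par, tb, vb, fit$family, bounds,
                       rep(1, length(vb)))
        if (is.null(res)) return(NA_real_)
        l50_closed_form(res$par, fit$family)$l50
      }, numeric(1))
    })
    draws <- draws[is.finite(draws)]
    if (length(draws) >= 10) {
      alpha <- (1 - conf) / 2
      # type 6 avoids the inward bias of sample tail quantiles at
      # moderate bootstrap sizes
      q <- unname(stats::quantile(draws, c(alpha, 1 - alpha), type = 6))
      if (interval == "percentile") {
        ci <- q
      } else {
        m <- min(vapply(by_time, length, integer(1)))
        s <- sqrt(m / (m - 1))
        ci <- c(pt$l50 - s * (q[2] - pt$l50), pt$l50 + s * (pt$l50 - q[1]))
      }
      ci <- c(max(0, min(ci[1], pt$l50)), max(ci[2], pt$l50))
    }
  }
  structure(list(l50 = pt$l50, estimable = pt$estimable,
                 ci_low = ci[1], ci_high = ci[2],
                 b_boot = b_boot, rng_seed = rng_seed,
                 single_replicate = single_rep, fit = fit),
            class = "l50_estimate")
}

#' @export
print.l50_estimate <- function(x, digits = 4, ...) {
  cat("L50:", if (x$estimable) format(x$l50, digits = digits)
      else "0 (n.e.)", "days")
  if (is.finite(x$ci_low)) {
    cat("  95% bootstrap interval (", format(x$ci_low, digits = digits),
        ", ", format(x$ci_high, digits = digits), ")  B = ", x$b_boot,
        sep = "")
  } else if (x$single_replicate) {
    cat("  [interval unavailable: fewer than 2 replicates per timepoint]")
  }
  cat("\n")
  invisible(x)
}

# ---- L50-vs-age regression -------------------------------------------------

#' Regress L50 on chronological seed age
#'
#' Fits either a second-order polynomial
#' `l50 = Intercept + B1 * age + B2 * age^2` by exact least squares or a
#' four-parameter Weibull-form curve
#' `l50 = A * exp(-((age + B) / C)^D)` by multistart nonlinear least
#' squares. Reports RSS, the plain coefficient of determination
#' `1 - RSS / TSS`, and RSS-based AIC/BIC with p = 3 or 4.
#'
#' @param points Data frame with columns `age` (years) and `l50` (days),
#'   or a formula-free pair of vectors via `age=`/`l50=`.
#' @param form `"quadratic"` or `"weibull4"`.
#' @param age,l50 Alternative vector interface.
#' @return Object of class `"l50_regression"`: `form`, `coefficients`,
#'   `rss`, `r_squared`, `aic`, `bic`, `n_points`, `points`.
#' @examples
#' pts <- solanum_age_l50()
#' l50_age_fit(pts)
#' @export
l50_age_fit <- function(points = NULL, form = c("quadratic", "weibull4"),
                        age = NULL, l50 = NULL) {
  form <- match.arg(form)
  if (is.null(points)) points <- data.frame(age = age, l50 = l50)
  if (!all(c("age", "l50") %in% names(points))) {
    stop("points must have columns 'age' and 'l50'", call. = FALSE)
  }
  x <- as.numeric(points$age); y <- as.numeric(points$l50)
  if (any(x < 0) || any(y < 0)) {
    stop("ages and L50 values must be non-negative", call. = FALSE)
  }
  n <- length(x)
  p <- if (form == "quadratic") 3L else 4L
  min_n <- p + 1L
  if (n < min_n) {
    stop("need at least ", min_n, " points for form '", form, "'",
         call. = FALSE)
  }
  if (form == "quadratic") {
    fit <- stats::lm(y ~ x + I(x^2))
    co <- stats::coef(fit)
    names(co) <- c("Intercept", "B1", "B2")
    res <- stats::resid(fit)
  } else {
    co <- .fit_weibull4(x, y)
    res <- y - .weibull4_curve(x, co)
  }
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  ic <- if (rss > 0) information_criteria(rss, n, p)
        else c(aic = -Inf, bic = -Inf)
  structure(list(form = form, coefficients = co, rss = rss,
                 r_squared = 1 - rss / tss,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 n_points = n, points = data.frame(age = x, l50 = y)),
            class = "l50_regression")
}

.weibull4_curve <- function(x, co) {
  co[["A"]] * exp(-((x + co[["B"]]) / co[["C"]])^co[["D"]])
}

.fit_weibull4 <- function(x, y) {
  lower <- c(1e-6, -min(x) + 1e-6, 1e-3, 1e-2)
  upper <- c(1e4, 1e4, 1e4, 50)
  starts <- expand.grid(A = c(max(y), 2 * max(y), 15),
                        B = c(1, 10, 25),
                        C = c(5, 20, 50),
                        D = c(1, 2.5, 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(p) {
          names(p) <- c("A", "B", "C", "D")
          y - .weibull4_curve(x, p)
        },
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300, ptol = 1e-13,
                                             ftol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(out)) {
      rss <- sum(out$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(par = out$par,
                                                        rss = rss)
    }
  }
  if (is.null(best)) stop("Weibull-form age regression failed to converge",
                          call. = FALSE)
  co <- best$par
  names(co) <- c("A", "B", "C", "D")
  co
}

#' Construct an L50-age regression from known coefficients
#'
#' Wraps externally supplied coefficients (for example values printed in a
#' report) as an `l50_regression` so they can be evaluated on data with
#' [evaluate_l50_regression()] or used with [longevity_bound()] and
#' [equivalent_age()] without refitting.
#'
#' @param coefficients Named numeric: `Intercept`, `B1`, `B2` for
#'   `form = "quadratic"`; `A`, `B`, `C`, `D` for `form = "weibull4"`.
#' @param form Regression form.
#' @return An `l50_regression` with empty fit statistics.
#' @export
as_l50_regression <- function(coefficients,
                              form = c("quadratic", "weibull4")) {
  form <- match.arg(form)
  want <- if (form == "quadratic") c("Intercept", "B1", "B2")
          else c("A", "B", "C", "D")
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(want)) {
    stop("form '", form, "' needs coefficients ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  names(coefficients) <- want
  structure(list(form = form, coefficients = coefficients, rss = NA_real_,
                 r_squared = NA_real_, aic = NA_real_, bic = NA_real_,
                 n_points = 0L, points = NULL),
            class = "l50_regression")
}

#' @export
print.l50_regression <- function(x, digits = 6, ...) {
  cat("L50-age regression (", x$form, "), n = ", x$n_points, "\n", sep = "")
  print(round(x$coefficients, digits))
  if (is.finite(x$rss)) {
    cat("RSS", format(x$rss, digits = digits),
        " R^2", format(x$r_squared, digits = digits),
        " AIC", format(x$aic, digits = digits),
        " BIC", format(x$bic, digits = digits), "\n")
  }
  if (x$form == "quadratic") {
    b <- longevity_bound(x)
    if (b$crossing) {
      cat("L50 reaches zero at", format(b$root_small, digits = digits),
          "and", format(b$root_large, digits = digits), "years\n")
    }
  }
  invisible(x)
}

#' @export
coef.l50_regression <- function(object, ...) object$coefficients

#' @export
predict.l50_regression <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$age
       else if (is.data.frame(newdata)) newdata$age
       else as.numeric(newdata)
  co <- object$coefficients
  if (object$form == "quadratic") {
    co[["Intercept"]] + co[["B1"]] * x + co[["B2"]] * x^2
  } else {
    .weibull4_curve(x, co)
  }
}

#' @export
plot.l50_regression <- function(x, ...) {
  if (is.null(x$points)) stop("regression carries no points to plot",
                              call. = FALSE)
  graphics::plot(x$points$age, x$points$l50, xlab = "Seed age (years)",
                 ylab = "L50 (days)", ...)
  xx <- seq(0, max(x$points$age) * 1.1, length.out = 200)
  graphics::lines(xx, predict(x, xx))
  invisible(x)
}

#' Residual metrics of a fixed regression curve on data
#'
#' Evaluates a regression curve (fitted here or built from published
#' coefficients with [as_l50_regression()]) on a set of (age, L50) points
#' without refitting, returning RSS, the coefficient of determination and
#' RSS-based information criteria with p = 3 (quadratic) or 4 (Weibull
#' form).
#'
#' @param reg An `l50_regression`.
#' @param points Data frame with `age` and `l50`.
#' @return List with `rss`, `r_squared`, `aic`, `bic`, `n`.
#' @export
evaluate_l50_regression <- function(reg, points) {
  stopifnot(inherits(reg, "l50_regression"))
  y <- as.numeric(points$l50)
  yhat <- predict(reg, points)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- if (reg$form == "quadratic") 3L else 4L
  ic <- if (rss > 0) information_criteria(rss, n, p)
        else c(aic = -Inf, bic = -Inf)
  list(rss = rss, r_squared = 1 - rss / tss, aic = unname(ic["aic"]),
       bic = unname(ic["bic"]), n = n)
}

#' Longevity bound: roots of the quadratic L50-age regression
#'
#' Solves `Intercept + B1 * age + B2 * age^2 = 0`. The smaller positive
#' root is designated the longevity upper-bound estimate: beyond it the
#' regression predicts no lot retains 50\% viability, and germination
#' evidence (old cohorts failing to germinate) rules out the region past
#' the larger root. Both roots are always reported.
#'
#' @param reg An `l50_regression` with `form = "quadratic"`.
#' @return List with `root_small`, `root_large`, `bound`
#'   (= `root_small`), and `crossing` (FALSE when the discriminant is
#'   negative, i.e. the curve never reaches zero).
#' @examples
#' longevity_bound(l50_age_fit(solanum_age_l50()))
#' @export
longevity_bound <- function(reg) {
  stopifnot(inherits(reg, "l50_regression"))
  if (reg$form != "quadratic") {
    stop("longevity_bound requires the quadratic form", call. = FALSE)
  }
  co <- reg$coefficients
  a <- co[["B2"]]; b <- co[["B1"]]; cc <- co[["Intercept"]]
  if (a == 0 && b == 0) {
    stop("degenerate regression: no age dependence", call. = FALSE)
  }
  if (a == 0) {
    r <- -cc / b
    return(list(root_small = r, root_large = r, bound = r,
                crossing = TRUE))
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    return(list(root_small = NA_real_, root_large = NA_real_,
                bound = NA_real_, crossing = FALSE))
  }
  roots <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  list(root_small = roots[1], root_large = roots[2], bound = roots[1],
       crossing = TRUE)
}

#' Equivalent storage age of an observed L50
#'
#' Inverts the quadratic regression: given an L50 measured on a lot of
#' unknown history (for example a soil seed bank sample), returns the
#' storage age whose expected L50 matches it — the smaller solution of
#' `Intercept + B1 * age + B2 * age^2 = l50` lying between 0 and the
#' longevity bound.
#'
#' @param reg Quadratic `l50_regression`.
#' @param l50 Observed L50 in days, `0 < l50 <= Intercept`.
#' @return Age in years.
#' @examples
#' reg <- l50_age_fit(solanum_age_l50())
#' equivalent_age(reg, 1.59)
#' @export
equivalent_age <- function(reg, l50) {
  stopifnot(inherits(reg, "l50_regression"))
  if (reg$form != "quadratic") {
    stop("equivalent_age requires the quadratic form", call. = FALSE)
  }
  co <- reg$coefficients
  if (l50 <= 0) stop("l50 must be positive", call. = FALSE)
  # rounded published intercepts may overshoot the fitted one slightly
  tol <- 1e-6 * max(1, abs(co[["Intercept"]]))
  if (l50 > co[["Intercept"]] + tol) {
    stop("l50 exceeds the age-0 intercept: lot is fresher than the ",
         "age-0 reference", call. = FALSE)
  }
  l50 <- min(l50, co[["Intercept"]])
  shifted <- as_l50_regression(c(co[["Intercept"]] - l50, co[["B1"]],
                                 co[["B2"]]), "quadratic")
  b <- longevity_bound(shifted)
  if (!b$crossing) stop("regression never attains this l50", call. = FALSE)
  upper <- longevity_bound(reg)$root_small
  cand <- c(b$root_small, b$root_large)
  cand <- cand[cand >= -1e-9 & cand <= upper + 1e-9]
  if (!length(cand)) stop("no age in [0, bound] attains this l50",
                          call. = FALSE)
  max(min(cand), 0)
}

# ---- validation statistics -------------------------------------------------

#' One-way analysis of variance on replicate-level values
#'
#' Classical fixed-effects one-way ANOVA, used to compare replicate-level
#' L50 values across populations or collection years. Returns the F
#' statistic, degrees of freedom, upper-tail p-value and the full
#' sum-of-squares decomposition.
#'
#' @param groups A named list of numeric vectors (one per group, each of
#'   length >= 2).
#' @return List with `F`, `df_between`, `df_within`, `p`, `ss_between`,
#'   `ss_within`, `ss_total`, and `undefined` (TRUE when both between- and
#'   within-group variation are zero).
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) stop("every group needs >= 2 values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ss_b <- tab$`Sum Sq`[1]; ss_w <- tab$`Sum Sq`[2]
  if (ss_b < .Machine$double.eps * sum(y^2) &&
      ss_w < .Machine$double.eps * sum(y^2)) {
    return(list(F = NA_real_, df_between = tab$Df[1],
                df_within = tab$Df[2], p = NA_real_, ss_between = ss_b,
                ss_within = ss_w, ss_total = ss_b + ss_w,
                undefined = TRUE))
  }
  list(F = tab$`F value`[1], df_between = tab$Df[1],
       df_within = tab$Df[2], p = tab$`Pr(>F)`[1], ss_between = ss_b,
       ss_within = ss_w, ss_total = ss_b + ss_w, undefined = FALSE)
}

# Compact-letter display from a matrix of pairwise "significantly
# different" indicators over groups sorted by mean (descending). Uses the
# contiguous-range construction: each letter covers a maximal run of
# mean-adjacent groups with no significant difference inside the run.
.cld_letters <- function(means, sig) {
  k <- length(means)
  ord <- order(means)
  runs <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k) {
      block <- ord[i:(j + 1)]
      pairs <- utils::combn(block, 2)
      ok <- !any(apply(pairs, 2, function(pr) sig[pr[1], pr[2]]))
      if (ok) j <- j + 1 else break
    }
    runs[[length(runs) + 1]] <- ord[i:j]
    i <- if (j == k) k + 1 else i + 1
  }
  # absorb runs nested in an earlier run
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) {
    for (b in seq_along(runs)) {
      if (a != b && keep[a] && all(runs[[a]] %in% runs[[b]]) &&
          length(runs[[a]]) < length(runs[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  runs <- runs[keep]
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    for (gi in runs[[r]]) {
      letters_out[gi] <- paste0(letters_out[gi], letters[r])
    }
  }
  letters_out
}

#' Summarise germination trials with Tukey HSD letters
#'
#' Per-cohort mean and sample standard deviation of replicate germination
#' percentages, with a compact-letter display from Tukey's HSD at
#' `alpha = 0.05` following one-way ANOVA: cohorts sharing a letter do not
#' differ significantly.
#'
#' @param trials Named list of numeric vectors of replicate germination
#'   percentages (each in \[0, 100\], length >= 2), or a data frame with
#'   columns `cohort` and `percent_germinated`.
#' @param alpha Significance level for the letter display.
#' @return Data frame with `cohort`, `n`, `mean`, `sd`, `letter`.
#' @examples
#' germination_summary(list(`2008` = rep(0, 6),
#'                          `2015` = c(10, 6.67, 13.33, 6.67, 16.67, 10),
#'                          `2023` = c(83.33, 93.33, 86.67, 80, 83.33,
#'                                     93.33)))
#' @export
germination_summary <- function(trials, alpha = 0.05) {
  if (is.data.frame(trials)) {
    trials <- split(trials$percent_germinated, trials$cohort)
  }
  if (length(trials) < 1) stop("no trials supplied", call. = FALSE)
  sizes <- vapply(trials, length, integer(1))
  if (any(sizes < 2)) stop("every cohort needs >= 2 replicates",
                           call. = FALSE)
  vals <- unlist(trials, use.names = FALSE)
  if (any(vals < 0 | vals > 100)) {
    stop("germination percentages must lie in [0, 100]", call. = FALSE)
  }
  cohorts <- names(trials)
  if (is.null(cohorts)) cohorts <- as.character(seq_along(trials))
  means <- vapply(trials, mean, numeric(1))
  sds <- vapply(trials, stats::sd, numeric(1))
  letter <- rep("a", length(trials))
  if (length(trials) >= 2 && stats::sd(vals) > 0) {
    g <- factor(rep(cohorts, sizes), levels = cohorts)
    fit <- stats::aov(vals ~ g)
    hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    sig <- matrix(FALSE, length(trials), length(trials))
    pair_names <- rownames(hsd)
    for (r in seq_len(nrow(hsd))) {
      pr <- strsplit(pair_names[r], "-", fixed = TRUE)[[1]]
      i <- match(pr[1], cohorts); j <- match(pr[2], cohorts)
      if (!is.na(i) && !is.na(j) && hsd[r, "p adj"] < alpha) {
        sig[i, j] <- sig[j, i] <- TRUE
      }
    }
    letter <- .cld_letters(means, sig)
  }
  data.frame(cohort = cohorts, n = sizes, mean = means, sd = sds,
             letter = letter, row.names = NULL,
             stringsAsFactors = FALSE)
}
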