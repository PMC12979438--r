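#' RSS-based information criteria
#'
#' Akaike and Bayesian information criteria computed from a residual sum
#' of squares, the convention used throughout for ranking decay curves and
#' longevity regressions: `AIC = n ln(RSS/n) + 2p`,
#' `BIC = n ln(RSS/n) + p ln(n)`, with `p` the number of fitted curve
#' parameters (no additional variance parameter).
#'
#' @param rss Residual sum of squares, `> 0`.
#' @param n Number of residuals, `> p`.
#' @param p Number of fitted parameters, `>= 0`.
#' @return Named numeric vector `c(aic = , bic = )`.
#' @examples
#' information_criteria(0.096720, 7, 3)  # c(-23.97, -24.14)
#' @export
information_criteria <- function(rss, n, p) {
  if (!is.finite(rss) || rss < 0) stop("rss must be non-negative",
                                       call. = FALSE)
  if (rss == 0) {
    stop("rss is exactly 0: report a perfect fit instead of AIC/BIC",
         call. = FALSE)
  }
  if (p < 0 || n <= p) stop("need n > p >= 0", call. = FALSE)
  base <- n * log(rss / n)
  c(aic = base + 2 * p, bic = base + p * log(n))
}

# ---- multistart initial values --------------------------------------------

# Time at which linearly-interpolated mean viability crosses 0.5
# (fallback: median observation time).
.crossing_time <- function(time, viability) {
  tt <- sort(unique(time))
  vv <- vapply(tt, function(t) mean(viability[time == t]), numeric(1))
  above <- vv >= 0.5
  if (all(above) || all(!above)) return(stats::median(time))
  i <- which(above)[sum(above)]          # last timepoint still >= 0.5
  if (i >= length(tt)) return(stats::median(time))
  t0 <- tt[i]; t1 <- tt[i + 1L]; v0 <- vv[i]; v1 <- vv[i + 1L]
  if (v0 == v1) return((t0 + t1) / 2)
  t0 + (0.5 - v0) * (t1 - t0) / (v1 - v0)
}

.start_grid <- function(family, time, viability) {
  m <- max(.crossing_time(time, viability), 1e-3)
  vmax <- min(max(viability), 1)
  switch(family,
    weibull3 = {
      ks <- c(0.5, 1, 2, 5, 20, 100, 300)
      lams <- c(m + 0.5, 2 * m + 1, 10 * (m + 1))
      g <- expand.grid(lambda = lams, k = ks)
      g$c <- m - g$lambda * log(2)^(1 / g$k)
      g[, c("lambda", "k", "c")]
    },
    weibull2 = {
      ks <- c(0.5, 1, 2, 5, 20, 100, 300)
      g <- expand.grid(k = ks)
      g$lambda <- m / log(2)^(1 / g$k)
      g[, c("lambda", "k")]
    },
    logistic = {
      g <- expand.grid(A = unique(c(vmax, 1)), r = c(0.5, 1, 2, 5, 10))
      g$m <- m
      g[, c("A", "m", "r")]
    },
    gompertz = {
      g <- expand.grid(A = unique(c(vmax, 1)), g = c(0.5, 1, 2, 5))
      # pick b so the start curve passes 0.5 at the crossing time
      g$b <- pmax(log(pmax(2 * g$A, 1.0001)) * exp(-g$g * m), 1e-6)
      g[, c("A", "b", "g")]
    }
  )
}

.param_bounds <- function(family, time) {
  tmin <- min(time)
  switch(family,
    # c upper bound is min(t) inclusive so weibull2 (c = 0) is exactly
    # nested when the series starts at time 0
    weibull3 = list(lower = c(1e-3, 1e-2, -1e4),
                    upper = c(1e4, 1e4, tmin)),
    weibull2 = list(lower = c(1e-3, 1e-2), upper = c(1e4, 1e4)),
    logistic = list(lower = c(1e-6, -100, 1e-3),
                    upper = c(1, max(time) + 100, 100)),
    gompertz = list(lower = c(1e-6, 1e-8, 1e-3),
                    upper = c(1, 1e6, 100))
  )
}

# One bounded Levenberg-Marquardt descent; returns NULL on hard failure.
# Exploratory starts use loose tolerances; the winner is re-polished with
# tight ones (see fit_decay).
.lm_one <- function(start, time, viability, family, bounds, weights,
                    maxiter = 200, tol = 1e-12) {
  sw <- sqrt(weights)
  resid_fn <- function(p) {
    v <- .curve_eval(time, p, family)
    if (anyNA(v)) return(rep(1e6, length(time)))
    (viability - v) * sw
  }
  out <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = as.numeric(start), fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = tol, ftol = tol))),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(par = out$par, rss = sum(out$fvec^2), info = out$info,
       hessian = out$hessian, deviance = out$deviance)
}

#' Fit a viability-decay curve to an assay
#'
#' Minimises the sum of squared residuals between replicate-level observed
#' viability fractions and the decay curve, using bounded
#' Levenberg-Marquardt descent from a deterministic grid of starting
#' values (shape values spanning 0.5-300 crossed with scale values tied to
#' the interpolated 50\%-crossing time), optionally augmented with seeded
#' jittered starts up to `multistart`. The best solution over all starts
#' is returned. The three-parameter Weibull objective has a flat ridge in
#' (lambda, k, c) — individual parameters can be wildly uncertain while the
#' fitted curve and its L50 are sharp; such fits are flagged, not altered.
#'
#' @param assay A [viability_assay()].
#' @param family Curve family (see [decay_families()]).
#' @param multistart Total number of starts; the deterministic grid is
#'   always used, and seeded jitters around the best grid start top it up.
#' @param start_seed Seed for the jittered extra starts.
#' @param level `"replicate"` (default) fits all replicate observations;
#'   `"means"` fits per-timepoint mean viability (sensitivity analysis).
#' @param weights `"none"` (default, ordinary least squares) or
#'   `"binomial"` for inverse-variance weights `n/(v(1-v))` bounded away
#'   from infinity.
#' @return An object of class `"decay_fit"` with components `family`,
#'   `par` (named), `rss`, `n_obs`, `aic`, `bic`, `converged`,
#'   `condition_flag`, `data` and the source `assay`.
#' @examples
#' a <- simulate_assay(c(2, 4, -0.3), timepoints = 0:4, rng_seed = 1)
#' f <- fit_decay(a)
#' coef(f); l50(f)
#' @export
fit_decay <- function(assay, family = "weibull3", multistart = 32,
                      start_seed = 0, level = c("replicate", "means"),
                      weights = c("none", "binomial")) {
  stopifnot(inherits(assay, "viability_assay"))
  level <- match.arg(level)
  weights <- match.arg(weights)
  if (length(unique(assay$time)) < 3) {
    stop("assay has fewer than 3 distinct timepoints; refusing to fit",
         call. = FALSE)
  }
  if (level == "means") {
    tt <- sort(unique(assay$time))
    vv <- vapply(tt, function(t) mean(assay$viability[assay$time == t]),
                 numeric(1))
    time <- tt; viability <- vv
  } else {
    time <- assay$time; viability <- assay$viability
  }
  if (stats::sd(viability) == 0) {
    stop("degenerate assay: all observations have identical viability",
         call. = FALSE)
  }
  p <- n_decay_params(family)
  n <- length(viability)
  if (n < p + 1) stop("need at least ", p + 1, " observations for family '",
                      family, "'", call. = FALSE)
  w <- if (weights == "binomial") {
    nt <- if (all(is.finite(assay$n_tested))) assay$n_tested else 50
    v_clamped <- pmin(pmax(viability, 0.02), 0.98)
    nt / (v_clamped * (1 - v_clamped))
  } else {
    rep(1, n)
  }

  bounds <- .param_bounds(family, time)
  starts <- .start_grid(family, time, viability)
  # clamp starts into bounds
  for (j in seq_len(ncol(starts))) {
    starts[[j]] <- pmin(pmax(starts[[j]], bounds$lower[j]), bounds$upper[j])
  }
  # nested start: embed the best two-parameter solution when fitting the
  # three-parameter Weibull, guaranteeing RSS dominance
  if (family == "weibull3") {
    f2 <- tryCatch(
      fit_decay(assay, "weibull2", multistart = multistart,
                start_seed = start_seed, level = level, weights = weights),
      error = function(e) NULL)
    if (!is.null(f2)) {
      starts <- rbind(starts,
                      data.frame(lambda = f2$par[["lambda"]],
                                 k = f2$par[["k"]],
                                 c = min(0, bounds$upper[3])))
    }
  }
  fits <- lapply(seq_len(nrow(starts)),
                 function(i) .lm_one(starts[i, ], time, viability, family,
                                     bounds, w, maxiter = 80, tol = 1e-9))
  fits <- Filter(Negate(is.null), fits)
  if (multistart > nrow(starts) && length(fits)) {
    best0 <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
    extra <- with_seed(start_seed, {
      lapply(seq_len(multistart - nrow(starts)), function(i) {
        jit <- best0$par * exp(stats::rnorm(length(best0$par), 0, 0.3))
        jit <- pmin(pmax(jit, bounds$lower), bounds$upper)
        .lm_one(jit, time, viability, family, bounds, w,
                maxiter = 80, tol = 1e-9)
      })
    })
    fits <- c(fits, Filter(Negate(is.null), extra))
  }
  if (!length(fits)) {
    stop("no start converged for family '", family, "' on lot '",
         attr(assay, "lot_id"), "'", call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  polished <- .lm_one(best$par, time, viability, family, bounds, w)
  if (!is.null(polished) && polished$rss <= best$rss) best <- polished
  par <- best$par
  names(par) <- .family_par_names(family)
  rss <- best$rss
  ic <- if (rss > 0) information_criteria(rss, n, p)
        else c(aic = -Inf, bic = -Inf)

  # Ridge diagnosis from the Gauss-Newton Hessian: flag when the relative
  # parameter uncertainty exceeds 1e3, or (scale-invariantly, so that
  # noise-free data do not mask the ridge) when the parameter-scaled
  # Hessian is numerically singular.
  condition_flag <- TRUE
  se <- rep(NA_real_, p)
  H <- best$hessian
  if (!is.null(H) && all(is.finite(H))) {
    D <- diag(pmax(abs(par), 1e-12), p)
    rc <- tryCatch(rcond(D %*% H %*% D), error = function(e) 0)
    condition_flag <- rc < 1e-10
    if (n > p && rss > 0) {
      sigma2 <- rss / (n - p)
      covm <- tryCatch(solve(H) * sigma2, error = function(e) NULL)
      if (!is.null(covm) && all(is.finite(diag(covm))) &&
          all(diag(covm) >= 0)) {
        se <- sqrt(diag(covm))
        rel <- se / pmax(abs(par), 1e-12)
        condition_flag <- condition_flag || any(rel > 1e3)
      }
    }
  }
  structure(list(family = family, par = par, rss = rss, n_obs = n,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 converged = best$info %in% 1:3,
                 condition_flag = condition_flag,
                 se = se, level = level, weights = weights,
                 data = data.frame(time = time, viability = viability),
                 assay = assay),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Decay-curve fit (", x$family, ") for lot '",
      attr(x$assay, "lot_id"), "'\n", sep = "")
  print(round(x$par, digits))
  l <- l50(x)
  cat("RSS:", format(x$rss, digits = digits),
      " AIC:", format(x$aic, digits = digits),
      " BIC:", format(x$bic, digits = digits), "\n")
  cat("L50:", if (l$estimable) format(l$l50, digits = digits)
      else "0 (n.e.)", "days\n")
  if (x$condition_flag) {
    cat("note: parameters lie on a flat ridge (curve and L50 remain",
        "well determined)\n")
  }
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  l <- l50(object)
  out <- list(family = object$family,
              coefficients = cbind(Estimate = object$par,
                                   `Std. Error` = object$se),
              rss = object$rss, n_obs = object$n_obs,
              aic = object$aic, bic = object$bic,
              l50 = l$l50, l50_estimable = l$estimable,
              converged = object$converged,
              condition_flag = object$condition_flag)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  cat("Family:", x$family, "\n")
  print(round(x$coefficients, digits))
  cat("RSS", format(x$rss, digits = digits), "on", x$n_obs,
      "observations; AIC", format(x$aic, digits = digits), "BIC",
      format(x$bic, digits = digits), "\n")
  cat("L50:", if (x$l50_estimable) format(x$l50, digits = digits)
      else "0 (n.e.)", "days\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$par

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.data.frame(newdata)) newdata$time
       else as.numeric(newdata)
  decay_viability(t, object$par, object$family)
}

#' @export
fitted.decay_fit <- function(object, ...) predict(object)

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$viability - fitted(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$viability, xlab = "Aging time (days)",
                 ylab = "Viability (fraction)", ylim = c(0, 1), ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
  graphics::lines(tt, decay_viability(tt, x$par, x$family))
  l <- l50(x)
  if (l$estimable) graphics::abline(v = l$l50, h = 0.5, lty = 3)
  invisible(x)
}

#' Simulate new assays from a fitted decay curve
#'
#' Draws binomial viable counts along the fitted curve at the fitted
#' design's timepoints, mirroring the assay layout.
#'
#' @param object A `decay_fit`.
#' @param nsim Number of simulated assays.
#' @param seed RNG seed (restored on exit).
#' @param ... Unused.
#' @return A list of [viability_assay()] objects of length `nsim`.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = 0, ...) {
  a <- object$assay
  reps <- length(unique(a$replicate))
  n_seeds <- if (all(is.finite(a$n_tested))) round(stats::median(a$n_tested))
             else 50
  tps <- sort(unique(a$time))
  lapply(seq_len(nsim), function(i) {
    simulate_assay(object$par, family = object$family, timepoints = tps,
                   replicates = reps, seeds_per_replicate = n_seeds,
                   rng_seed = seed + i - 1,
                   lot_id = paste0(attr(a, "lot_id"), "_sim", i))
  })
}

#' Compare candidate decay families on one assay
#'
#' Fits each requested family and ranks the fits by RSS-based AIC
#' (ascending), breaking ties by fewer parameters then family name.
#' Per-family fitting failures become flagged rows rather than errors.
#'
#' @inheritParams fit_decay
#' @param families Character vector of at least two family names.
#' @return A data frame of class `"decay_comparison"` with columns
#'   `family`, `n_par`, `rss`, `aic`, `bic`, `delta_aic`, `l50`,
#'   `l50_estimable`, `converged`, `error`, plus the fits in
#'   `attr(, "fits")`.
#' @export
compare_decay_models <- function(assay,
                                 families = c("weibull3", "weibull2",
                                              "logistic", "gompertz"),
                                 multistart = 32, start_seed = 0,
                                 level = "replicate") {
  families <- unique(families)
  if (length(families) < 2) {
    stop("need >= 2 families to compare", call. = FALSE)
  }
  fits <- lapply(families, function(fam) {
    tryCatch(fit_decay(assay, fam, multistart = multistart,
                       start_seed = start_seed, level = level),
             error = function(e) conditionMessage(e))
  })
  rows <- lapply(seq_along(families), function(i) {
    f <- fits[[i]]
    if (is.character(f)) {
      data.frame(family = families[i], n_par = n_decay_params(families[i]),
                 rss = NA_real_, aic = NA_real_, bic = NA_real_,
                 l50 = NA_real_, l50_estimable = NA, converged = FALSE,
                 error = f, stringsAsFactors = FALSE)
    } else {
      l <- l50(f)
      data.frame(family = f$family, n_par = length(f$par), rss = f$rss,
                 aic = f$aic, bic = f$bic, l50 = l$l50,
                 l50_estimable = l$estimable, converged = f$converged,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  ord <- order(is.na(tab$aic), tab$aic, tab$n_par, tab$family)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab <- tab[, c("family", "n_par", "rss", "aic", "bic", "delta_aic",
                 "l50", "l50_estimable", "converged", "error")]
  structure(tab, fits = fits[ord], class = c("decay_comparison",
                                             "data.frame"))
}

#' @export
print.decay_comparison <- function(x, digits = 4, ...) {
  cat("Decay-model comparison (ranked by AIC)\n")
  y <- as.data.frame(x)
  y$error <- ifelse(is.na(y$error), "", y$error)
  print(format(y, digits = digits), row.names = FALSE)
  invisible(x)
}
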