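#' Read (age, L50) pairs from CSV
#'
#' Expects header columns `age_years,l50_days`.
#'
#' @param path CSV path.
#' @return Data frame with columns `age`, `l50`.
#' @export
read_age_l50_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age_years", "l50_days") %in% names(d))) {
    stop("age-L50 CSV needs columns age_years,l50_days", call. = FALSE)
  }
  data.frame(age = d$age_years, l50 = d$l50_days)
}

#' Read germination replicates from CSV
#'
#' Expects header columns `cohort,replicate,percent_germinated`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [germination_summary()].
#' @export
read_germination_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("cohort", "replicate", "percent_germinated")
  if (!all(need %in% names(d))) {
    stop("germination CSV needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  d$percent_germinated <- as.numeric(d$percent_germinated)
  d
}

#' Write a JSON report
#'
#' Serialises any report list with package version and unboxed scalars,
#' so every writer's output round-trips through [jsonlite::fromJSON()].
#'
#' @param x Report list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  x$package_version <- as.character(utils::packageVersion("seedaging"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' JSON-ready fit report for one decay fit
#'
#' @param fit A `decay_fit`.
#' @param l50_est Optional [l50_with_ci()] result to include interval
#'   fields.
#' @return A plain list (family, params, rss, n, aic, bic, l50, flags).
#' @export
fit_report <- function(fit, l50_est = NULL) {
  l <- if (is.null(l50_est)) l50(fit) else l50_est
  rep <- list(lot_id = attr(fit$assay, "lot_id"),
              family = fit$family,
              params = as.list(fit$par),
              rss = fit$rss, n = fit$n_obs,
              aic = fit$aic, bic = fit$bic,
              l50 = l$l50, l50_estimable = l$estimable,
              converged = fit$converged,
              condition_flag = fit$condition_flag)
  if (!is.null(l50_est)) {
    rep$ci_low <- l50_est$ci_low
    rep$ci_high <- l50_est$ci_high
    rep$b_boot <- l50_est$b_boot
    rep$rng_seed <- l50_est$rng_seed
  }
  rep
}

#' Run the full longevity pipeline
#'
#' One-shot chain on a set of assays: fit the decay curve per lot, extract
#' L50 (with bootstrap interval when requested), map collection years to
#' seed age (`age = test_year - collection_year`), regress L50 on age,
#' extract the longevity bound by root finding, and optionally attach a
#' germination-validation summary.
#'
#' @param assays Named list of [viability_assay()] objects (as returned by
#'   [read_viability_csv()]), each carrying a `collection_year`; or a list
#'   as returned by [simulate_cohort_series()] (ages taken directly).
#' @param germination Optional germination data frame (see
#'   [read_germination_csv()]).
#' @param family Decay family to fit.
#' @param b_boot Bootstrap resamples per lot (0 skips intervals).
#' @param rng_seed Seed for all stochastic stages.
#' @param test_year Year the assays were run, for the age mapping.
#' @return Object of class `"longevity_pipeline"`: per-lot `fits` and
#'   `l50_table`, the `regression`, the `bound`, optional
#'   `germination`, and the seed.
#' @export
run_longevity_pipeline <- function(assays, germination = NULL,
                                   family = "weibull3", b_boot = 0,
                                   rng_seed = 0, test_year = 2023) {
  cohort <- length(assays) && is.list(assays[[1]]) &&
    !inherits(assays[[1]], "viability_assay") &&
    !is.null(assays[[1]]$assay)
  items <- if (cohort) {
    lapply(assays, function(s) list(age = s$age, assay = s$assay))
  } else {
    lapply(assays, function(a) {
      yr <- attr(a, "collection_year")
      age <- if (is.na(yr)) NA_real_ else test_year - yr
      list(age = age, assay = a)
    })
  }
  rows <- list(); fits <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    est <- l50_with_ci(it$assay, family, b_boot = b_boot,
                       rng_seed = rng_seed + i)
    fits[[attr(it$assay, "lot_id")]] <- est$fit
    rows[[i]] <- data.frame(lot_id = attr(it$assay, "lot_id"),
                            age = it$age, l50 = est$l50,
                            estimable = est$estimable,
                            ci_low = est$ci_low, ci_high = est$ci_high)
  }
  l50_table <- do.call(rbind, rows)
  reg <- NULL; bound <- NULL
  usable <- l50_table[is.finite(l50_table$age), , drop = FALSE]
  if (nrow(usable) >= 4) {
    reg <- l50_age_fit(data.frame(age = usable$age, l50 = usable$l50))
    bound <- longevity_bound(reg)
  }
  germ <- if (!is.null(germination)) germination_summary(germination)
          else NULL
  structure(list(l50_table = l50_table, fits = fits, regression = reg,
                 bound = bound, germination = germ, family = family,
                 rng_seed = rng_seed, test_year = test_year),
            class = "longevity_pipeline")
}

#' @export
print.longevity_pipeline <- function(x, digits = 4, ...) {
  cat("Longevity pipeline (", x$family, " fits, seed ", x$rng_seed,
      ")\n", sep = "")
  print(format(x$l50_table, digits = digits), row.names = FALSE)
  if (!is.null(x$regression)) {
    cat("\n")
    print(x$regression, digits = digits)
  }
  if (!is.null(x$bound)) {
    if (x$bound$crossing) {
      cat("Longevity upper bound:", format(x$bound$bound, digits = digits),
          "years\n")
    } else {
      cat("Fitted quadratic does not reach zero L50:",
          "no longevity upper bound on this series\n")
    }
  }
  if (!is.null(x$germination)) {
    cat("\nGermination validation:\n")
    print(format(x$germination, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits a JSON report and a markdown summary (per-lot L50 table,
#' regression coefficients, both roots and the designated bound,
#' germination letters) into a directory.
#'
#' @param pipeline A `longevity_pipeline`.
#' @param dir Output directory (created if absent).
#' @return Paths of the files written, invisibly.
#' @export
write_pipeline_report <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "longevity_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "longevity_report.json")
  md_path <- file.path(dir, "longevity_report.md")
  rep <- list(
    family = pipeline$family,
    rng_seed = pipeline$rng_seed,
    test_year = pipeline$test_year,
    l50_table = pipeline$l50_table,
    fits = lapply(pipeline$fits, fit_report)
  )
  if (!is.null(pipeline$regression)) {
    r <- pipeline$regression
    rep$regression <- list(form = r$form,
                           coefficients = as.list(r$coefficients),
                           rss = r$rss, r_squared = r$r_squared,
                           aic = r$aic, bic = r$bic,
                           n_points = r$n_points)
  }
  if (!is.null(pipeline$bound)) rep$bound <- pipeline$bound
  if (!is.null(pipeline$germination)) rep$germination <- pipeline$germination
  write_json_report(rep, json_path)

  con <- file(md_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# Seed longevity report")
  w("")
  w("## Per-lot L50 (", pipeline$family, " fits)")
  w("")
  w("| lot | age (y) | L50 (d) | 95% interval |")
  w("|---|---|---|---|")
  tb <- pipeline$l50_table
  for (i in seq_len(nrow(tb))) {
    ci <- if (is.finite(tb$ci_low[i])) {
      sprintf("(%.2f, %.2f)", tb$ci_low[i], tb$ci_high[i])
    } else {
      "-"
    }
    l50txt <- if (tb$estimable[i]) sprintf("%.2f", tb$l50[i]) else "0 n.e."
    w("| ", tb$lot_id[i], " | ", tb$age[i], " | ", l50txt, " | ", ci, " |")
  }
  if (!is.null(pipeline$regression)) {
    r <- pipeline$regression
    w("")
    w("## L50-age regression (", r$form, ")")
    w("")
    co <- r$coefficients
    w("`l50 = ", sprintf("%.6f %+.6f*age %+.6f*age^2",
                         co[["Intercept"]], co[["B1"]], co[["B2"]]), "`")
    w("")
    w(sprintf("RSS %.6f, R^2 %.5f, AIC %.2f, BIC %.2f",
              r$rss, r$r_squared, r$aic, r$bic))
  }
  if (!is.null(pipeline$bound) && pipeline$bound$crossing) {
    w("")
    w(sprintf(paste0("L50 extrapolates to zero at %.2f and %.2f years; ",
                     "the smaller root is the longevity upper bound."),
              pipeline$bound$root_small, pipeline$bound$root_large))
  }
  if (!is.null(pipeline$germination)) {
    g <- pipeline$germination
    w("")
    w("## Germination validation")
    w("")
    w("| cohort | n | mean (%) | sd | letters |")
    w("|---|---|---|---|---|")
    for (i in seq_len(nrow(g))) {
      w("| ", g$cohort[i], " | ", g$n[i], " | ",
        sprintf("%.2f", g$mean[i]), " | ", sprintf("%.2f", g$sd[i]),
        " | ", g$letter[i], " |")
    }
  }
  invisible(c(json = json_path, md = md_path))
}
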