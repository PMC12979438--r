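#' Simulate a replicate-level viability assay
#'
#' Draws binomial viable counts along a known decay curve, emulating the
#' accelerated-aging design: a handful of sampling times (default 0-4
#' days, i.e. 0-96 h at 24 h intervals), three biological replicates of 50
#' seeds each. Each replicate's viable count at time t is
#' `Binomial(seeds_per_replicate, v(t))`. Deterministic under a fixed
#' `rng_seed`.
#'
#' @param params True decay parameters (see [decay_families()]).
#' @param family Decay family of the generating curve.
#' @param timepoints Sampling times in days.
#' @param replicates Biological replicates per timepoint.
#' @param seeds_per_replicate Seeds scored per replicate.
#' @param rng_seed Integer seed; recorded on the result.
#' @param lot_id Label for the simulated lot.
#' @param collection_year Optional year carried into the assay metadata.
#' @return A [viability_assay()] with attributes `true_params`,
#'   `true_l50` and `rng_seed`.
#' @examples
#' simulate_assay(c(2, 4, -0.3), rng_seed = 42)
#' @export
simulate_assay <- function(params, family = "weibull3",
                           timepoints = c(0, 1, 2, 3, 4), replicates = 3,
                           seeds_per_replicate = 50, rng_seed = 0,
                           lot_id = "sim", collection_year = NA_integer_) {
  params <- check_decay_params(params, family)
  stopifnot(replicates >= 1, seeds_per_replicate >= 1)
  v_true <- decay_viability(timepoints, params, family)
  grid <- expand.grid(replicate = seq_len(replicates), time = timepoints)
  p <- rep(v_true, each = replicates)
  n_viable <- with_seed(rng_seed,
                        stats::rbinom(nrow(grid), seeds_per_replicate, p))
  a <- viability_assay(grid$time, grid$replicate,
                       n_tested = seeds_per_replicate,
                       n_viable = n_viable, lot_id = lot_id,
                       collection_year = collection_year)
  attr(a, "true_params") <- params
  attr(a, "true_family") <- family
  attr(a, "true_l50") <- l50_closed_form(params, family)$l50
  attr(a, "rng_seed") <- rng_seed
  a
}

#' Simulate an age-stratified cohort series
#'
#' Emulates seed lots of increasing storage age whose true L50 declines
#' with age along a known quadratic. For each age the target L50 comes
#' from the quadratic; the generating Weibull curve fixes shape `k` and
#' location `c` and back-solves the scale
#' `lambda = (L50 - c) / (ln 2)^(1/k)`, so truth bookkeeping is
#' unambiguous along the (lambda, k, c) ridge. Each lot is then simulated
#' as in [simulate_assay()].
#'
#' @param ages Age grid in years.
#' @param coefficients Quadratic `(Intercept, B1, B2)` giving the true
#'   L50-age law; defaults to the published estimates for the studied
#'   seed lots.
#' @param k,c Fixed shape and location of the generating curves.
#' @inheritParams simulate_assay
#' @return A list with one element per age: `age`, `true_l50`,
#'   `true_params`, `assay`. Attributes carry the generating quadratic
#'   and its smaller positive root.
#' @examples
#' ser <- simulate_cohort_series(rng_seed = 1)
#' sapply(ser, function(s) s$true_l50)
#' @export
simulate_cohort_series <- function(ages = c(0, 1, 2, 3, 4, 8),
                                   coefficients = c(2.403749, -0.403234,
                                                    0.016114),
                                   k = 6, c = -0.3,
                                   timepoints = c(0, 1, 2, 3, 4),
                                   replicates = 3,
                                   seeds_per_replicate = 50,
                                   rng_seed = 0) {
  co <- as.numeric(coefficients)
  l50_target <- co[1] + co[2] * ages + co[3] * ages^2
  bad <- which(l50_target <= c)
  if (length(bad)) {
    stop("target L50 at age ", ages[bad[1]],
         " does not exceed the location c: lambda would be non-positive",
         call. = FALSE)
  }
  if (any(l50_target < 0)) {
    stop("quadratic is negative at age ",
         ages[which(l50_target < 0)[1]], call. = FALSE)
  }
  out <- lapply(seq_along(ages), function(i) {
    lambda <- (l50_target[i] - c) / log(2)^(1 / k)
    pars <- c(lambda = lambda, k = k, c = c)
    assay <- simulate_assay(pars, "weibull3", timepoints, replicates,
                            seeds_per_replicate,
                            rng_seed = rng_seed + i,
                            lot_id = paste0("age", ages[i]))
    list(age = ages[i], true_l50 = unname(l50_target[i]),
         true_params = pars, assay = assay)
  })
  attr(out, "coefficients") <- co
  attr(out, "true_root") <-
    longevity_bound(as_l50_regression(co, "quadratic"))$root_small
  attr(out, "rng_seed") <- rng_seed
  out
}

#' Simulate replicate germination percentages
#'
#' Each replicate germinates `Binomial(n_seeds, p_germ)` seeds; the
#' percentage is reported, emulating germination-validation trials of six
#' replicates of 30 seeds.
#'
#' @param n_reps Number of replicates.
#' @param n_seeds Seeds per replicate.
#' @param p_germ True germination probability in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return Numeric vector of replicate percentages in \[0, 100\].
#' @examples
#' simulate_germination(6, 30, 0.105, rng_seed = 3)
#' @export
simulate_germination <- function(n_reps = 6, n_seeds = 30, p_germ,
                                 rng_seed = 0) {
  if (!is.finite(p_germ) || p_germ < 0 || p_germ > 1) {
    stop("p_germ must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_reps >= 1, n_seeds >= 1)
  with_seed(rng_seed,
            100 * stats::rbinom(n_reps, n_seeds, p_germ) / n_seeds)
}

#' Render a synthetic stained seed cross-section image
#'
#' Draws an elliptical "section" on a white background and paints a
#' contiguous region of exactly `round(target_fraction * section_pixels)`
#' pixels saturated red (the formazan-stained area); the remainder of the
#' section is pale yellow (unstained tissue). Ground-truth pixel counts
#' are returned alongside, so segmentation accuracy can be scored
#' exactly. A small seeded colour jitter keeps pixels away from exact
#' threshold boundaries without crossing them.
#'
#' @param target_fraction Stained fraction of the section in \[0, 1\].
#' @param size `c(height, width)` in pixels.
#' @param rng_seed Integer seed for the colour jitter.
#' @return List with `image` (height x width x 3 RGB array in \[0, 1\]),
#'   `stained_pixels`, `section_pixels`, `target_fraction`.
#' @examples
#' img <- render_seed_image(0.3, rng_seed = 1)
#' img$stained_pixels / img$section_pixels
#' @export
render_seed_image <- function(target_fraction, size = c(200, 200),
                              rng_seed = 0) {
  if (!is.finite(target_fraction) || target_fraction < 0 ||
      target_fraction > 1) {
    stop("target_fraction must lie in [0, 1]", call. = FALSE)
  }
  h <- size[1]; w <- size[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- h * 0.38; rx <- w * 0.44
  section <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  n_section <- sum(section)
  n_stain <- round(target_fraction * n_section)
  # paint left-to-right across the section: contiguous stained region
  idx <- which(section)
  ord <- order(xx[section], yy[section])
  stain_idx <- idx[ord][seq_len(n_stain)]
  img <- array(1, dim = c(h, w, 3))          # white background
  pale <- c(0.93, 0.88, 0.55)                # unstained tissue
  red <- c(0.75, 0.10, 0.12)                 # formazan red
  jit <- with_seed(rng_seed,
                   matrix(stats::runif(n_section * 3, -0.02, 0.02),
                          n_section, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- pale[ch] + jit[, ch]
    plane[stain_idx] <- red[ch] + jit[match(stain_idx, idx), ch]
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  list(image = img, stained_pixels = n_stain, section_pixels = n_section,
       target_fraction = target_fraction)
}

#' Write an RGB array to PNG
#'
#' @param image Height x width x 3 array in \[0, 1\] (or the list
#'   returned by [render_seed_image()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seed_image <- function(image, path) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  png::writePNG(image, path)
  invisible(path)
}
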