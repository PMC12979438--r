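#' Published decay-curve parameter tables for Solanum rostratum
#'
#' Three-parameter Weibull parameters (scale lambda, shape k, location c)
#' and the published L50 (days) for each seed lot of the S. rostratum
#' accelerated-aging study: six geographical populations, eight collection
#' years and two soil-seed-bank habitats. These are the published point
#' estimates, shipped so the downstream chain (closed-form L50, age
#' regression, longevity bound) can be reproduced without the raw assay
#' data, which were not deposited.
#'
#' @param context Optional filter: `"population"`, `"collection_year"` or
#'   `"habitat"`.
#' @return Data frame with columns `group`, `context`, `lambda`, `k`,
#'   `c`, `l50_printed`.
#' @examples
#' solanum_decay_params("population")
#' @export
solanum_decay_params <- function(context = NULL) {
  d <- utils::read.csv(system.file("extdata", "solanum_decay_params.csv",
                                   package = "seedaging"),
                       stringsAsFactors = FALSE)
  if (!is.null(context)) d <- d[d$context == context, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Published (seed age, L50) pairs
#'
#' The seven collection-year lots' L50 values (days, from three-parameter
#' Weibull fits to accelerated-aging data) paired with chronological seed
#' age in years at testing. Lots already below 50\% viability at time zero
#' enter with L50 = 0 (the "not estimable" clamping convention). This is
#' the input of the quadratic longevity regression.
#'
#' @return Data frame with columns `age` (years) and `l50` (days).
#' @examples
#' l50_age_fit(solanum_age_l50())
#' @export
solanum_age_l50 <- function() {
  d <- utils::read.csv(system.file("extdata", "solanum_age_l50.csv",
                                   package = "seedaging"))
  data.frame(age = d$age_years, l50 = d$l50_days)
}

#' Published germination-validation replicates
#'
#' Replicate germination percentages (six replicates of 30 seeds,
#' GA3-treated) for the 2008, 2015 and 2023 collection cohorts, used to
#' cross-check the extrapolated longevity bound: 15-year-old seeds no
#' longer germinate, 8-year-old seeds retain ~10\% germination.
#'
#' @return Data frame with columns `cohort`, `replicate`,
#'   `percent_germinated`.
#' @examples
#' germination_summary(solanum_germination())
#' @export
solanum_germination <- function() {
  utils::read.csv(system.file("extdata", "solanum_germination.csv",
                              package = "seedaging"),
                  colClasses = c(cohort = "character"))
}
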