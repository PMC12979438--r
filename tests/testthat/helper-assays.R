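# Shared fixtures, built in code.

# Published three-parameter Weibull rows used repeatedly in tests.
gy_params <- c(lambda = 139.35, k = 329.10, c = -137.65)
tz_params <- c(lambda = 62.61, k = 163.43, c = -61.00)
by_params <- c(lambda = 1.96, k = 5.54, c = -0.22)
farmland_params <- c(lambda = 22.46, k = 63.61, c = -20.74)

# The seven (age, L50) pairs of the collection-year series.
age_l50_points <- data.frame(
  age = c(0, 1, 2, 3, 4, 8, 15),
  l50 = c(2.39, 2.06, 1.45, 1.46, 1.20, 0.10, 0)
)

# Published germination replicates per cohort.
germ_reps <- list(
  `2008` = rep(0, 6),
  `2015` = c(10.00, 6.67, 13.33, 6.67, 16.67, 10.00),
  `2023` = c(83.33, 93.33, 86.67, 80.00, 83.33, 93.33)
)

# Noise-free assay sampled from a known curve on the standard design.
noise_free_assay <- function(params, family = "weibull3",
                             timepoints = 0:4, replicates = 3,
                             lot_id = "nf") {
  tt <- rep(timepoints, each = replicates)
  viability_assay(tt, rep(seq_len(replicates), length(timepoints)),
                  viability = decay_viability(tt, params, family),
                  lot_id = lot_id)
}

# Back-solve the Weibull scale so a (k, c) curve has a target L50.
lambda_for_l50 <- function(l50, k, c) (l50 - c) / log(2)^(1 / k)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Temporary CSV helper.
write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
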