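#' Construct a viability assay
#'
#' A viability assay holds replicate-level viable/tested counts over aging
#' time for one seed lot — the unit every decay fit consumes. Observations
#' are stored sorted by (time, replicate); viability is the fraction
#' `n_viable / n_tested` (or supplied directly when only percentages are
#' available).
#'
#' @param time Numeric vector, aging time in days (`>= 0`).
#' @param replicate Integer replicate ids.
#' @param n_tested,n_viable Seed counts per observation (`0 <= n_viable <=
#'   n_tested`). Either both are given, or `viability` is.
#' @param viability Viability fractions in \[0, 1\], used when counts are
#'   unavailable.
#' @param lot_id Seed-lot label.
#' @param collection_year Optional integer collection year.
#' @param habitat Optional habitat label.
#' @return An object of class `"viability_assay"`: a data frame of
#'   observations with lot metadata attached as attributes.
#' @examples
#' viability_assay(time = rep(0:4, each = 3), replicate = rep(1:3, 5),
#'                 n_tested = 50, n_viable = c(rep(50, 6), 40, 42, 38,
#'                 20, 25, 18, 2, 0, 1), lot_id = "demo")
#' @export
viability_assay <- function(time, replicate, n_tested = NULL,
                            n_viable = NULL, viability = NULL,
                            lot_id = "lot", collection_year = NA_integer_,
                            habitat = NA_character_) {
  time <- as.numeric(time)
  replicate <- as.integer(replicate)
  n <- length(time)
  if (length(replicate) != n) stop("time and replicate lengths differ",
                                   call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("aging times must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(n_viable)) {
    n_tested <- rep_len(as.numeric(n_tested), n)
    n_viable <- rep_len(as.numeric(n_viable), n)
    if (any(n_tested <= 0)) stop("n_tested must be positive", call. = FALSE)
    bad <- which(n_viable < 0 | n_viable > n_tested)
    if (length(bad)) {
      stop("n_viable outside [0, n_tested] at observation ", bad[1L],
           call. = FALSE)
    }
    viability <- n_viable / n_tested
  } else if (!is.null(viability)) {
    viability <- rep_len(as.numeric(viability), n)
    if (any(viability < 0 | viability > 1)) {
      stop("viability fractions must lie in [0, 1]", call. = FALSE)
    }
    n_tested <- rep(NA_real_, n)
    n_viable <- rep(NA_real_, n)
  } else {
    stop("supply either n_tested & n_viable or viability", call. = FALSE)
  }
  obs <- data.frame(time = time, replicate = replicate,
                    n_tested = n_tested, n_viable = n_viable,
                    viability = viability)
  obs <- obs[order(obs$time, obs$replicate), , drop = FALSE]
  rownames(obs) <- NULL
  structure(obs,
            lot_id = as.character(lot_id),
            collection_year = collection_year,
            habitat = habitat,
            class = c("viability_assay", "data.frame"))
}

#' @export
print.viability_assay <- function(x, ...) {
  cat("Viability assay for lot '", attr(x, "lot_id"), "': ",
      nrow(x), " observations, ", length(unique(x$time)),
      " timepoints\n", sep = "")
  if (!is.na(attr(x, "collection_year"))) {
    cat("  collection year:", attr(x, "collection_year"), "\n")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Read replicate-level viability assays from CSV
#'
#' Expects a header with columns `lot_id`, `time_days`, `replicate` and
#' either the count pair `n_tested`,`n_viable` or `percent_viable`
#' (divided by 100 on load). Optional metadata columns `collection_year`
#' and `habitat` are carried through. One assay is built per `lot_id`.
#'
#' @param path Path to a UTF-8 CSV file (or connection).
#' @return A named list of [viability_assay()] objects, one per lot.
#' @export
read_viability_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lot_id", "time_days", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("viability CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  counts <- all(c("n_tested", "n_viable") %in% names(d))
  if (!counts && !("percent_viable" %in% names(d))) {
    stop("viability CSV needs n_tested & n_viable or percent_viable",
         call. = FALSE)
  }
  bad <- which(!is.finite(d$time_days) | d$time_days < 0)
  if (length(bad)) {
    stop("negative or missing time_days at row ", bad[1L], call. = FALSE)
  }
  if (counts) {
    bad <- which(d$n_viable < 0 | d$n_viable > d$n_tested)
    if (length(bad)) {
      stop("n_viable > n_tested at row ", bad[1L], call. = FALSE)
    }
  } else {
    bad <- which(d$percent_viable < 0 | d$percent_viable > 100)
    if (length(bad)) {
      stop("percent_viable outside [0, 100] at row ", bad[1L],
           call. = FALSE)
    }
  }
  out <- lapply(split(d, d$lot_id), function(g) {
    year <- if ("collection_year" %in% names(g)) g$collection_year[1L]
            else NA_integer_
    hab <- if ("habitat" %in% names(g)) g$habitat[1L] else NA_character_
    if (counts) {
      viability_assay(g$time_days, g$replicate, n_tested = g$n_tested,
                      n_viable = g$n_viable, lot_id = g$lot_id[1L],
                      collection_year = year, habitat = hab)
    } else {
      viability_assay(g$time_days, g$replicate,
                      viability = g$percent_viable / 100,
                      lot_id = g$lot_id[1L],
                      collection_year = year, habitat = hab)
    }
  })
  out[unique(d$lot_id)]
}

#' Write viability assays to CSV
#'
#' Inverse of [read_viability_csv()]; counts are written when present,
#' otherwise a `percent_viable` column.
#'
#' @param assays A `viability_assay` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_viability_csv <- function(assays, path) {
  if (inherits(assays, "viability_assay")) assays <- list(assays)
  rows <- lapply(assays, function(a) {
    base <- data.frame(lot_id = attr(a, "lot_id"),
                       collection_year = attr(a, "collection_year"),
                       habitat = attr(a, "habitat"),
                       time_days = a$time, replicate = a$replicate)
    if (all(is.finite(a$n_tested))) {
      cbind(base, n_tested = a$n_tested, n_viable = a$n_viable)
    } else {
      cbind(base, percent_viable = 100 * a$viability)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
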