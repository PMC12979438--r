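#' Thresholds for tetrazolium stain segmentation
#'
#' HSV windows selecting formazan-red pixels on a seed cross-section
#' image. The hue window wraps around 0 degrees when `hue_lo > hue_hi`
#' (the default `[340, 20]` covers red on both sides of 0). Pixels darker
#' than `bg_brightness` (brightness = max of the RGB channels) belong to
#' the section; everything at or above it is treated as white background.
#'
#' @param hue_lo,hue_hi Hue window bounds in degrees \[0, 360).
#' @param sat_min Minimum saturation of a stained pixel.
#' @param val_min,val_max Brightness window of a stained pixel.
#' @param bg_brightness Background brightness cut defining the section
#'   mask.
#' @return An object of class `"stain_thresholds"`.
#' @export
stain_thresholds <- function(hue_lo = 340, hue_hi = 20, sat_min = 0.35,
                             val_min = 0.15, val_max = 0.95,
                             bg_brightness = 0.98) {
  if (hue_lo < 0 || hue_lo >= 360 || hue_hi < 0 || hue_hi >= 360) {
    stop("hue bounds must lie in [0, 360)", call. = FALSE)
  }
  for (v in c(sat_min, val_min, val_max, bg_brightness)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("saturation/brightness thresholds must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (val_min > val_max) stop("val_min exceeds val_max", call. = FALSE)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 val_min = val_min, val_max = val_max,
                 bg_brightness = bg_brightness),
            class = "stain_thresholds")
}

#' @export
print.stain_thresholds <- function(x, ...) {
  cat("Stain thresholds: hue [", x$hue_lo, ",", x$hue_hi,
      "] deg (wraps past 0 if lo > hi), sat >=", x$sat_min,
      ", brightness [", x$val_min, ",", x$val_max,
      "], background cut", x$bg_brightness, "\n")
  invisible(x)
}

#' Read a seed-section raster image
#'
#' Reads PNG or TIFF into a height x width x 3 RGB array in \[0, 1\]
#' (alpha channels are dropped, grayscale is expanded to three channels).
#'
#' @param path Image path; format inferred from the extension.
#' @return RGB array.
#' @export
read_seed_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  )
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Stained-area fraction of a seed cross-section
#'
#' Counts section pixels (brightness below the background cut) and the
#' subset lying inside the red hue/saturation/brightness windows, and
#' reports the stained fraction: stained area / total section area. A
#' seed is classified viable when the fraction is at least 0.5.
#'
#' @param image RGB array in \[0, 1\] (height x width x 3), a path, or
#'   the list returned by [render_seed_image()].
#' @param thresholds A [stain_thresholds()] object.
#' @return Object of class `"stain_result"`: `stained_pixels`,
#'   `section_pixels`, `stained_fraction`, `viable`.
#' @examples
#' img <- render_seed_image(0.3, rng_seed = 1)
#' stained_fraction(img)
#' @export
stained_fraction <- function(image, thresholds = stain_thresholds()) {
  stopifnot(inherits(thresholds, "stain_thresholds"))
  if (is.character(image)) image <- read_seed_image(image)
  if (is.list(image) && !is.null(image$image)) image <- image$image
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    stop("image must be a height x width x 3 RGB array", call. = FALSE)
  }
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g),
                                  as.vector(b)), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val <- hsv[3, ]
  section <- val < thresholds$bg_brightness
  n_section <- sum(section)
  if (n_section == 0) stop("no section detected", call. = FALSE)
  in_hue <- if (thresholds$hue_lo <= thresholds$hue_hi) {
    hue >= thresholds$hue_lo & hue <= thresholds$hue_hi
  } else {
    hue >= thresholds$hue_lo | hue <= thresholds$hue_hi
  }
  stained <- section & in_hue & sat >= thresholds$sat_min &
    val >= thresholds$val_min & val <= thresholds$val_max
  n_stained <- sum(stained)
  frac <- n_stained / n_section
  structure(list(stained_pixels = n_stained, section_pixels = n_section,
                 stained_fraction = frac,
                 viable = classify_viability(frac) == "viable"),
            class = "stain_result")
}

#' @export
print.stain_result <- function(x, ...) {
  cat(sprintf("Stained %d / %d section pixels = %.1f%% -> %s\n",
              x$stained_pixels, x$section_pixels,
              100 * x$stained_fraction,
              if (x$viable) "viable" else "non-viable"))
  invisible(x)
}

#' Classify seed viability from its stained fraction
#'
#' Seeds with less than 50\% stained embryo area are non-viable; the
#' boundary value 0.5 counts as viable.
#'
#' @param fraction Stained fraction(s) in \[0, 1\].
#' @return Character vector, `"viable"` or `"non-viable"`.
#' @examples
#' classify_viability(c(0.49, 0.5, 1))
#' @export
classify_viability <- function(fraction) {
  if (any(!is.finite(fraction) | fraction < 0 | fraction > 1)) {
    stop("stained fraction must lie in [0, 1]", call. = FALSE)
  }
  ifelse(fraction >= 0.5, "viable", "non-viable")
}

#' Batch viability from a set of section images
#'
#' Applies [stained_fraction()] to each image and aggregates: percent
#' viable = 100 * (viable seeds) / (seeds scored). Per-image failures are
#' reported as flagged rows, not raised.
#'
#' @param images List of RGB arrays, paths, or [render_seed_image()]
#'   results (a character vector of paths also works).
#' @param thresholds A [stain_thresholds()].
#' @return List with `table` (one row per image: `image`,
#'   `stained_pixels`, `section_pixels`, `fraction`, `viable`, `error`)
#'   and `percent_viable`.
#' @export
batch_viability <- function(images, thresholds = stain_thresholds()) {
  if (is.character(images)) images <- as.list(images)
  if (!length(images)) stop("no images supplied", call. = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    lab <- if (is.character(images[[i]])) images[[i]]
           else paste0("image_", i)
    res <- tryCatch(stained_fraction(images[[i]], thresholds),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(image = lab, stained_pixels = NA_integer_,
                 section_pixels = NA_integer_, fraction = NA_real_,
                 viable = NA, error = res, stringsAsFactors = FALSE)
    } else {
      data.frame(image = lab, stained_pixels = res$stained_pixels,
                 section_pixels = res$section_pixels,
                 fraction = res$stained_fraction, viable = res$viable,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$viable)
  pct <- if (any(ok)) 100 * sum(tab$viable[ok]) / sum(ok) else NA_real_
  list(table = tab, percent_viable = pct)
}
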