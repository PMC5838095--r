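#' Blue-channel calibration for image-based egg counting
#'
#' Egg masses photographed on a whitish background are segmented by
#' thresholding the blue channel of the split RGB image: pixels with blue
#' intensity inside `[intensity_low, intensity_high]` (0 = black,
#' 255 = white; both ends inclusive) are counted as egg pixels, and a linear
#' regression converts pixel counts to egg numbers.
#'
#' @param slope,intercept regression coefficients (eggs per pixel; eggs).
#'   `NULL` until fitted with [fit_calibration()].
#' @param intensity_low,intensity_high inclusive blue-intensity window,
#'   defaults 0 and 98.
#' @return An object of class `egg_calibration`.
#' @export
egg_calibration <- function(slope = NULL, intercept = NULL,
                            intensity_low = 0L, intensity_high = 98L) {
  intensity_low <- assert_count(intensity_low, "intensity_low")
  intensity_high <- assert_count(intensity_high, "intensity_high")
  if (intensity_low > intensity_high || intensity_high > 255L) {
    stop_input("need 0 <= intensity_low <= intensity_high <= 255")
  }
  if (!is.null(slope) && slope <= 0) {
    stop_input("calibration slope must be positive")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = NULL,
         n_points = NULL, intensity_low = intensity_low,
         intensity_high = intensity_high, channel = "blue"),
    class = "egg_calibration"
  )
}

#' @export
print.egg_calibration <- function(x, ...) {
  cat(sprintf("Egg calibration: blue channel window [%d, %d]\n",
              x$intensity_low, x$intensity_high))
  if (is.null(x$slope)) {
    cat("  (regression not fitted)\n")
  } else {
    cat(sprintf("  eggs = %.6g * pixels + %.6g (R^2 = %s, n = %s)\n",
                x$slope, x$intercept,
                if (is.null(x$r_squared)) "?" else sprintf("%.4f", x$r_squared),
                if (is.null(x$n_points)) "?" else x$n_points))
  }
  invisible(x)
}

# coerce an in-memory raster to an 8-bit RGB intensity array (0..255);
# rejects grayscale input — the procedure is defined on the blue channel
# of a split RGB image.
as_rgb255 <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    stop_input("image must be an RGB array (height x width x 3 channels); ",
               "grayscale input is rejected, not coerced")
  }
  if (anyNA(image) || min(image) < 0) stop_input("image has invalid intensities")
  mx <- max(image)
  if (mx <= 1) {
    image <- round(image * 255)
  } else if (mx > 255 || any(image != round(image))) {
    stop_input("image must be 8-bit: intensities in [0, 1] or integers in [0, 255]")
  }
  image[, , 1:3, drop = FALSE]
}

#' Count egg pixels in the blue channel of an RGB image
#'
#' @param image an RGB raster: a `height x width x 3` array with
#'   intensities either in \[0, 1\] (as returned by [png::readPNG()]) or
#'   8-bit integers in \[0, 255\]. An alpha channel, if present, is ignored.
#' @param calibration an [egg_calibration()] supplying the intensity window.
#' @return Integer count of pixels whose blue intensity lies inside the
#'   window (inclusive).
#' @export
egg_pixel_count <- function(image, calibration = egg_calibration()) {
  if (!inherits(calibration, "egg_calibration")) {
    stop_input("calibration must be an egg_calibration")
  }
  rgb <- as_rgb255(image)
  blue <- rgb[, , 3L]
  sum(blue >= calibration$intensity_low & blue <= calibration$intensity_high)
}

#' Fit the pixel-to-egg regression
#'
#' Ordinary least squares of manually counted egg numbers on egg-pixel
#' counts over a set of calibration photographs.
#'
#' @param pixel_counts egg-pixel counts from [egg_pixel_count()].
#' @param egg_counts manually counted egg numbers, same length.
#' @param calibration an [egg_calibration()] carrying the intensity window
#'   to attach the coefficients to.
#' @return The calibration with `slope`, `intercept`, `r_squared` and
#'   `n_points` filled in.
#' @export
fit_calibration <- function(pixel_counts, egg_counts,
                            calibration = egg_calibration()) {
  if (!is.numeric(pixel_counts) || !is.numeric(egg_counts) ||
      length(pixel_counts) != length(egg_counts)) {
    stop_input("pixel_counts and egg_counts must be numeric of equal length")
  }
  if (length(pixel_counts) < 3L) {
    stop_input("need at least 3 paired observations to fit the calibration")
  }
  if (length(unique(pixel_counts)) < 2L) {
    stop_input("pixel counts are constant; regression is undefined")
  }
  fit <- lm(egg_counts ~ pixel_counts)
  slope <- unname(coef(fit)[2L])
  if (slope <= 0) stop_input("fitted slope is not positive; check the pairs")
  calibration$slope <- slope
  calibration$intercept <- unname(coef(fit)[1L])
  ss_tot <- sum((egg_counts - mean(egg_counts))^2)
  ss_res <- sum(fit$residuals^2)
  calibration$r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  calibration$n_points <- length(pixel_counts)
  calibration
}

#' Estimate the number of eggs in an image
#'
#' Applies the fitted regression to the blue-channel pixel count:
#' `max(0, round(slope * pixels + intercept))`.
#'
#' @inheritParams egg_pixel_count
#' @param calibration a fitted [egg_calibration()].
#' @return Non-negative integer egg estimate.
#' @export
estimate_egg_count <- function(image, calibration) {
  if (!inherits(calibration, "egg_calibration")) {
    stop_input("calibration must be an egg_calibration")
  }
  if (is.null(calibration$slope)) {
    stop_state("calibration has not been fitted; call fit_calibration first")
  }
  px <- egg_pixel_count(image, calibration)
  max(0, round(calibration$slope * px + calibration$intercept))
}

#' Read an RGB photograph from PNG or TIFF
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A `height x width x channels` array with intensities in
#'   \[0, 1\].
#' @export
read_egg_image <- function(path) {
  if (!file.exists(path)) stop_input("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_state("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop_input("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
}
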