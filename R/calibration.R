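#' Physical calibration of a slide raster
#'
#' Binds a raster grid (and any point coordinates on it) to physical units.
#' Pixels are square and isotropic; anisotropic calibrations are rejected at
#' construction because none of the geometric operators define behaviour for
#' them. Coordinates are 0-based: the pixel stored at matrix row `r`, column
#' `c` has its center at `(x, y) = (c - 1, r - 1)` pixel units, x rightward,
#' y downward.
#'
#' @param microns_per_pixel Positive scalar, microns per pixel side.
#' @param width_px,height_px Positive integer raster dimensions.
#' @return A `stil_calibration` object.
#' @examples
#' cal <- calibration(2, 100, 80)
#' px_area_mm2(cal) * 100 * 80   # total raster area in mm^2
#' @export
calibration <- function(microns_per_pixel, width_px, height_px) {
  stopifnot(
    is.numeric(microns_per_pixel), length(microns_per_pixel) == 1L,
    is.finite(microns_per_pixel), microns_per_pixel > 0,
    length(width_px) == 1L, length(height_px) == 1L,
    width_px >= 1, height_px >= 1,
    width_px == as.integer(width_px), height_px == as.integer(height_px)
  )
  structure(
    list(
      microns_per_pixel = as.numeric(microns_per_pixel),
      width_px = as.integer(width_px),
      height_px = as.integer(height_px)
    ),
    class = "stil_calibration"
  )
}

#' @export
print.stil_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> %d x %d px @ %g um/px (%.3f x %.3f mm)\n",
    x$width_px, x$height_px, x$microns_per_pixel,
    x$width_px * x$microns_per_pixel / 1000,
    x$height_px * x$microns_per_pixel / 1000
  ))
  invisible(x)
}

#' Area of one pixel in square millimetres
#' @param cal A [calibration()].
#' @export
px_area_mm2 <- function(cal) {
  stopifnot(inherits(cal, "stil_calibration"))
  (cal$microns_per_pixel / 1000)^2
}

#' Convert a physical length in microns to pixels
#' @param cal A [calibration()].
#' @param um Length in microns.
#' @export
um_to_px <- function(cal, um) {
  stopifnot(inherits(cal, "stil_calibration"))
  um / cal$microns_per_pixel
}

#' Convert a pixel length to microns
#' @param cal A [calibration()].
#' @param px Length in pixels.
#' @export
px_to_um <- function(cal, px) {
  stopifnot(inherits(cal, "stil_calibration"))
  px * cal$microns_per_pixel
}

same_calibration <- function(a, b, tol = 1e-9) {
  inherits(a, "stil_calibration") && inherits(b, "stil_calibration") &&
    abs(a$microns_per_pixel - b$microns_per_pixel) <= tol &&
    a$width_px == b$width_px && a$height_px == b$height_px
}

check_same_calibration <- function(a, b, what = "inputs") {
  if (!same_calibration(a, b)) {
    stop("calibration mismatch: ", what, " do not share one calibration ",
         "(", a$width_px, "x", a$height_px, " @ ", a$microns_per_pixel,
         " vs ", b$width_px, "x", b$height_px, " @ ", b$microns_per_pixel, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
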