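#' Discretized disk membership offsets
#'
#' A pixel belongs to the disk of radius `r_px` iff its center lies within
#' the radius (inclusive boundary). Returns a 0/1 kernel matrix of odd
#' dimensions `2*floor(r_px)+1`.
#' @param r_px Radius in pixels, >= 1.
#' @keywords internal
disk_kernel <- function(r_px) {
  R <- floor(r_px + 1e-9)
  off <- seq(-R, R)
  d2 <- outer(off^2, off^2, "+")
  (d2 <= r_px^2 + 1e-9) * 1
}

radius_px_checked <- function(cal, radius_um) {
  stopifnot(is.numeric(radius_um), length(radius_um) == 1L, radius_um > 0)
  r_px <- um_to_px(cal, radius_um)
  if (r_px < 1) {
    stop("radius ", radius_um, " um is below one pixel at ",
         cal$microns_per_pixel, " um/px; calibration mismatch?", call. = FALSE)
  }
  r_px
}

# Integer-exact convolution of a 0/1 matrix with a 0/1 kernel, zero boundary.
# filter2 is FFT-based; counts are integers, so rounding restores exactness.
# The image is zero-padded when smaller than the kernel.
conv_count <- function(mat, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  nr <- nrow(mat); nc <- ncol(mat)
  pr <- max(0L, kr - nr); pc <- max(0L, kc - nc)
  if (pr > 0 || pc > 0) {
    big <- matrix(0, nr + 2 * pr, nc + 2 * pc)
    big[pr + seq_len(nr), pc + seq_len(nc)] <- mat
    out <- round(EBImage::filter2(big, kernel, boundary = 0))
    out[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE]
  } else {
    round(EBImage::filter2(mat, kernel, boundary = 0))
  }
}

#' Local true-pixel fraction under a circular kernel
#'
#' For every pixel, the fraction of true mask pixels among the disk of radius
#' `radius_um` centered there, the disk clipped to the image; the denominator
#' is the in-image disk pixel count, so edge positions are not biased by
#' padding.
#'
#' @param mask A [binary_mask()].
#' @param radius_um Kernel radius in microns (> 0; must be >= 1 px).
#' @return A numeric matrix in `[0, 1]` of the mask's dimensions.
#' @export
disk_kernel_fraction <- function(mask, radius_um) {
  stopifnot(inherits(mask, "stil_binary_mask"))
  k <- disk_kernel(radius_px_checked(mask$calibration, radius_um))
  num <- conv_count(mask$raster * 1, k)
  den <- conv_count(matrix(1, nrow(mask$raster), ncol(mask$raster)), k)
  num / den
}

# Distance (in px) from every pixel center to the nearest TRUE pixel center.
# Exact Euclidean via EBImage's distance transform of the complement.
dist_to_true_px <- function(raster) {
  if (!any(raster)) {
    return(matrix(Inf, nrow(raster), ncol(raster)))
  }
  EBImage::distmap(1 - raster)
}

#' Euclidean dilation of a binary mask by a physical distance
#'
#' The result contains every pixel whose center-to-center Euclidean distance
#' to the nearest true pixel is at most `distance_um`; distance 0 returns the
#' input unchanged.
#'
#' @param mask A [binary_mask()].
#' @param distance_um Nonnegative distance in microns.
#' @return A [binary_mask()].
#' @export
dilate_um <- function(mask, distance_um) {
  stopifnot(inherits(mask, "stil_binary_mask"),
            is.numeric(distance_um), length(distance_um) == 1L,
            distance_um >= 0)
  if (distance_um == 0 || !any(mask$raster)) return(mask)
  r_px <- um_to_px(mask$calibration, distance_um)
  d <- dist_to_true_px(mask$raster)
  binary_mask(d <= r_px + 1e-9, mask$calibration)
}

#' Euclidean erosion of a binary mask by a physical distance
#'
#' Adjoint of [dilate_um()]: keeps pixels whose whole disk neighbourhood of
#' radius `distance_um` lies inside the mask.
#' @inheritParams dilate_um
#' @export
erode_um <- function(mask, distance_um) {
  stopifnot(inherits(mask, "stil_binary_mask"), distance_um >= 0)
  if (distance_um == 0) return(mask)
  inv <- binary_mask(!mask$raster, mask$calibration)
  binary_mask(!dilate_um(inv, distance_um)$raster, mask$calibration)
}

#' Morphological closing followed by opening with a disk element
#'
#' Closing (dilation then erosion) bridges gaps narrower than twice the
#' radius; the subsequent opening (erosion then dilation) removes features
#' thinner than the element. Both use the Euclidean disk of `radius_um`, so
#' the composite is idempotent.
#'
#' @inheritParams dilate_um
#' @param radius_um Structuring-element radius in microns (> 0).
#' @export
morph_close_open <- function(mask, radius_um) {
  stopifnot(inherits(mask, "stil_binary_mask"),
            is.numeric(radius_um), length(radius_um) == 1L, radius_um > 0)
  closed <- erode_um(dilate_um(mask, radius_um), radius_um)
  dilate_um(erode_um(closed, radius_um), radius_um)
}

#' Flag points within a physical distance of a mask
#'
#' Flag `i` is `TRUE` iff the Euclidean distance from point `i` (snapped to
#' its nearest pixel center) to the nearest true pixel center is at most
#' `distance_um`. An all-false mask yields all-false flags.
#'
#' @param points A [cell_detections()] tibble.
#' @param mask A [binary_mask()] with the same calibration.
#' @param distance_um Nonnegative threshold in microns.
#' @return Logical vector, one flag per point, in point order.
#' @export
within_distance <- function(points, mask, distance_um) {
  stopifnot(inherits(mask, "stil_binary_mask"),
            is.numeric(distance_um), length(distance_um) == 1L,
            distance_um >= 0)
  cal <- cells_calibration(points)
  check_same_calibration(cal, mask$calibration, "points and mask")
  if (nrow(points) == 0L) return(logical(0))
  if (!any(mask$raster)) return(rep(FALSE, nrow(points)))
  d <- dist_to_true_px(mask$raster)
  idx <- snap_to_pixel(points$x_px, points$y_px, cal)
  px_to_um(cal, d[idx]) <= distance_um + 1e-9
}

# Connected components (8-connectivity) of a logical matrix; returns an
# integer label matrix, 0 = background.
label_components <- function(raster) {
  lab <- EBImage::bwlabel(raster * 1)
  storage.mode(lab) <- "integer"
  lab
}
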