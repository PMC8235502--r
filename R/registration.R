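#' Affine transform between two slide frames
#'
#' A 2x3 matrix `A` mapping source pixel coordinates to target pixel
#' coordinates: `(x', y')^T = A %*% (x, y, 1)^T`. Used to carry
#' IHC-derived dot annotations from a restained or serial section onto the
#' H&E frame.
#'
#' @param matrix_2x3 Numeric 2x3 matrix.
#' @return A `stil_affine`.
#' @export
affine_transform <- function(matrix_2x3) {
  stopifnot(is.matrix(matrix_2x3), all(dim(matrix_2x3) == c(2L, 3L)))
  det <- matrix_2x3[1, 1] * matrix_2x3[2, 2] -
    matrix_2x3[1, 2] * matrix_2x3[2, 1]
  if (abs(det) < 1e-9) {
    stop("degenerate affine transform: linear part is singular",
         call. = FALSE)
  }
  structure(list(A = matrix_2x3), class = "stil_affine")
}

#' Apply an affine transform to point coordinates
#' @param transform A [affine_transform()].
#' @param x,y Numeric coordinate vectors.
#' @return A list with transformed `x`, `y`.
#' @export
apply_affine <- function(transform, x, y) {
  stopifnot(inherits(transform, "stil_affine"))
  A <- transform$A
  list(x = A[1, 1] * x + A[1, 2] * y + A[1, 3],
       y = A[2, 1] * x + A[2, 2] * y + A[2, 3])
}

#' Invert an affine transform
#' @param transform A [affine_transform()].
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "stil_affine"))
  A <- transform$A
  L <- A[, 1:2]
  Linv <- solve(L)
  affine_transform(cbind(Linv, -Linv %*% A[, 3]))
}

#' Least-squares affine fit from landmark correspondences
#'
#' Fits the affine transform minimizing the summed squared distance between
#' transformed source landmarks and their target positions, by ordinary
#' least squares on the two coordinate equations. Requires at least three
#' non-collinear pairs.
#'
#' @param src_points,dst_points Data frames or matrices with columns `x`,
#'   `y` (or two unnamed columns), equal row counts.
#' @param microns_per_pixel Optional scale of the target frame, used to
#'   report residuals in microns (1 if omitted).
#' @return A [affine_transform()] with attribute `residuals` (tibble:
#'   per-pair `dx_px`, `dy_px`, `residual_um`) and `rms_um`.
#' @export
fit_affine <- function(src_points, dst_points, microns_per_pixel = 1) {
  src <- as_xy(src_points); dst <- as_xy(dst_points)
  if (nrow(src) != nrow(dst)) {
    stop("source and target landmark lists differ in length", call. = FALSE)
  }
  n <- nrow(src)
  X <- cbind(src$x, src$y, 1)
  if (n < 3 || qr(X)$rank < 3) {
    stop("degenerate landmark set: need >= 3 non-collinear pairs",
         call. = FALSE)
  }
  # Normal equations per output coordinate: A_row = (X'X)^-1 X' dst
  coefs <- qr.solve(X, cbind(dst$x, dst$y))
  tr <- affine_transform(t(coefs))
  pred <- apply_affine(tr, src$x, src$y)
  dx <- dst$x - pred$x
  dy <- dst$y - pred$y
  res <- tibble::tibble(
    dx_px = dx, dy_px = dy,
    residual_um = sqrt(dx^2 + dy^2) * microns_per_pixel
  )
  attr(tr, "residuals") <- res
  attr(tr, "rms_um") <- sqrt(mean(res$residual_um^2))
  tr
}

as_xy <- function(p) {
  p <- as.data.frame(p)
  if (!all(c("x", "y") %in% names(p))) {
    stopifnot(ncol(p) >= 2L)
    names(p)[1:2] <- c("x", "y")
  }
  p[, c("x", "y")]
}

#' Transfer dot annotations into a target frame
#'
#' Maps each detection through the transform; dots landing outside the
#' target frame are dropped and counted. Labels and point order are
#' preserved.
#'
#' @param dots A [cell_detections()] tibble in the source frame.
#' @param transform A [affine_transform()] from source to target frame.
#' @param target_calibration The target frame's [calibration()].
#' @return [cell_detections()] in the target frame with attribute
#'   `n_dropped`.
#' @export
transfer_annotations <- function(dots, transform, target_calibration) {
  stopifnot(inherits(transform, "stil_affine"),
            inherits(target_calibration, "stil_calibration"))
  mapped <- apply_affine(transform, dots$x_px, dots$y_px)
  inside <- mapped$x >= 0 & mapped$x < target_calibration$width_px &
    mapped$y >= 0 & mapped$y < target_calibration$height_px
  out <- cell_detections(mapped$x[inside], mapped$y[inside],
                         dots$label[inside], target_calibration)
  attr(out, "n_dropped") <- sum(!inside)
  out
}

#' Read landmark correspondences from CSV
#'
#' Expects columns `src_x, src_y, dst_x, dst_y`.
#' @param path CSV path.
#' @return List of data frames `src`, `dst`.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  list(src = data.frame(x = df$src_x, y = df$src_y),
       dst = data.frame(x = df$dst_x, y = df$dst_y))
}

#' Write / read an affine transform as JSON
#' @param transform A [affine_transform()].
#' @param path JSON path.
#' @export
write_affine_json <- function(transform, path) {
  stopifnot(inherits(transform, "stil_affine"))
  jsonlite::write_json(
    list(matrix = transform$A,
         rms_um = attr(transform, "rms_um")),
    path, auto_unbox = TRUE, digits = NA, null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(as.numeric(t(js$matrix)), 2, 3, byrow = TRUE))
}

#' Export a rectangular field-of-view crop
#'
#' Data plumbing for manual FOV selection on aligned sections: crops a
#' label mask (or binary mask) to a pixel-aligned rectangle and returns it
#' with an adjusted calibration.
#'
#' @param mask A [label_mask()] or [binary_mask()].
#' @param x0_px,y0_px Top-left corner (0-based).
#' @param width_px,height_px Crop size in pixels.
#' @export
crop_fov <- function(mask, x0_px, y0_px, width_px, height_px) {
  stopifnot(inherits(mask, "stil_label_mask") ||
              inherits(mask, "stil_binary_mask"))
  cal <- mask$calibration
  stopifnot(x0_px >= 0, y0_px >= 0,
            x0_px + width_px <= cal$width_px,
            y0_px + height_px <= cal$height_px)
  sub <- mask$raster[(y0_px + 1):(y0_px + height_px),
                     (x0_px + 1):(x0_px + width_px), drop = FALSE]
  newcal <- calibration(cal$microns_per_pixel, width_px, height_px)
  if (inherits(mask, "stil_label_mask")) label_mask(sub, newcal)
  else binary_mask(sub, newcal)
}
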