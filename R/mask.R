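#' Tissue class codes
#'
#' The five tissue classes a segmentation backend may assign. Codes are stable
#' across save/load and across the package.
#'
#' @return Named integer vector of class codes.
#' @export
stil_classes <- function() {
  c(BACKGROUND = 0L, STROMA = 1L, TUMOR = 2L, NECROSIS = 3L,
    NONINVASIVE_EPITHELIUM = 4L)
}

#' Binary mask over a calibrated raster
#'
#' @param raster Logical matrix (rows = y, columns = x).
#' @param cal A [calibration()] matching the raster dimensions.
#' @return A `stil_binary_mask`.
#' @export
binary_mask <- function(raster, cal) {
  stopifnot(is.matrix(raster), inherits(cal, "stil_calibration"))
  if (!is.logical(raster)) {
    stopifnot(all(raster %in% c(0, 1)))
    raster <- raster > 0
  }
  if (nrow(raster) != cal$height_px || ncol(raster) != cal$width_px) {
    stop("raster is ", nrow(raster), "x", ncol(raster),
         " but calibration says ", cal$height_px, "x", cal$width_px,
         call. = FALSE)
  }
  structure(list(raster = raster, calibration = cal),
            class = "stil_binary_mask")
}

#' Class-labeled mask over a calibrated raster
#'
#' @param raster Integer matrix of class codes from [stil_classes()].
#' @param cal A [calibration()] matching the raster dimensions.
#' @return A `stil_label_mask`.
#' @export
label_mask <- function(raster, cal) {
  stopifnot(is.matrix(raster), inherits(cal, "stil_calibration"))
  storage.mode(raster) <- "integer"
  bad <- setdiff(unique(as.vector(raster)), unname(stil_classes()))
  if (length(bad)) {
    stop("unknown class codes in raster: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raster) != cal$height_px || ncol(raster) != cal$width_px) {
    stop("raster dimensions do not match calibration", call. = FALSE)
  }
  structure(list(raster = raster, calibration = cal),
            class = "stil_label_mask")
}

#' @export
print.stil_binary_mask <- function(x, ...) {
  cat(sprintf("<binary mask> %d x %d px @ %g um/px, %d true px (%.4f mm^2)\n",
              ncol(x$raster), nrow(x$raster), x$calibration$microns_per_pixel,
              sum(x$raster), mask_area_mm2(x)))
  invisible(x)
}

#' @export
print.stil_label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x$raster), levels = unname(stil_classes()),
                      labels = names(stil_classes())))
  cat(sprintf("<label mask> %d x %d px @ %g um/px\n",
              ncol(x$raster), nrow(x$raster), x$calibration$microns_per_pixel))
  print(tab)
  invisible(x)
}

#' Physical area of the true pixels of a binary mask
#' @param mask A [binary_mask()].
#' @return Area in mm^2.
#' @export
mask_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "stil_binary_mask"))
  sum(mask$raster) * px_area_mm2(mask$calibration)
}

#' Extract one class of a label mask as a binary mask
#' @param labels A [label_mask()].
#' @param class Class name from [stil_classes()].
#' @export
class_mask <- function(labels, class) {
  stopifnot(inherits(labels, "stil_label_mask"))
  code <- stil_classes()[[match.arg(class, names(stil_classes()))]]
  binary_mask(labels$raster == code, labels$calibration)
}

#' Tissue (non-background) pixels of a label mask
#' @param labels A [label_mask()].
#' @export
tissue_mask <- function(labels) {
  stopifnot(inherits(labels, "stil_label_mask"))
  binary_mask(labels$raster != stil_classes()[["BACKGROUND"]],
              labels$calibration)
}

# ---- I/O ------------------------------------------------------------------
# Masks travel as PNG rasters plus a JSON sidecar holding the calibration and
# (for label masks) the code -> class-name table. Binary masks are 0/255.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a binary mask as PNG (0/255) + JSON sidecar
#' @param mask A [binary_mask()].
#' @param path PNG file path; the sidecar is written at `<path>.json`.
#' @export
write_binary_mask <- function(mask, path) {
  stopifnot(inherits(mask, "stil_binary_mask"))
  png::writePNG(ifelse(mask$raster, 1, 0), path)
  jsonlite::write_json(
    list(microns_per_pixel = mask$calibration$microns_per_pixel,
         width_px = mask$calibration$width_px,
         height_px = mask$calibration$height_px,
         kind = "binary"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binary_mask
#' @export
read_binary_mask <- function(path) {
  meta <- read_mask_sidecar(path)
  r <- png_to_matrix(png::readPNG(path))
  cal <- calibration(meta$microns_per_pixel, ncol(r), nrow(r))
  binary_mask(r > 0.5, cal)
}

#' Write / read a label mask as PNG + JSON sidecar
#'
#' Class codes are stored in the gray channel as `code / 255`, which
#' round-trips exactly for 8-bit codes; the sidecar records the code table
#' and the calibration.
#' @param labels A [label_mask()].
#' @param path PNG file path; the sidecar is written at `<path>.json`.
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(inherits(labels, "stil_label_mask"))
  png::writePNG(labels$raster / 255, path)
  jsonlite::write_json(
    list(microns_per_pixel = labels$calibration$microns_per_pixel,
         width_px = labels$calibration$width_px,
         height_px = labels$calibration$height_px,
         kind = "label",
         classes = as.list(stil_classes())),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  meta <- read_mask_sidecar(path)
  r <- round(png_to_matrix(png::readPNG(path)) * 255)
  cal <- calibration(meta$microns_per_pixel, ncol(r), nrow(r))
  if (!is.null(meta$classes)) {
    stored <- unlist(meta$classes)
    own <- stil_classes()
    if (!identical(sort(names(stored)), sort(names(own))) ||
        any(stored[names(own)] != own)) {
      stop("class-code table in ", sidecar_path(path),
           " does not match this package's codes", call. = FALSE)
    }
  }
  label_mask(r, cal)
}

read_mask_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing calibration sidecar: ", sc, call. = FALSE)
  }
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

# png::readPNG returns matrices [row, col] possibly with channels; collapse.
png_to_matrix <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
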