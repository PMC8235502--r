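#' Cell detections on a calibrated slide
#'
#' A tibble of point detections (`x_px`, `y_px`, `label`) carrying the slide
#' calibration as an attribute. Coordinates are 0-based continuous pixel
#' units (see [calibration()]); `label` is `"TIL"` or `"OTHER"`. Point order
#' is preserved by every filtering operation.
#'
#' @param x_px,y_px Numeric coordinates in `[0, width_px)` x `[0, height_px)`.
#' @param label Character vector of `"TIL"` / `"OTHER"`.
#' @param cal A [calibration()].
#' @return A `stil_cells` tibble.
#' @export
cell_detections <- function(x_px, y_px, label, cal) {
  stopifnot(inherits(cal, "stil_calibration"),
            length(x_px) == length(y_px), length(label) == length(x_px))
  label <- as.character(label)
  if (length(label) && !all(label %in% c("TIL", "OTHER"))) {
    stop("cell labels must be 'TIL' or 'OTHER'", call. = FALSE)
  }
  if (length(x_px)) {
    inb <- x_px >= 0 & x_px < cal$width_px & y_px >= 0 & y_px < cal$height_px
    if (!all(inb)) {
      stop(sum(!inb), " point(s) fall outside the calibrated frame",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                        label = label)
  attr(out, "calibration") <- cal
  class(out) <- c("stil_cells", class(out))
  out
}

#' Calibration attached to a detection set
#' @param cells A [cell_detections()] tibble.
#' @export
cells_calibration <- function(cells) {
  cal <- attr(cells, "calibration")
  if (is.null(cal)) stop("detections carry no calibration", call. = FALSE)
  cal
}

# Keep the stil_cells class + calibration through dplyr-style subsetting.
restore_cells <- function(new, old) {
  attr(new, "calibration") <- attr(old, "calibration")
  if (!inherits(new, "stil_cells")) class(new) <- c("stil_cells", class(new))
  new
}

# Nearest-pixel matrix indices for point coordinates (documented snapping
# rule: a sub-pixel centroid is assigned to the nearest pixel center).
snap_to_pixel <- function(x_px, y_px, cal) {
  col <- pmin(pmax(as.integer(round(x_px)) + 1L, 1L), cal$width_px)
  row <- pmin(pmax(as.integer(round(y_px)) + 1L, 1L), cal$height_px)
  cbind(row, col)
}

#' Write / read cell detections as CSV
#'
#' Plain CSV with columns `x_px,y_px,label` and one metadata comment line
#' `# microns_per_pixel=<v> width_px=<w> height_px=<h>` holding the
#' calibration.
#' @param cells A [cell_detections()] tibble.
#' @param path CSV path.
#' @export
write_cells_csv <- function(cells, path) {
  cal <- cells_calibration(cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# microns_per_pixel=%.10g width_px=%d height_px=%d",
                     cal$microns_per_pixel, cal$width_px, cal$height_px), con)
  utils::write.csv(as.data.frame(cells[, c("x_px", "y_px", "label")]),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "^#\\s*microns_per_pixel=([0-9.eE+-]+)\\s+width_px=(\\d+)\\s+height_px=(\\d+)",
    hdr))[[1]]
  if (length(m) != 4L) {
    stop("missing calibration metadata line in ", path, call. = FALSE)
  }
  cal <- calibration(as.numeric(m[2]), as.integer(m[3]), as.integer(m[4]))
  df <- utils::read.csv(path, comment.char = "#")
  cell_detections(df$x_px, df$y_px, df$label, cal)
}

#' Write / read cell detections as GeoJSON point features
#'
#' Each detection is a `Point` feature with a `label` property; the
#' calibration travels in the top-level `properties`.
#' @param cells A [cell_detections()] tibble.
#' @param path GeoJSON path.
#' @export
write_cells_geojson <- function(cells, path) {
  cal <- cells_calibration(cells)
  features <- purrr::pmap(cells[, c("x_px", "y_px", "label")],
    function(x_px, y_px, label) {
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(x_px, y_px)),
           properties = list(label = label))
    })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         properties = list(microns_per_pixel = cal$microns_per_pixel,
                           width_px = cal$width_px,
                           height_px = cal$height_px),
         features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cells_geojson
#' @export
read_cells_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  pr <- js$properties
  if (is.null(pr$microns_per_pixel)) {
    stop("GeoJSON lacks calibration properties in ", path, call. = FALSE)
  }
  cal <- calibration(pr$microns_per_pixel, pr$width_px, pr$height_px)
  xy <- purrr::map(js$features, function(f) {
    c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]])
  })
  lab <- purrr::map_chr(js$features, function(f) f$properties$label)
  if (length(xy)) {
    mat <- do.call(rbind, xy)
    cell_detections(mat[, 1], mat[, 2], lab, cal)
  } else {
    cell_detections(numeric(), numeric(), character(), cal)
  }
}
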