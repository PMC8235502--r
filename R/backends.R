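#' Default color code table shared by the synthetic renderer and the
#' reference backends
#'
#' RGB triplets (0-255) for the glass background, the four tissue classes,
#' and the two rendered cell classes. The reference backends invert these
#' codes; a backend for real H&E stains would replace them.
#' @return Named list of length-3 integer vectors.
#' @export
default_palette <- function() {
  list(
    BACKGROUND             = c(242L, 242L, 240L),
    STROMA                 = c(231L, 180L, 188L),
    TUMOR                  = c(121L,  64L, 143L),
    NECROSIS               = c(196L, 166L, 121L),
    NONINVASIVE_EPITHELIUM = c( 96L, 129L,  66L),
    CELL_TIL               = c( 38L,  44L, 164L),
    CELL_OTHER             = c(168L,  40L,  40L)
  )
}

#' Synthetic RGB slide image
#'
#' @param rgb Numeric array `height x width x 3`, values in 0-255.
#' @param cal A [calibration()].
#' @return A `stil_slide_image`.
#' @export
slide_image <- function(rgb, cal) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L,
            inherits(cal, "stil_calibration"),
            dim(rgb)[1] == cal$height_px, dim(rgb)[2] == cal$width_px,
            min(rgb) >= 0, max(rgb) <= 255)
  structure(list(rgb = rgb, calibration = cal), class = "stil_slide_image")
}

#' @export
print.stil_slide_image <- function(x, ...) {
  cat(sprintf("<slide image> %d x %d px @ %g um/px\n",
              x$calibration$width_px, x$calibration$height_px,
              x$calibration$microns_per_pixel))
  invisible(x)
}

#' Construct an inference-backend contract
#'
#' A backend wraps one of the three inference stages of the pipeline:
#' tissue-vs-glass detection (`TISSUE_DETECT`, returns a [binary_mask()]),
#' tissue-class segmentation (`TISSUE_SEGMENT`, returns a [label_mask()]),
#' or cell detection (`CELL_DETECT`, returns [cell_detections()]). Trained
#' models plug in through this contract; the shipped reference backends are
#' deterministic rules that invert the synthetic renderer's color codes.
#'
#' @param name Backend identifier.
#' @param stage One of `"TISSUE_DETECT"`, `"TISSUE_SEGMENT"`, `"CELL_DETECT"`.
#' @param fn The inference function; its signature must match the stage
#'   (see [detect_tissue()], [segment_tissue()], [detect_cells()]).
#' @param config Named list of backend settings, kept for provenance.
#' @param class_definition Free-text description of the cell-class boundary
#'   the backend implements (e.g. which mononuclear cells count as TILs).
#' @export
stil_backend <- function(name, stage, fn, config = list(),
                         class_definition = NULL) {
  stage <- match.arg(stage, c("TISSUE_DETECT", "TISSUE_SEGMENT", "CELL_DETECT"))
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  structure(list(name = name, stage = stage, fn = fn, config = config,
                 class_definition = class_definition),
            class = "stil_backend")
}

#' @export
print.stil_backend <- function(x, ...) {
  cat(sprintf("<backend '%s'> stage %s\n", x$name, x$stage))
  invisible(x)
}

rgb_dist <- function(rgb, color) {
  sqrt((rgb[, , 1] - color[1])^2 + (rgb[, , 2] - color[2])^2 +
         (rgb[, , 3] - color[3])^2)
}

#' Reference tissue detection: chromatic distance from the glass color
#'
#' Marks a pixel as tissue when its RGB distance from the configured
#' background (glass) color exceeds `threshold`, then drops connected
#' components smaller than `min_area_mm2`.
#'
#' @param image A [slide_image()].
#' @param palette Color table, see [default_palette()].
#' @param threshold Chromatic distance threshold (8-bit RGB units).
#' @param min_area_mm2 Minimum component area kept, in mm^2.
#' @return A [binary_mask()]; `TRUE` = tissue.
#' @export
detect_tissue <- function(image, palette = default_palette(),
                          threshold = 30, min_area_mm2 = 0.01) {
  stopifnot(inherits(image, "stil_slide_image"))
  tissue <- rgb_dist(image$rgb, palette$BACKGROUND) > threshold
  if (any(tissue) && min_area_mm2 > 0) {
    lab <- label_components(tissue)
    areas <- tabulate(lab[lab > 0L])
    min_px <- min_area_mm2 / px_area_mm2(image$calibration)
    keep <- which(areas >= min_px)
    tissue <- matrix(lab %in% keep, nrow(tissue), ncol(tissue))
  }
  binary_mask(tissue, image$calibration)
}

#' Reference tissue segmentation: nearest-color class assignment
#'
#' Assigns every tissue pixel the tissue class whose palette color is
#' nearest in RGB. Rendered cell pixels are not a tissue class; by default
#' (`cell_host = "nearest"`) they inherit the class of the nearest
#' non-cell tissue pixel by an iterative 4-neighbour fill, so a cell lying
#' in tumor stays tumor at the pixel level. A fixed class name can be
#' given instead. Non-tissue pixels become BACKGROUND.
#'
#' @param image A [slide_image()].
#' @param tissue A [binary_mask()] from [detect_tissue()].
#' @param palette Color table, see [default_palette()].
#' @param cell_host `"nearest"` or a tissue class name for rendered cell
#'   pixels.
#' @param strict If `TRUE`, error when a tissue pixel's nearest color is
#'   farther than `strict_tol` (an unmappable color), listing the color.
#' @param strict_tol RGB distance beyond which a color is unmappable.
#' @return A [label_mask()].
#' @export
segment_tissue <- function(image, tissue, palette = default_palette(),
                           cell_host = "nearest", strict = FALSE,
                           strict_tol = 60) {
  stopifnot(inherits(image, "stil_slide_image"),
            inherits(tissue, "stil_binary_mask"))
  check_same_calibration(image$calibration, tissue$calibration,
                         "image and tissue mask")
  cls <- stil_classes()
  targets <- c("STROMA", "TUMOR", "NECROSIS", "NONINVASIVE_EPITHELIUM",
               "CELL_TIL", "CELL_OTHER")
  cell_code <- -1L  # placeholder resolved below
  codes <- c(cls[["STROMA"]], cls[["TUMOR"]], cls[["NECROSIS"]],
             cls[["NONINVASIVE_EPITHELIUM"]],
             if (identical(cell_host, "nearest")) c(cell_code, cell_code)
             else rep(cls[[cell_host]], 2))
  d <- vapply(targets, function(nm) rgb_dist(image$rgb, palette[[nm]]),
              matrix(0, nrow(tissue$raster), ncol(tissue$raster)))
  dim(d) <- c(length(tissue$raster), length(targets))
  best <- max.col(-d, ties.method = "first")
  if (strict) {
    mind <- d[cbind(seq_len(nrow(d)), best)]
    bad <- which(tissue$raster & matrix(mind > strict_tol,
                                        nrow(tissue$raster)))
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf(
        "unmappable color rgb(%d,%d,%d) at %d tissue pixel(s)",
        round(image$rgb[, , 1][i]), round(image$rgb[, , 2][i]),
        round(image$rgb[, , 3][i]), length(bad)), call. = FALSE)
    }
  }
  out <- matrix(codes[best], nrow(tissue$raster), ncol(tissue$raster))
  out[!tissue$raster] <- cls[["BACKGROUND"]]
  if (identical(cell_host, "nearest")) {
    out <- fill_from_neighbours(out, out == cell_code,
                                fallback = cls[["STROMA"]])
  }
  label_mask(out, image$calibration)
}

# Resolve marked pixels from resolved 4-neighbours, iterating inward;
# deterministic neighbour order (up, down, left, right). Pixels never
# reached (a marked region wider than max_iter) take the fallback class.
fill_from_neighbours <- function(out, unresolved, fallback,
                                 max_iter = 16L) {
  nr <- nrow(out); nc <- ncol(out)
  for (it in seq_len(max_iter)) {
    idx <- which(unresolved)
    if (!length(idx)) break
    shifted <- function(dr, dc) {
      r <- (idx - 1L) %% nr + 1L + dr
      c <- (idx - 1L) %/% nr + 1L + dc
      ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
      v <- rep(NA_integer_, length(idx))
      nb <- (c[ok] - 1L) * nr + r[ok]
      v[ok] <- ifelse(unresolved[nb], NA_integer_, out[nb])
      v
    }
    cand <- shifted(-1L, 0L)
    for (sh in list(c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      miss <- is.na(cand)
      if (!any(miss)) break
      cand[miss] <- shifted(sh[1], sh[2])[miss]
    }
    got <- !is.na(cand)
    out[idx[got]] <- cand[got]
    unresolved[idx[got]] <- FALSE
    if (!any(got)) break
  }
  out[unresolved] <- fallback
  out
}

# Boundary-pixel perimeter (4-neighbourhood): pixels of the component with
# at least one 4-neighbor outside it. Circularity 4*pi*A/P^2 with this P is
# ~2.5 for a small discretized disc and < 0.3 for an elongated bar, so a 0.6
# threshold separates round nuclei from fragments.
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          perim_px = integer(), cx = numeric(),
                          cy = numeric()))
  }
  inside <- lab > 0L
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up <- pad[1:nr, 2:(nc + 1)]; down <- pad[3:(nr + 2), 2:(nc + 1)]
  left <- pad[2:(nr + 1), 1:nc]; right <- pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- inside & (up != core | down != core | left != core |
                          right != core)
  idx <- which(inside)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  tibble::tibble(
    id = seq_len(n),
    area_px = tabulate(ids, n),
    perim_px = tabulate(lab[boundary], n),
    cx = as.numeric(tapply(cols - 1L, ids, mean)),
    cy = as.numeric(tapply(rows - 1L, ids, mean))
  )
}

#' Reference cell detection: color threshold + shape filter
#'
#' Thresholds pixels near each rendered cell color, extracts 4-connected
#' components, keeps those with area in `[min_area_um2, max_area_um2]` and
#' circularity `4*pi*A/P^2 >= c_min` (P = boundary-pixel count), and returns
#' component centroids whose nearest pixel lies in `roi`.
#'
#' @param image A [slide_image()].
#' @param roi A [binary_mask()] restricting reported centroids.
#' @param palette Color table, see [default_palette()].
#' @param color_tol RGB distance tolerance for cell-color membership.
#' @param min_area_um2,max_area_um2 Component area window (um^2).
#' @param c_min Minimum circularity.
#' @return [cell_detections()] with labels `TIL` / `OTHER`.
#' @export
detect_cells <- function(image, roi, palette = default_palette(),
                         color_tol = 40, min_area_um2 = 12,
                         max_area_um2 = 120, c_min = 0.6) {
  stopifnot(inherits(image, "stil_slide_image"),
            inherits(roi, "stil_binary_mask"))
  check_same_calibration(image$calibration, roi$calibration, "image and roi")
  cal <- image$calibration
  pa_um2 <- cal$microns_per_pixel^2
  one_class <- function(color, lab_name) {
    hit <- rgb_dist(image$rgb, color) <= color_tol
    st <- component_stats(label_components(hit))
    st <- dplyr::filter(
      st,
      .data$area_px * pa_um2 >= min_area_um2,
      .data$area_px * pa_um2 <= max_area_um2,
      4 * pi * .data$area_px / pmax(.data$perim_px, 1L)^2 >= c_min
    )
    dplyr::mutate(st, label = lab_name)
  }
  st <- dplyr::bind_rows(one_class(palette$CELL_TIL, "TIL"),
                         one_class(palette$CELL_OTHER, "OTHER"))
  st <- dplyr::arrange(st, .data$label, .data$cy, .data$cx)
  cells <- cell_detections(st$cx, st$cy, st$label, cal)
  keep <- roi$raster[snap_to_pixel(cells$x_px, cells$y_px, cal)]
  if (nrow(cells) == 0L) keep <- logical(0)
  restore_cells(cells[keep, , drop = FALSE], cells)
}
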