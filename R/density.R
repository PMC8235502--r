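#' sTIL density in the tumor-associated stroma
#'
#' The biomarker itself: number of kept TIL detections per mm^2 of
#' tumor-associated stroma. The density is reported unrounded; any display
#' rounding happens at the CLI so cutpoint comparisons never depend on
#' formatting.
#'
#' @param kept Kept detections from [filter_tils()] (only `TIL`-labeled
#'   points are counted).
#' @param stroma Tumor-associated-stroma [binary_mask()]; must have
#'   positive area.
#' @param heatmap Optional heatmap matrix from [local_density_heatmap()]
#'   to bundle into the result.
#' @param params Optional [geometry_params()] recorded in the result.
#' @param heatmap_radius_um Radius recorded alongside the heatmap.
#' @return A `stil_biomarker_result` with `stil_density_per_mm2`,
#'   `til_count`, `stroma_area_mm2`, `heatmap`, `params`, `provenance`.
#' @export
compute_density <- function(kept, stroma, heatmap = NULL,
                            params = NULL, heatmap_radius_um = 200) {
  stopifnot(inherits(stroma, "stil_binary_mask"))
  cal <- cells_calibration(kept)
  check_same_calibration(cal, stroma$calibration, "cells and stroma")
  area <- mask_area_mm2(stroma)
  if (area <= 0) {
    stop("undefined density: tumor-associated stroma has zero area",
         call. = FALSE)
  }
  n_til <- sum(kept$label == "TIL")
  structure(list(
    stil_density_per_mm2 = n_til / area,
    til_count = as.integer(n_til),
    stroma_area_mm2 = area,
    heatmap = heatmap,
    params = params,
    heatmap_radius_um = heatmap_radius_um,
    provenance = list(
      package_version = as.character(utils::packageVersion("stilquant")),
      microns_per_pixel = cal$microns_per_pixel,
      stroma_hash = hash_object(stroma$raster),
      cells_hash = hash_object(kept[, c("x_px", "y_px", "label")])
    )
  ), class = "stil_biomarker_result")
}

#' @export
print.stil_biomarker_result <- function(x, ...) {
  cat(sprintf(
    "<sTIL biomarker> %.1f cells/mm^2 (%d TILs in %.3f mm^2 stroma)\n",
    x$stil_density_per_mm2, x$til_count, x$stroma_area_mm2))
  invisible(x)
}

#' Local sTIL density heatmap
#'
#' For every stroma pixel, the number of kept TILs within `radius_um`
#' divided by the area (mm^2) of the disk intersected with the stroma, so
#' densities at stroma boundaries are not diluted by non-stroma area.
#' Non-stroma pixels are `NA`. Points are snapped to their nearest pixel
#' center before counting.
#'
#' @param kept Kept TIL detections ([cell_detections()]).
#' @param stroma Tumor-associated-stroma [binary_mask()].
#' @param radius_um Kernel radius in microns (> 0).
#' @return Numeric matrix (cells/mm^2) of the stroma's dimensions.
#' @export
local_density_heatmap <- function(kept, stroma, radius_um = 200) {
  stopifnot(inherits(stroma, "stil_binary_mask"), radius_um > 0)
  cal <- cells_calibration(kept)
  check_same_calibration(cal, stroma$calibration, "cells and stroma")
  k <- disk_kernel(radius_px_checked(cal, radius_um))
  counts <- matrix(0, nrow(stroma$raster), ncol(stroma$raster))
  tils <- kept[kept$label == "TIL", , drop = FALSE]
  if (nrow(tils) > 0L) {
    idx <- snap_to_pixel(tils$x_px, tils$y_px, cal)
    for (i in seq_len(nrow(idx))) {
      counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
    }
  }
  local_n <- conv_count(counts, k)
  local_area <- conv_count(stroma$raster * 1, k) * px_area_mm2(cal)
  heat <- local_n / local_area
  heat[!stroma$raster] <- NA_real_
  heat[stroma$raster & local_area == 0] <- 0  # unreachable: pixel itself in stroma
  heat
}

# Small fixed color ramp (dark blue -> yellow); linear interpolation.
heat_ramp <- function(v) {
  anchors <- rbind(c(13, 8, 135), c(126, 3, 168), c(204, 71, 120),
                   c(248, 149, 64), c(240, 249, 33))
  v <- pmin(pmax(v, 0), 1)
  pos <- v * (nrow(anchors) - 1)
  lo <- pmin(floor(pos) + 1, nrow(anchors) - 1)
  fr <- pos - (lo - 1)
  anchors[lo, ] * (1 - fr) + anchors[lo + 1, ] * fr
}

#' Render a local-density heatmap to a color PNG
#'
#' Writes an 8-bit RGB PNG via a fixed value-to-color ramp: values map
#' linearly from 0 (dark blue) to `vmax` (yellow), values above `vmax` are
#' clamped to the top color, `NA` (non-stroma) pixels are light gray. A
#' color-ramp strip and a 1 mm scale bar are drawn along the bottom edge;
#' the numeric legend (value range, clamping) is written to a JSON sidecar
#' so the PNG bytes are a pure function of the input.
#'
#' @param heatmap Matrix from [local_density_heatmap()].
#' @param path Output PNG path.
#' @param cal A [calibration()] (for the scale bar); optional.
#' @param vmax Ramp maximum in cells/mm^2; defaults to the finite maximum.
#' @return `path`, invisibly; sidecar at `<path>.json`.
#' @export
render_heatmap <- function(heatmap, path, cal = NULL, vmax = NULL) {
  stopifnot(is.matrix(heatmap))
  fin <- heatmap[is.finite(heatmap)]
  if (is.null(vmax)) vmax <- if (length(fin)) max(fin) else 0
  clamped <- length(fin) > 0 && any(fin > vmax)
  norm <- if (vmax > 0) heatmap / vmax else heatmap * 0
  nr <- nrow(heatmap); nc <- ncol(heatmap)
  img <- array(0.85, dim = c(nr, nc, 3))  # light-gray background
  ok <- which(is.finite(heatmap))
  if (length(ok)) {
    cols <- heat_ramp(norm[ok]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ok] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  # bottom strip: color ramp over the left half, black 1 mm scale bar right
  strip_h <- max(4L, nr %/% 50)
  ramp_cols <- heat_ramp(seq(0, 1, length.out = nc %/% 2)) / 255
  for (ch in 1:3) {
    img[(nr - strip_h + 1):nr, seq_len(nc %/% 2), ch] <-
      matrix(ramp_cols[, ch], strip_h, nc %/% 2, byrow = TRUE)
  }
  if (!is.null(cal)) {
    bar_px <- min(nc %/% 3, max(1L, round(um_to_px(cal, 1000))))
    img[(nr - strip_h + 1):nr, (nc - bar_px + 1):nc, ] <- 0
  }
  png::writePNG(img, path)
  jsonlite::write_json(
    list(value_min = 0, value_max = vmax, units = "cells/mm^2",
         clamped_above_max = clamped,
         ramp = "dark blue (0) to yellow (max), non-stroma gray",
         scale_bar_um = if (is.null(cal)) NULL else 1000),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a biomarker result as JSON (+ heatmap rasters)
#'
#' The scalar result goes to `<dir>/biomarker.json`; when a heatmap is
#' present it is written as a 32-bit float TIFF and a rendered PNG.
#'
#' @param result A [compute_density()] result.
#' @param dir Output directory.
#' @param cal Optional [calibration()] for the rendered heatmap scale bar.
#' @export
write_biomarker_result <- function(result, dir, cal = NULL) {
  stopifnot(inherits(result, "stil_biomarker_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stil_density_per_mm2 = result$stil_density_per_mm2,
         til_count = result$til_count,
         stroma_area_mm2 = result$stroma_area_mm2,
         heatmap_radius_um = result$heatmap_radius_um,
         params = if (is.null(result$params)) NULL else
           unclass(result$params),
         provenance = result$provenance),
    file.path(dir, "biomarker.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (!is.null(result$heatmap)) {
    hm <- result$heatmap
    vmax <- max(hm[is.finite(hm)], 1e-12)
    hm_norm <- hm / vmax
    hm_norm[!is.finite(hm_norm)] <- 0  # non-stroma sentinel, see sidecar
    tiff::writeTIFF(hm_norm, file.path(dir, "heatmap.tif"),
                    bits.per.sample = 32L)
    jsonlite::write_json(
      list(scale_cells_per_mm2 = vmax,
           note = "pixel value x scale = local density; non-stroma = 0"),
      file.path(dir, "heatmap.tif.json"), auto_unbox = TRUE, digits = NA)
    render_heatmap(result$heatmap, file.path(dir, "heatmap.png"), cal = cal)
  }
  invisible(dir)
}

# md5 of an object via its canonical JSON serialization (base tools only).
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
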