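#' Geometry parameters of the tumor-microenvironment delineation
#'
#' Physical parameters of the macro-tumor outline and the TIL exclusion
#' rules. Defaults follow the published guideline-compliant workflow:
#' a 750 um circular kernel scores local accumulated tumor area, closing and
#' opening smooth the outline, a 250 um invasive margin is added to the
#' stroma, and TILs within 150 um of non-invasive epithelium are excluded.
#' The kernel threshold converting local tumor fraction into macro-tumor
#' membership and the structuring-element radius are not fixed by the
#' guideline; their defaults (0.10, 250 um) are package choices and are
#' recorded in every output's provenance.
#'
#' @param kernel_radius_um Local tumor-area kernel radius (um).
#' @param tumor_fraction_threshold Minimum local tumor fraction, in (0, 1].
#' @param morph_radius_um Closing/opening structuring-element radius (um).
#' @param margin_um Invasive-margin width added around the macro tumor (um).
#' @param epi_exclusion_um Exclusion buffer around non-invasive epithelium (um).
#' @return A `stil_geometry_params` list.
#' @export
geometry_params <- function(kernel_radius_um = 750,
                            tumor_fraction_threshold = 0.10,
                            morph_radius_um = 250,
                            margin_um = 250,
                            epi_exclusion_um = 150) {
  stopifnot(kernel_radius_um > 0,
            tumor_fraction_threshold > 0, tumor_fraction_threshold <= 1,
            morph_radius_um > 0, margin_um >= 0, epi_exclusion_um >= 0)
  structure(list(kernel_radius_um = kernel_radius_um,
                 tumor_fraction_threshold = tumor_fraction_threshold,
                 morph_radius_um = morph_radius_um,
                 margin_um = margin_um,
                 epi_exclusion_um = epi_exclusion_um),
            class = "stil_geometry_params")
}

#' Macro-tumor outline from a class-labeled mask
#'
#' Mimics the macro outline a pathologist would draw around the whole tumor:
#' pixels whose local tumor-area fraction under the circular kernel reaches
#' `tumor_fraction_threshold` are smoothed by closing/opening and clipped to
#' tissue. An input without tumor pixels yields an empty mask flagged with
#' `attr(, "empty") = TRUE`; downstream density computation refuses such a
#' partition.
#'
#' @param labels A [label_mask()].
#' @param params A [geometry_params()].
#' @return A [binary_mask()]; attribute `empty` is `TRUE` when no macro
#'   tumor was found.
#' @export
macro_tumor_outline <- function(labels, params = geometry_params()) {
  stopifnot(inherits(labels, "stil_label_mask"),
            inherits(params, "stil_geometry_params"))
  tumor <- class_mask(labels, "TUMOR")
  if (!any(tumor$raster)) {
    out <- binary_mask(matrix(FALSE, nrow(labels$raster),
                              ncol(labels$raster)), labels$calibration)
    attr(out, "empty") <- TRUE
    return(out)
  }
  frac <- disk_kernel_fraction(tumor, params$kernel_radius_um)
  cand <- binary_mask(frac >= params$tumor_fraction_threshold,
                      labels$calibration)
  sm <- morph_close_open(cand, params$morph_radius_um)
  out <- binary_mask(sm$raster & tissue_mask(labels)$raster,
                     labels$calibration)
  attr(out, "empty") <- !any(out$raster)
  out
}

#' Tumor-associated stroma including the invasive margin
#'
#' Stroma-class pixels inside the macro-tumor outline extended by the
#' invasive margin: `(macro U dilate(macro, margin_um))` intersected with
#' tissue, minus tumor, necrosis, and non-invasive epithelium.
#'
#' @param labels A [label_mask()].
#' @param macro Macro-tumor [binary_mask()] from [macro_tumor_outline()].
#' @param params A [geometry_params()].
#' @return A [binary_mask()].
#' @export
tumor_associated_stroma <- function(labels, macro,
                                    params = geometry_params()) {
  stopifnot(inherits(labels, "stil_label_mask"),
            inherits(macro, "stil_binary_mask"),
            inherits(params, "stil_geometry_params"))
  check_same_calibration(labels$calibration, macro$calibration,
                         "labels and macro mask")
  if (!any(macro$raster)) {
    stop("empty macro-tumor mask: tumor-associated stroma is undefined",
         call. = FALSE)
  }
  extended <- dilate_um(macro, params$margin_um)$raster | macro$raster
  cls <- stil_classes()
  excluded <- labels$raster %in% c(cls[["TUMOR"]], cls[["NECROSIS"]],
                                   cls[["NONINVASIVE_EPITHELIUM"]])
  dim(excluded) <- dim(labels$raster)
  binary_mask(extended & tissue_mask(labels)$raster & !excluded,
              labels$calibration)
}

#' TIL exclusion zone
#'
#' Union of tumor pixels, necrosis pixels (which also covers a central
#' hyalinized scar, provided the segmentation labels it NECROSIS), and
#' non-invasive epithelium dilated by `epi_exclusion_um` to shed the dense
#' lymphoid aggregates that surround such lesions. The component masks are
#' kept in `attr(, "components")` so TIL filtering can report which rule
#' fired.
#'
#' @param labels A [label_mask()].
#' @param params A [geometry_params()].
#' @return A [binary_mask()] with attribute `components` (named list of
#'   binary masks `tumor`, `necrosis`, `near_epithelium`).
#' @export
exclusion_zone <- function(labels, params = geometry_params()) {
  stopifnot(inherits(labels, "stil_label_mask"),
            inherits(params, "stil_geometry_params"))
  tumor <- class_mask(labels, "TUMOR")
  necrosis <- class_mask(labels, "NECROSIS")
  epi <- dilate_um(class_mask(labels, "NONINVASIVE_EPITHELIUM"),
                   params$epi_exclusion_um)
  out <- binary_mask(tumor$raster | necrosis$raster | epi$raster,
                     labels$calibration)
  attr(out, "components") <- list(tumor = tumor, necrosis = necrosis,
                                  near_epithelium = epi)
  out
}

#' Audit codes assigned by [filter_tils()]
#' @export
til_audit_codes <- function() {
  c("KEPT", "IN_TUMOR", "IN_NECROSIS", "NEAR_EPI", "OUTSIDE_STROMA",
    "NOT_TIL")
}

#' Filter TIL detections to the tumor-associated stroma
#'
#' Keeps TIL-labeled points whose nearest pixel lies in the
#' tumor-associated stroma and outside every exclusion zone. Every input
#' point receives exactly one audit code, with deterministic precedence
#' `IN_TUMOR > IN_NECROSIS > NEAR_EPI > OUTSIDE_STROMA` when zones overlap;
#' non-TIL points are coded `NOT_TIL`.
#'
#' @param cells A [cell_detections()] tibble.
#' @param stroma Tumor-associated-stroma [binary_mask()].
#' @param zone Exclusion [binary_mask()] from [exclusion_zone()] (its
#'   `components` attribute drives the per-rule audit codes).
#' @return The kept detections (point order preserved), with attributes
#'   `audit` (tibble: `x_px`, `y_px`, `label`, `code`) and `counts` (named
#'   integer vector over [til_audit_codes()]).
#' @export
filter_tils <- function(cells, stroma, zone) {
  stopifnot(inherits(stroma, "stil_binary_mask"),
            inherits(zone, "stil_binary_mask"))
  cal <- cells_calibration(cells)
  check_same_calibration(cal, stroma$calibration, "cells and stroma")
  check_same_calibration(cal, zone$calibration, "cells and exclusion zone")
  comp <- attr(zone, "components")
  n <- nrow(cells)
  code <- rep("KEPT", n)
  if (n > 0L) {
    idx <- snap_to_pixel(cells$x_px, cells$y_px, cal)
    in_tumor <- if (!is.null(comp)) comp$tumor$raster[idx] else
      rep(FALSE, n)
    in_necr <- if (!is.null(comp)) comp$necrosis$raster[idx] else
      rep(FALSE, n)
    near_epi <- if (!is.null(comp)) comp$near_epithelium$raster[idx] else
      zone$raster[idx]
    in_stroma <- stroma$raster[idx]
    code[!in_stroma] <- "OUTSIDE_STROMA"
    code[near_epi] <- "NEAR_EPI"
    code[in_necr] <- "IN_NECROSIS"
    code[in_tumor] <- "IN_TUMOR"
    code[cells$label != "TIL"] <- "NOT_TIL"
  }
  audit <- tibble::tibble(x_px = cells$x_px, y_px = cells$y_px,
                          label = cells$label, code = code)
  kept <- restore_cells(cells[code == "KEPT", , drop = FALSE], cells)
  attr(kept, "audit") <- audit
  attr(kept, "counts") <- vapply(til_audit_codes(),
                                 function(cd) sum(code == cd), integer(1))
  kept
}

#' Full region partition of one slide
#'
#' Runs [macro_tumor_outline()], [tumor_associated_stroma()], and
#' [exclusion_zone()] and bundles the results with their parameters.
#'
#' @param labels A [label_mask()].
#' @param params A [geometry_params()].
#' @return A `stil_region_partition` with fields `macro_tumor`,
#'   `tumor_associated_stroma`, `exclusion_zone`, `params`, `empty`.
#' @export
region_partition <- function(labels, params = geometry_params()) {
  macro <- macro_tumor_outline(labels, params)
  if (isTRUE(attr(macro, "empty"))) {
    return(structure(list(macro_tumor = macro, tumor_associated_stroma = NULL,
                          exclusion_zone = NULL, params = params,
                          empty = TRUE),
                     class = "stil_region_partition"))
  }
  structure(list(
    macro_tumor = macro,
    tumor_associated_stroma = tumor_associated_stroma(labels, macro, params),
    exclusion_zone = exclusion_zone(labels, params),
    params = params,
    empty = FALSE
  ), class = "stil_region_partition")
}

#' Write a region partition as PNG masks + provenance JSON
#' @param partition A [region_partition()].
#' @param dir Output directory (created if missing).
#' @export
write_region_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "stil_region_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_binary_mask(partition$macro_tumor, file.path(dir, "macro_tumor.png"))
  if (!partition$empty) {
    write_binary_mask(partition$tumor_associated_stroma,
                      file.path(dir, "tumor_associated_stroma.png"))
    write_binary_mask(partition$exclusion_zone,
                      file.path(dir, "exclusion_zone.png"))
  }
  jsonlite::write_json(
    c(unclass(partition$params), list(empty = partition$empty)),
    file.path(dir, "geometry_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
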