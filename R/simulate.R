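#' Specification of a synthetic slide
#'
#' Defines a deterministic synthetic slide: an elliptical tissue region on
#' glass, invasive tumor blobs with necrotic cores, non-invasive (DCIS-like)
#' epithelial blobs with surrounding dense lymphoid aggregates, stromal TILs
#' from a (optionally spatially varying) Poisson process, decoy TILs inside
#' exclusion regions, and OTHER-class mononuclear cells. The same spec and
#' seed always produce bit-identical output.
#'
#' @param microns_per_pixel,width_px,height_px Raster calibration (default
#'   4 x 4 mm at 2 um/px).
#' @param n_tumor_blobs Number of invasive tumor discs.
#' @param tumor_radius_um Range the blob radii are drawn from.
#' @param tumor_center_jitter Half-width (as a fraction of the slide) of
#'   the uniform window around the slide center that blob centers are drawn
#'   from.
#' @param necrosis_fraction Necrotic core radius as a fraction of the blob
#'   radius (0 disables necrosis).
#' @param n_dcis Number of non-invasive epithelial blobs placed in stroma.
#' @param dcis_radius_um DCIS blob radius.
#' @param til_intensity_per_mm2 Stromal TIL intensity (cells/mm^2).
#' @param til_field_amplitude Relative amplitude (0..1) of a low-frequency
#'   sinusoidal modulation of the stromal TIL intensity; 0 = homogeneous.
#' @param decoy_intensity_per_mm2 TIL intensity inside tumor and necrosis.
#' @param dcis_aggregate_intensity_per_mm2 TIL intensity in the stromal ring
#'   (up to `dcis_aggregate_width_um`) around DCIS blobs, emulating the
#'   dense lymphoid aggregates such lesions attract.
#' @param dcis_aggregate_width_um Width of that ring.
#' @param other_intensity_per_mm2 Intensity of OTHER-class cells in stroma.
#' @param cell_radius_um Rendered cell disc radius.
#' @param min_spacing_um Minimum center-to-center distance between rendered
#'   cells (Matern-II thinning; 0 keeps the pure Poisson process). Ground
#'   truth lists the retained points.
#' @param palette Color table, see [default_palette()].
#' @param seed Integer seed; part of the spec.
#' @return A `stil_slide_spec` list.
#' @export
slide_spec <- function(microns_per_pixel = 2, width_px = 2000,
                       height_px = 2000, n_tumor_blobs = 3,
                       tumor_radius_um = c(400, 900),
                       tumor_center_jitter = 0.2,
                       necrosis_fraction = 0.3, n_dcis = 2,
                       dcis_radius_um = 120,
                       til_intensity_per_mm2 = 400,
                       til_field_amplitude = 0,
                       decoy_intensity_per_mm2 = 150,
                       dcis_aggregate_intensity_per_mm2 = 2000,
                       dcis_aggregate_width_um = 100,
                       other_intensity_per_mm2 = 100,
                       cell_radius_um = 4, min_spacing_um = 0,
                       palette = default_palette(), seed = 1) {
  stopifnot(til_intensity_per_mm2 >= 0, decoy_intensity_per_mm2 >= 0,
            other_intensity_per_mm2 >= 0,
            til_field_amplitude >= 0, til_field_amplitude <= 1,
            necrosis_fraction >= 0, necrosis_fraction < 1,
            min_spacing_um >= 0)
  structure(as.list(environment()), class = "stil_slide_spec")
}

disc_raster <- function(nr, nc, cy, cx, r_px) {
  rows <- matrix(seq_len(nr) - 1L, nr, nc)
  cols <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r_px^2
}

# Homogeneous / thinned Poisson sample over the TRUE pixels of a region.
# Count is Poisson(intensity x region area); positions are uniform within
# the region with sub-pixel jitter. `field` (same dims, mean free) scales
# the local intensity by thinning from its maximum.
sample_points_in_region <- function(region, intensity_per_mm2, cal,
                                    field = NULL) {
  idx <- which(region)
  area <- length(idx) * px_area_mm2(cal)
  if (length(idx) == 0L || intensity_per_mm2 <= 0) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  fmax <- if (is.null(field)) 1 else max(field[idx])
  n <- stats::rpois(1, intensity_per_mm2 * fmax * area)
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  nr <- nrow(region)
  y <- (pick - 1L) %% nr + stats::runif(n, -0.5, 0.5)
  x <- (pick - 1L) %/% nr + stats::runif(n, -0.5, 0.5)
  if (!is.null(field)) {
    keep <- stats::runif(n) <= field[pick] / fmax
    x <- x[keep]; y <- y[keep]
  }
  cbind(x = pmin(pmax(x, 0), cal$width_px - 1e-6),
        y = pmin(pmax(y, 0), cal$height_px - 1e-6))
}

# Matern-II thinning: drop any point with an earlier-marked point closer
# than min_dist. Deterministic given the marks (here: sampling order).
matern_thin <- function(xy, min_dist) {
  n <- nrow(xy)
  if (n <= 1L || min_dist <= 0) return(rep(TRUE, n))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    if (length(prev)) {
      d2 <- (xy[prev, 1] - xy[i, 1])^2 + (xy[prev, 2] - xy[i, 2])^2
      if (any(d2 < min_dist^2)) keep[i] <- FALSE
    }
  }
  keep
}

#' Render a synthetic slide with full ground truth
#'
#' Rasterizes the spec into an RGB image plus ground truth: the class label
#' mask, the tissue mask, and every placed cell with its true label and
#' compartment. Overlapping region claims are resolved with precedence
#' TUMOR > NECROSIS > NONINVASIVE_EPITHELIUM > STROMA (necrotic cores are
#' carved out of their tumor blob so both classes survive).
#'
#' @param spec A [slide_spec()].
#' @return List with `image` ([slide_image()]), `labels` ([label_mask()]),
#'   `tissue` ([binary_mask()]), `cells` ([cell_detections()] with an extra
#'   `compartment` column: `stroma`, `tumor`, `necrosis`, or `near_dcis`),
#'   and `spec`.
#' @export
render_slide <- function(spec) {
  stopifnot(inherits(spec, "stil_slide_spec"))
  set.seed(spec$seed)
  cal <- calibration(spec$microns_per_pixel, spec$width_px, spec$height_px)
  nr <- spec$height_px; nc <- spec$width_px
  cls <- stil_classes()
  upx <- function(um) um_to_px(cal, um)

  # tissue: centered ellipse covering most of the slide
  rows <- matrix(seq_len(nr) - 1L, nr, nc)
  cols <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  tissue <- ((rows - (nr - 1) / 2) / (0.46 * nr))^2 +
    ((cols - (nc - 1) / 2) / (0.46 * nc))^2 <= 1

  tumor <- matrix(FALSE, nr, nc)
  necro <- matrix(FALSE, nr, nc)
  for (i in seq_len(spec$n_tumor_blobs)) {
    r_px <- upx(stats::runif(1, spec$tumor_radius_um[1],
                             spec$tumor_radius_um[2]))
    jit <- spec$tumor_center_jitter
    cy <- stats::runif(1, (0.5 - jit) * nr, (0.5 + jit) * nr)
    cx <- stats::runif(1, (0.5 - jit) * nc, (0.5 + jit) * nc)
    blob <- disc_raster(nr, nc, cy, cx, r_px)
    tumor <- tumor | blob
    if (spec$necrosis_fraction > 0) {
      necro <- necro | disc_raster(nr, nc, cy, cx,
                                   r_px * spec$necrosis_fraction)
    }
  }
  tumor <- tumor & tissue
  necro <- necro & tumor
  tumor <- tumor & !necro

  # DCIS blobs in stroma, clear of the tumor region
  dcis <- matrix(FALSE, nr, nc)
  if (spec$n_dcis > 0) {
    r_px <- upx(spec$dcis_radius_um)
    clear_px <- r_px + upx(spec$dcis_aggregate_width_um) + upx(100)
    dist_tumor <- dist_to_true_px(tumor | necro)
    placed <- 0L; tries <- 0L
    while (placed < spec$n_dcis && tries < 200L) {
      tries <- tries + 1L
      cy <- stats::runif(1, 0.15 * nr, 0.85 * nr)
      cx <- stats::runif(1, 0.15 * nc, 0.85 * nc)
      at <- cbind(round(cy) + 1L, round(cx) + 1L)
      if (tissue[at] && dist_tumor[at] > clear_px &&
          !dcis[at]) {
        dcis <- dcis | disc_raster(nr, nc, cy, cx, r_px)
        placed <- placed + 1L
      }
    }
  }
  dcis <- dcis & tissue & !tumor & !necro

  labels_raster <- matrix(cls[["BACKGROUND"]], nr, nc)
  labels_raster[tissue] <- cls[["STROMA"]]
  labels_raster[dcis] <- cls[["NONINVASIVE_EPITHELIUM"]]
  labels_raster[necro] <- cls[["NECROSIS"]]
  labels_raster[tumor] <- cls[["TUMOR"]]
  labels <- label_mask(labels_raster, cal)

  stroma_r <- labels_raster == cls[["STROMA"]]
  near_dcis_px <- if (any(dcis)) {
    dist_to_true_px(dcis) <= upx(spec$dcis_aggregate_width_um) + 1e-9
  } else matrix(FALSE, nr, nc)

  field <- NULL
  if (spec$til_field_amplitude > 0) {
    field <- 1 + spec$til_field_amplitude *
      sin(2 * pi * cols / nc) * sin(2 * pi * rows / nr)
  }

  pts_stroma <- sample_points_in_region(stroma_r & !near_dcis_px,
                                        spec$til_intensity_per_mm2, cal,
                                        field)
  pts_aggr <- sample_points_in_region(stroma_r & near_dcis_px,
                                      spec$dcis_aggregate_intensity_per_mm2,
                                      cal)
  pts_decoy <- sample_points_in_region(tumor | necro,
                                       spec$decoy_intensity_per_mm2, cal)
  pts_other <- sample_points_in_region(stroma_r,
                                       spec$other_intensity_per_mm2, cal)

  xy <- rbind(pts_stroma, pts_aggr, pts_decoy, pts_other)
  lab <- c(rep("TIL", nrow(pts_stroma) + nrow(pts_aggr) + nrow(pts_decoy)),
           rep("OTHER", nrow(pts_other)))
  if (spec$min_spacing_um > 0 && nrow(xy) > 1L) {
    keep <- matern_thin(xy, upx(spec$min_spacing_um))
    xy <- xy[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  cells <- cell_detections(xy[, 1], xy[, 2], lab, cal)
  if (nrow(cells)) {
    at <- snap_to_pixel(cells$x_px, cells$y_px, cal)
    code <- labels_raster[at]
    cells$compartment <- dplyr::case_when(
      code == cls[["TUMOR"]] ~ "tumor",
      code == cls[["NECROSIS"]] ~ "necrosis",
      near_dcis_px[at] | code == cls[["NONINVASIVE_EPITHELIUM"]] ~
        "near_dcis",
      TRUE ~ "stroma")
  } else {
    cells$compartment <- character(0)
  }
  cells <- restore_cells(cells, cells)

  pal <- spec$palette
  img <- array(0, dim = c(nr, nc, 3))
  paint <- function(img, mask, color) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- color[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, !tissue, pal$BACKGROUND)
  img <- paint(img, labels_raster == cls[["STROMA"]], pal$STROMA)
  img <- paint(img, dcis, pal$NONINVASIVE_EPITHELIUM)
  img <- paint(img, necro, pal$NECROSIS)
  img <- paint(img, tumor, pal$TUMOR)
  if (nrow(cells)) {
    r_cell <- upx(spec$cell_radius_um)
    off <- which(disk_kernel(max(1, r_cell)) == 1, arr.ind = TRUE)
    off <- off - (floor(max(1, r_cell)) + 1L)
    at <- snap_to_pixel(cells$x_px, cells$y_px, cal)
    stamp <- function(which_cells, color) {
      if (!length(which_cells)) return()
      rr <- rep(at[which_cells, 1], each = nrow(off)) + off[, 1]
      cc <- rep(at[which_cells, 2], each = nrow(off)) + off[, 2]
      okpx <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      lin <- (cc[okpx] - 1L) * nr + rr[okpx]
      plane_n <- as.integer(nr) * as.integer(nc)
      for (ch in 1:3) {
        img[lin + (ch - 1L) * plane_n] <<- color[ch]
      }
    }
    stamp(which(cells$label == "TIL"), pal$CELL_TIL)
    stamp(which(cells$label == "OTHER"), pal$CELL_OTHER)
  }

  list(image = slide_image(img, cal), labels = labels,
       tissue = binary_mask(tissue, cal), cells = cells, spec = spec)
}

#' Specification of a synthetic patient cohort
#'
#' Proportional-hazards survival structure over a log-normal sTIL-density
#' biomarker, either log-linear in density/300 or with a step in the hazard
#' at a density threshold; independent censoring; manual scores coupled to
#' density with reader noise and two-block averaging; clinical covariates
#' matching the standard codings.
#'
#' @param n Number of patients.
#' @param density_meanlog,density_sdlog Log-normal parameters of the sTIL
#'   density (cells/mm^2).
#' @param model `"loglinear"` (hazard multiplier `exp(beta * density/300)`)
#'   or `"step"` (multiplier `exp(beta)` above `step_location`).
#' @param log_hr_per_300 True log hazard ratio per 300 cells/mm^2
#'   (log-linear model).
#' @param step_location,step_log_hr Step-model threshold and log HR.
#' @param baseline_hazard_per_day Exponential baseline hazard.
#' @param censor_max_days Administrative censoring horizon (uniform entry).
#' @param rfs_log_hr_per_300 Log HR of density on relapse.
#' @param relapse_hazard_per_day Baseline relapse hazard.
#' @param manual_noise_sd Reader noise (percent) on each block score.
#' @param block2_missing_prob Probability the second block is unavailable.
#' @param seed Integer seed; part of the spec.
#' @return A `stil_cohort_spec` list.
#' @export
cohort_spec <- function(n = 250, density_meanlog = log(400),
                        density_sdlog = 0.8,
                        model = c("loglinear", "step"),
                        log_hr_per_300 = log(0.8),
                        step_location = 470, step_log_hr = log(0.45),
                        baseline_hazard_per_day = 1 / 2900,
                        censor_max_days = 4380,
                        rfs_log_hr_per_300 = log(0.9),
                        relapse_hazard_per_day = 1 / 4000,
                        manual_noise_sd = 4,
                        block2_missing_prob = 0.3,
                        seed = 1) {
  model <- match.arg(model)
  stopifnot(n >= 1, baseline_hazard_per_day > 0, censor_max_days > 0)
  structure(as.list(environment()), class = "stil_cohort_spec")
}

#' Simulate a patient cohort table
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `id`, `stil_density`, `manual_block1`,
#'   `manual_block2`, `manual_stil_pct`, `os_time`, `os_event`, `rfs_time`,
#'   `rfs_event`, `age_years`, `tumor_size_cm`, `n_positive_nodes`,
#'   `tumor_type`. Relapse-free survival censors at death or last visit.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "stil_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  density <- stats::rlnorm(n, spec$density_meanlog, spec$density_sdlog)

  lp_os <- if (spec$model == "loglinear") {
    spec$log_hr_per_300 * density / 300
  } else {
    spec$step_log_hr * (density >= spec$step_location)
  }
  death <- stats::rexp(n, spec$baseline_hazard_per_day * exp(lp_os))
  censor <- stats::runif(n, 0, spec$censor_max_days)
  os_time <- pmin(death, censor)
  os_event <- as.integer(death <= censor)
  if (!any(os_event == 1)) {
    stop("degenerate cohort spec: no events occurred", call. = FALSE)
  }

  relapse <- stats::rexp(
    n, spec$relapse_hazard_per_day * exp(spec$rfs_log_hr_per_300 *
                                           density / 300))
  rfs_time <- pmin(relapse, os_time)
  rfs_event <- as.integer(relapse <= os_time)

  true_manual <- pmin(100, pmax(0, density / 30))
  block1 <- pmin(100, pmax(0, true_manual + stats::rnorm(n, 0,
                                                         spec$manual_noise_sd)))
  block2 <- pmin(100, pmax(0, true_manual + stats::rnorm(n, 0,
                                                         spec$manual_noise_sd)))
  block2[stats::runif(n) < spec$block2_missing_prob] <- NA_real_

  tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    stil_density = density,
    manual_block1 = block1,
    manual_block2 = block2,
    manual_stil_pct = combine_block_scores(cbind(block1, block2)),
    os_time = os_time, os_event = os_event,
    rfs_time = rfs_time, rfs_event = rfs_event,
    age_years = round(stats::rnorm(n, 56, 12)),
    tumor_size_cm = round(stats::rlnorm(n, log(2), 0.4), 1),
    n_positive_nodes = stats::rpois(n, 1.2),
    tumor_type = sample(c("ductal", "lobular", "other"), n, replace = TRUE,
                        prob = c(0.8, 0.1, 0.1))
  )
}
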