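#' Pipeline configuration
#'
#' Bundles every tunable of the slide- and cohort-level runs so one object
#' fully determines the outputs; the whole config (plus input hashes) is
#' serialized into every artifact's provenance. Unknown keys in a config
#' file are rejected.
#'
#' @param geometry A [geometry_params()].
#' @param heatmap_radius_um Local-density kernel radius (um).
#' @param manual_cutpoint Manual sTIL cutpoint (percent, `>` rule).
#' @param density_cutpoint Density cutpoint (cells/mm^2, `>=` rule), or
#'   `NULL` to select one with [maxstat_cutpoint()].
#' @param maxstat_window Quantile window for the cutpoint scan.
#' @param backend_config Named list passed to the reference backends
#'   (palette, thresholds).
#' @param seed Integer seed for any stochastic step.
#' @return A `stil_pipeline_config`.
#' @export
pipeline_config <- function(geometry = geometry_params(),
                            heatmap_radius_um = 200,
                            manual_cutpoint = 10,
                            density_cutpoint = NULL,
                            maxstat_window = c(0.1, 0.9),
                            backend_config = list(),
                            seed = 1) {
  stopifnot(inherits(geometry, "stil_geometry_params"),
            heatmap_radius_um > 0)
  structure(list(geometry = geometry,
                 heatmap_radius_um = heatmap_radius_um,
                 manual_cutpoint = manual_cutpoint,
                 density_cutpoint = density_cutpoint,
                 maxstat_window = maxstat_window,
                 backend_config = backend_config,
                 seed = as.integer(seed)),
            class = "stil_pipeline_config")
}

config_known_keys <- function() {
  c("geometry", "heatmap_radius_um", "manual_cutpoint", "density_cutpoint",
    "maxstat_window", "backend_config", "seed")
}

#' Read / write a pipeline config as YAML
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_known_keys())
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  geometry <- if (is.null(raw$geometry)) geometry_params() else
    do.call(geometry_params, raw$geometry)
  pipeline_config(
    geometry = geometry,
    heatmap_radius_um = raw$heatmap_radius_um %||% 200,
    manual_cutpoint = raw$manual_cutpoint %||% 10,
    density_cutpoint = raw$density_cutpoint,
    maxstat_window = unlist(raw$maxstat_window) %||% c(0.1, 0.9),
    backend_config = raw$backend_config %||% list(),
    seed = raw$seed %||% 1)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "stil_pipeline_config"))
  out <- unclass(config)
  out$geometry <- unclass(out$geometry)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  hash_object(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x))
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("INFO [stilquant] ", sprintf(...))
  invisible(NULL)
}

#' Run the slide-level pipeline
#'
#' Executes the five pipeline stages in order: tissue detection, tissue
#' segmentation, macro-tumor outlining, cell detection and TIL filtering,
#' and density/heatmap computation. Either a raw synthetic `image` is given
#' (the reference backends run) or precomputed `labels` + `cells` (backends
#' skipped); both routes produce identical results on the same slide.
#' Artifacts written to `out_dir`: region masks, the per-cell audit CSV,
#' `biomarker.json`, and the heatmap (float TIFF + rendered PNG). An empty
#' macro tumor aborts with a documented error after writing the partial
#' partition.
#'
#' @param config A [pipeline_config()].
#' @param image Optional [slide_image()].
#' @param labels Optional [label_mask()] (required if `image` is absent).
#' @param cells Optional [cell_detections()] (required if `image` absent).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param verbose Log the fixed physical parameters and stage progress.
#' @return A list: `result` ([compute_density()] result), `kept`,
#'   `partition`, `labels`, `provenance`.
#' @export
run_slide <- function(config, image = NULL, labels = NULL, cells = NULL,
                      out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "stil_pipeline_config"))
  gp <- config$geometry
  pipeline_log(verbose,
               "geometry: kernel %g um, threshold %g, morph %g um, margin %g um, epi exclusion %g um; heatmap %g um",
               gp$kernel_radius_um, gp$tumor_fraction_threshold,
               gp$morph_radius_um, gp$margin_um, gp$epi_exclusion_um,
               config$heatmap_radius_um)
  bc <- config$backend_config
  if (!is.null(image)) {
    pipeline_log(verbose, "stage 1/5: tissue detection")
    tissue <- do.call(detect_tissue, c(list(image = image),
                                       bc[intersect(names(bc),
                                                    c("palette", "threshold",
                                                      "min_area_mm2"))]))
    pipeline_log(verbose, "stage 2/5: tissue segmentation")
    labels <- do.call(segment_tissue,
                      c(list(image = image, tissue = tissue),
                        bc[intersect(names(bc), c("palette", "cell_host",
                                                  "strict", "strict_tol"))]))
    pipeline_log(verbose, "stage 4/5: cell detection")
    cells <- do.call(detect_cells,
                     c(list(image = image, roi = tissue),
                       bc[intersect(names(bc),
                                    c("palette", "color_tol", "min_area_um2",
                                      "max_area_um2", "c_min"))]))
  }
  if (is.null(labels) || is.null(cells)) {
    stop("run_slide needs either an image or precomputed labels + cells",
         call. = FALSE)
  }
  pipeline_log(verbose, "stage 3/5: macro-tumor outline + stroma definition")
  partition <- region_partition(labels, gp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_region_partition(partition, file.path(out_dir, "regions"))
  }
  if (partition$empty) {
    stop("empty macro-tumor: no tumor region found; partial artifacts ",
         "retained", call. = FALSE)
  }
  pipeline_log(verbose, "stage 4/5: TIL exclusion filtering")
  kept <- filter_tils(cells, partition$tumor_associated_stroma,
                      partition$exclusion_zone)
  pipeline_log(verbose, "stage 5/5: density + heatmap")
  heat <- local_density_heatmap(kept, partition$tumor_associated_stroma,
                                config$heatmap_radius_um)
  result <- compute_density(kept, partition$tumor_associated_stroma,
                            heatmap = heat, params = gp,
                            heatmap_radius_um = config$heatmap_radius_um)
  result$provenance$config_hash <- config_hash(config)
  result$provenance$labels_hash <- hash_object(labels$raster)
  if (!is.null(out_dir)) {
    utils::write.csv(attr(kept, "audit"),
                     file.path(out_dir, "cell_audit.csv"), row.names = FALSE)
    write_biomarker_result(result, out_dir, cal = labels$calibration)
  }
  pipeline_log(verbose, "sTIL density: %.2f cells/mm^2",
               result$stil_density_per_mm2)
  list(result = result, kept = kept, partition = partition, labels = labels,
       provenance = result$provenance)
}

cohort_required_cols <- function() {
  c("id", "stil_density", "manual_stil_pct", "os_time", "os_event",
    "rfs_time", "rfs_event", "age_years", "tumor_size_cm",
    "n_positive_nodes", "tumor_type")
}

#' Validate a cohort table against the expected schema
#'
#' Collects every violation (missing columns, invalid codings, negative
#' times, duplicated ids) rather than stopping at the first.
#'
#' @param cohort A data frame.
#' @return Invisibly `TRUE`; errors with the full violation list otherwise.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  missing <- setdiff(cohort_required_cols(), names(cohort))
  if (length(missing)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing, collapse = ", ")))
  } else {
    if (anyDuplicated(cohort$id)) {
      problems <- c(problems, "duplicated patient ids")
    }
    for (tc in c("os_time", "rfs_time")) {
      if (any(cohort[[tc]] < 0, na.rm = TRUE)) {
        problems <- c(problems, paste0(tc, " contains negative times"))
      }
    }
    for (ec in c("os_event", "rfs_event")) {
      if (!all(cohort[[ec]] %in% c(0, 1, NA))) {
        problems <- c(problems, paste0(ec, " must be 0/1"))
      }
    }
    if (any(cohort$stil_density < 0, na.rm = TRUE)) {
      problems <- c(problems, "stil_density contains negative values")
    }
    if (any(cohort$manual_stil_pct < 0 | cohort$manual_stil_pct > 100,
            na.rm = TRUE)) {
      problems <- c(problems, "manual_stil_pct outside [0, 100]")
    }
    if (!all(cohort$tumor_type %in% c("ductal", "lobular", "other", NA))) {
      problems <- c(problems, "tumor_type must be ductal/lobular/other")
    }
  }
  if (length(problems)) {
    stop("cohort schema violations:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the cohort-level biomarker evaluation
#'
#' From a validated cohort table: selects (or applies) the density
#' cutpoint, dichotomizes both scores, estimates Kaplan-Meier curves per
#' group and endpoint, runs the log-rank tests, fits univariate and
#' multivariate Cox models with the standard covariate codings and
#' biomarker scalings, and reports automated-vs-manual concordance. Tidy
#' CSVs (one per table) are written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Cohort tibble (see [simulate_cohort()] for the schema).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param verbose Log progress.
#' @return A list: `cutpoint` (`stil_cutpoint` or fixed value), `groups`,
#'   `km` (per endpoint/group), `logrank`, `cox_univariate`,
#'   `cox_multivariate`, `concordance`, `n_excluded_multivariate`.
#' @export
run_cohort <- function(config, cohort, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "stil_pipeline_config"))
  cohort <- tibble::as_tibble(cohort)
  validate_cohort(cohort)
  cohort <- code_covariates(cohort)

  if (is.null(config$density_cutpoint)) {
    pipeline_log(verbose, "selecting density cutpoint (maxstat)")
    cut_obj <- maxstat_cutpoint(cohort$os_time, cohort$os_event,
                                cohort$stil_density,
                                quantile_window = config$maxstat_window)
    density_cut <- cut_obj$cutpoint
  } else {
    cut_obj <- NULL
    density_cut <- config$density_cutpoint
  }
  pipeline_log(verbose, "density cutpoint: %.6g cells/mm^2 (>= rule); manual %g%% (> rule)",
               density_cut, config$manual_cutpoint)
  groups <- tibble::tibble(
    id = cohort$id,
    manual_group = dichotomize(cohort$manual_stil_pct,
                               config$manual_cutpoint, "strictly_greater"),
    density_group = dichotomize(cohort$stil_density, density_cut, "geq"))

  km <- list()
  logrank <- list()
  for (ep in c("os", "rfs")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    for (gr in c("manual_group", "density_group")) {
      for (lv in c("low", "high")) {
        sel <- !is.na(groups[[gr]]) & groups[[gr]] == lv
        if (any(sel)) {
          km[[paste(ep, gr, lv, sep = ".")]] <-
            km_estimate(cohort[[tcol]][sel], cohort[[ecol]][sel])
        }
      }
      ok <- !is.na(groups[[gr]])
      if (length(unique(groups[[gr]][ok])) == 2L) {
        logrank[[paste(ep, gr, sep = ".")]] <-
          logrank_stat(cohort[[tcol]][ok], cohort[[ecol]][ok],
                       groups[[gr]][ok])
      }
    }
  }

  covars <- c("age_group", "size_group", "nodal_group", "type_group")
  fits_uni <- list()
  fits_multi <- list()
  can_cox <- sum(cohort$os_event, na.rm = TRUE) >= 2 && nrow(cohort) >= 10
  if (can_cox) {
    for (ep in c("os", "rfs")) {
      tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
      for (bio in c("stil_density", "manual_stil_pct")) {
        fits_uni[[paste(ep, bio, sep = ".")]] <-
          cox_fit(cohort, tcol, ecol, bio)
        fits_multi[[paste(ep, bio, sep = ".")]] <-
          cox_fit(cohort, tcol, ecol, c(bio, covars),
                  on_monotone = "warn")
      }
    }
  } else {
    pipeline_log(verbose,
                 "Cox models skipped: need >= 10 patients and >= 2 events")
  }
  n_excl <- nrow(cohort) -
    sum(stats::complete.cases(cohort[, c("stil_density", "manual_stil_pct",
                                         "os_time", "os_event", covars)]))
  pipeline_log(verbose, "multivariate analysis excludes %d incomplete cases",
               n_excl)

  conc <- concordance_report(
    groups$manual_group, groups$density_group, ids = cohort$id,
    manual_scores = cohort$manual_stil_pct,
    auto_scores = cohort$stil_density,
    manual_cutpoint = config$manual_cutpoint,
    auto_cutpoint = density_cut)

  out <- list(cutpoint = cut_obj, density_cutpoint = density_cut,
              groups = groups, km = km, logrank = logrank,
              cox_univariate = fits_uni, cox_multivariate = fits_multi,
              concordance = conc, n_excluded_multivariate = n_excl,
              provenance = list(config_hash = config_hash(config),
                                cohort_hash = hash_object(cohort)))
  if (!is.null(out_dir)) write_cohort_outputs(out, out_dir)
  out
}

write_cohort_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                     row.names = FALSE)
  }
  if (!is.null(out$cutpoint)) {
    wcsv(glance(out$cutpoint), "cutpoint.csv")
    wcsv(tidy(out$cutpoint), "cutpoint_scan.csv")
  }
  wcsv(out$groups, "groups.csv")
  km_tab <- dplyr::bind_rows(lapply(names(out$km), function(nm) {
    dplyr::mutate(tidy(out$km[[nm]]), stratum = nm, .before = 1)
  }))
  wcsv(km_tab, "km_curves.csv")
  wcsv(dplyr::bind_rows(lapply(names(out$logrank), function(nm) {
    dplyr::mutate(out$logrank[[nm]], comparison = nm, .before = 1)
  })), "logrank.csv")
  cox_tab <- function(fits) {
    dplyr::bind_rows(lapply(names(fits), function(nm) {
      dplyr::mutate(tidy(fits[[nm]]), model = nm, .before = 1)
    }))
  }
  if (length(out$cox_univariate)) {
    wcsv(cox_tab(out$cox_univariate), "cox_univariate.csv")
  }
  if (length(out$cox_multivariate)) {
    wcsv(cox_tab(out$cox_multivariate), "cox_multivariate.csv")
  }
  wcsv(glance(out$concordance), "concordance.csv")
  if (nrow(out$concordance$discrepant)) {
    wcsv(out$concordance$discrepant, "discrepant_cases.csv")
  }
  jsonlite::write_json(out$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
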