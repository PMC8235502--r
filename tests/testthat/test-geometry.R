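# Label-mask fixtures built directly (1 um/px unless noted) so distances
# are exact pixel counts.
labels_with <- function(nr, nc, mpp = 1, painter) {
  cls <- stil_classes()
  r <- matrix(cls[["STROMA"]], nr, nc)
  r <- painter(r, cls)
  label_mask(r, calibration(mpp, nc, nr))
}

test_that("a solid tumor disc yields one macro component covering it", {
  # scaled analog: 0.5 um/px-style geometry shrunk 10x (radii in um at
  # 1 um/px: kernel 75, morph 25, disc radius 200 on a 600 px raster)
  lm <- labels_with(600, 600, 1, function(r, cls) {
    rows <- matrix(seq_len(600), 600, 600)
    cols <- t(rows)
    r[(rows - 300)^2 + (cols - 300)^2 <= 200^2] <- cls[["TUMOR"]]
    r
  })
  p <- geometry_params(kernel_radius_um = 75, tumor_fraction_threshold = 0.1,
                       morph_radius_um = 25, margin_um = 25,
                       epi_exclusion_um = 15)
  macro <- macro_tumor_outline(lm, p)
  tumor <- lm$raster == stil_classes()[["TUMOR"]]
  expect_true(all(macro$raster[tumor]))
  expect_equal(max(EBImage::bwlabel(macro$raster * 1)), 1)
  expect_false(isTRUE(attr(macro, "empty")))
})

test_that("no tumor pixels gives an empty flagged macro mask", {
  lm <- labels_with(50, 50, 2, function(r, cls) r)
  macro <- macro_tumor_outline(lm)
  expect_false(any(macro$raster))
  expect_true(attr(macro, "empty"))
  expect_error(tumor_associated_stroma(lm, macro), "empty macro")
})

test_that("two tumor blobs with a sub-kernel gap merge into one macro", {
  # gap 80 um between blobs, kernel 75 um + closing 25 um bridges it
  mk <- function(gap) labels_with(400, 700, 1, function(r, cls) {
    rows <- matrix(seq_len(400), 400, 700)
    cols <- matrix(seq_len(700), 400, 700, byrow = TRUE)
    c1 <- 250; c2 <- 250 + 200 + gap  # disc radius 100, centers gap+200 apart
    r[(rows - 200)^2 + (cols - c1)^2 <= 100^2] <- cls[["TUMOR"]]
    r[(rows - 200)^2 + (cols - c2)^2 <= 100^2] <- cls[["TUMOR"]]
    r
  })
  p <- geometry_params(kernel_radius_um = 75, tumor_fraction_threshold = 0.1,
                       morph_radius_um = 25, margin_um = 25,
                       epi_exclusion_um = 15)
  near <- macro_tumor_outline(mk(80), p)
  expect_equal(max(EBImage::bwlabel(near$raster * 1)), 1)
  far <- macro_tumor_outline(mk(200), p)
  expect_equal(max(EBImage::bwlabel(far$raster * 1)), 2)
})

test_that("macro outline is monotone in the tumor-fraction threshold", {
  sl <- render_slide(slide_spec(width_px = 500, height_px = 500,
                                microns_per_pixel = 4,
                                til_intensity_per_mm2 = 0,
                                other_intensity_per_mm2 = 0,
                                decoy_intensity_per_mm2 = 0,
                                dcis_aggregate_intensity_per_mm2 = 0,
                                seed = 5))
  lo <- macro_tumor_outline(sl$labels,
                            geometry_params(tumor_fraction_threshold = 0.05))
  hi <- macro_tumor_outline(sl$labels,
                            geometry_params(tumor_fraction_threshold = 0.3))
  expect_true(all(lo$raster[hi$raster]))
})

test_that("the invasive margin includes 200 um and excludes 300 um probes", {
  lm <- labels_with(800, 800, 1, function(r, cls) {
    r[301:500, 301:500] <- cls[["TUMOR"]]
    r
  })
  macro <- binary_mask(lm$raster == stil_classes()[["TUMOR"]],
                       lm$calibration)
  p <- geometry_params(margin_um = 250)
  stroma <- tumor_associated_stroma(lm, macro, p)
  # probes straight right of the macro boundary (row 400, col 500)
  expect_true(stroma$raster[400, 500 + 200])
  expect_false(stroma$raster[400, 500 + 300])
  # distance-transform oracle over a probe strip
  probe_cols <- 501:800
  d_oracle <- probe_cols - 500  # exact distance to macro for row 400
  expect_identical(stroma$raster[400, probe_cols], d_oracle <= 250)
})

test_that("zero margin keeps stroma strictly inside the macro tumor", {
  lm <- labels_with(200, 200, 1, function(r, cls) {
    r[80:120, 80:120] <- cls[["TUMOR"]]
    r
  })
  macro <- binary_mask(matrix(FALSE, 200, 200), lm$calibration)
  macro$raster[60:140, 60:140] <- TRUE
  stroma <- tumor_associated_stroma(lm, macro, geometry_params(margin_um = 1e-9))
  expect_true(all(macro$raster[stroma$raster]))
  # tumor pixels are never stroma
  expect_false(any(stroma$raster & lm$raster == stil_classes()[["TUMOR"]]))
})

test_that("labels entirely tumor inside the macro give empty stroma", {
  lm <- labels_with(100, 100, 1, function(r, cls) {
    r[, ] <- cls[["TUMOR"]]
    r
  })
  macro <- binary_mask(matrix(TRUE, 100, 100), lm$calibration)
  stroma <- tumor_associated_stroma(lm, macro, geometry_params())
  expect_false(any(stroma$raster))
})

test_that("exclusion zone is the union of tumor, necrosis, buffered DCIS", {
  lm <- labels_with(500, 500, 1, function(r, cls) {
    r[101:150, 101:150] <- cls[["TUMOR"]]
    r[201:220, 201:220] <- cls[["NECROSIS"]]
    r[351:360, 351:360] <- cls[["NONINVASIVE_EPITHELIUM"]]
    r
  })
  p <- geometry_params(epi_exclusion_um = 150)
  zone <- exclusion_zone(lm, p)
  comp <- attr(zone, "components")
  expect_true(all(zone$raster[101:150, 101:150]))
  expect_true(all(zone$raster[201:220, 201:220]))
  # DCIS buffer: brute-force distances on a probe row through the blob
  dcis <- lm$raster == stil_classes()[["NONINVASIVE_EPITHELIUM"]]
  probe <- cbind(355, 1:500)  # row through the DCIS blob
  d <- oracle_point_mask_dist(probe[, 2] - 1, probe[, 1] - 1, dcis)
  expect_identical(comp$near_epithelium$raster[probe], d <= 150 + 1e-9)
  # monotone in the buffer width
  zone2 <- exclusion_zone(lm, geometry_params(epi_exclusion_um = 300))
  expect_true(all(zone2$raster[zone$raster]))
  expect_gt(sum(zone2$raster), sum(zone$raster))
  # none of the classes present -> empty zone
  plain <- labels_with(50, 50, 1, function(r, cls) r)
  expect_false(any(exclusion_zone(plain, p)$raster))
})

test_that("TIL filtering audits every point exactly once and conserves", {
  lm <- labels_with(600, 600, 1, function(r, cls) {
    r[201:400, 201:400] <- cls[["TUMOR"]]
    r[281:320, 281:320] <- cls[["NECROSIS"]]
    r[101:120, 451:470] <- cls[["NONINVASIVE_EPITHELIUM"]]
    r
  })
  p <- geometry_params(kernel_radius_um = 75, morph_radius_um = 25,
                       margin_um = 100, epi_exclusion_um = 50)
  part <- region_partition(lm, p)
  set.seed(21)
  cells <- cell_detections(runif(300, 0, 599), runif(300, 0, 599),
                           sample(c("TIL", "OTHER"), 300, TRUE,
                                  prob = c(0.8, 0.2)),
                           lm$calibration)
  kept <- filter_tils(cells, part$tumor_associated_stroma,
                      part$exclusion_zone)
  audit <- attr(kept, "audit")
  counts <- attr(kept, "counts")
  expect_equal(nrow(audit), 300)
  expect_true(all(audit$code %in% til_audit_codes()))
  expect_equal(sum(counts), 300)
  expect_equal(unname(counts["NOT_TIL"]), sum(cells$label == "OTHER"))
  # conservation: kept + excluded = number of input TILs
  n_til <- sum(cells$label == "TIL")
  expect_equal(unname(counts["KEPT"] + counts["IN_TUMOR"] +
                        counts["IN_NECROSIS"] + counts["NEAR_EPI"] +
                        counts["OUTSIDE_STROMA"]), n_til)
  expect_equal(nrow(kept), unname(counts["KEPT"]))
  # all-OTHER input: nothing kept, every code NOT_TIL
  others <- cell_detections(runif(20, 0, 599), runif(20, 0, 599),
                            rep("OTHER", 20), lm$calibration)
  k2 <- filter_tils(others, part$tumor_associated_stroma,
                    part$exclusion_zone)
  expect_equal(nrow(k2), 0)
  expect_true(all(attr(k2, "audit")$code == "NOT_TIL"))
})

test_that("audit codes match generator compartments on synthetic slides", {
  sl <- render_slide(slide_spec(width_px = 1000, height_px = 1000,
                                n_tumor_blobs = 1,
                                tumor_radius_um = c(600, 700),
                                tumor_center_jitter = 0.03,
                                til_intensity_per_mm2 = 150,
                                decoy_intensity_per_mm2 = 100,
                                dcis_aggregate_intensity_per_mm2 = 600,
                                dcis_aggregate_width_um = 150,
                                other_intensity_per_mm2 = 50, seed = 17))
  part <- region_partition(sl$labels, geometry_params())
  kept <- filter_tils(sl$cells, part$tumor_associated_stroma,
                      part$exclusion_zone)
  audit <- attr(kept, "audit")
  gt <- sl$cells$compartment
  is_til <- sl$cells$label == "TIL"
  expect_true(all(audit$code[!is_til] == "NOT_TIL"))
  expect_true(all(audit$code[is_til & gt == "tumor"] == "IN_TUMOR"))
  expect_true(all(audit$code[is_til & gt == "necrosis"] == "IN_NECROSIS"))
  # aggregate ring width equals the exclusion buffer, so near-DCIS TILs in
  # stroma are exactly the NEAR_EPI ones
  expect_true(all(audit$code[is_til & gt == "near_dcis"] == "NEAR_EPI"))
  # stromal TILs are KEPT or OUTSIDE_STROMA, decided by the stroma mask
  stroma_cells <- which(is_til & gt == "stroma")
  expect_true(all(audit$code[stroma_cells] %in%
                    c("KEPT", "OUTSIDE_STROMA")))
})

test_that("moving a DCIS blob flips exactly the 149/151 um proximity flag", {
  mk <- function(shift) labels_with(600, 600, 1, function(r, cls) {
    r[301:400, 301:400] <- cls[["TUMOR"]]
    r[(291:300) - shift, 101:110] <- cls[["NONINVASIVE_EPITHELIUM"]]
    r
  })
  # TIL at 0-based (x = 104, y = 448); nearest DCIS pixel center is the
  # blob's bottom row (0-based y = 299 at shift 0): distance 149 px;
  # shifting the blob up 2 px makes it 151 px.
  cal <- calibration(1, 600, 600)
  cells <- cell_detections(c(104, 50), c(448, 50), c("TIL", "TIL"), cal)
  codes <- function(lm) {
    part <- region_partition(lm, geometry_params(
      kernel_radius_um = 75, morph_radius_um = 25, margin_um = 250,
      epi_exclusion_um = 150))
    attr(filter_tils(cells, part$tumor_associated_stroma,
                     part$exclusion_zone), "audit")$code
  }
  near <- codes(mk(0))
  far <- codes(mk(2))
  expect_equal(near[1], "NEAR_EPI")
  expect_false(far[1] == "NEAR_EPI")
  expect_equal(near[2], far[2])  # the other TIL is untouched
})
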