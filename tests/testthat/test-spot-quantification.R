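test_that("disc segmentation matches area oracle and passes roundness filter", {
  img <- matrix(0, 120, 120)
  mask <- ellipseMask(120, 120, 60.3, 55.7, 10, 10)
  img[mask] <- 500
  spots <- segmentSpots(img, threshold = "absolute", absolute = 100)
  expect_equal(nrow(spots), 1)
  expect_equal(spots$pixel_area, sum(mask))            # exact pixel equality
  expect_lt(abs(spots$pixel_area - pi * 100) / (pi * 100), 0.05)
  expect_gte(spots$roundness, 0.9)
  expect_equal(spots$mean_intensity, 500)
})

test_that("elongated components are measured correctly and filtered out", {
  img <- matrix(0, 160, 120)
  mask <- ellipseMask(160, 120, 80.3, 60.7, 20, 5, theta = 0.4)
  img[mask] <- 300
  all_spots <- segmentSpots(img, threshold = "absolute", absolute = 100,
                            roundness_range = c(0, 1))
  # analytic roundness of a 20 x 5 ellipse: 4*pi*a*b / (pi*(2a)^2) = b/a
  expect_equal(all_spots$roundness, 0.25, tolerance = 0.05 * 0.25)
  filtered <- segmentSpots(img, threshold = "absolute", absolute = 100)
  expect_equal(nrow(filtered), 0)
})

test_that("blank images yield an empty, well-formed spot table", {
  spots <- segmentSpots(matrix(50, 64, 64), threshold = "absolute",
                        absolute = 100)
  expect_equal(nrow(spots), 0)
  expect_true(all(c("x", "y", "pixel_area", "mean_intensity", "roundness")
                  %in% names(spots)))
})

test_that("segmented areas equal the flood-fill oracle on multi-shape scenes", {
  img <- matrix(0, 100, 100)
  m1 <- ellipseMask(100, 100, 25, 25, 8, 8)
  m2 <- ellipseMask(100, 100, 70, 60, 12, 9, theta = 0.5)
  img[m1 | m2] <- 400
  spots <- segmentSpots(img, threshold = "absolute", absolute = 10,
                        roundness_range = c(0, 1), min_area = 1)
  expect_equal(sort(spots$pixel_area), sort(floodFillAreas(m1 | m2)))
})

test_that("normalization divides by the background-well mean", {
  spots <- data.frame(mean_intensity = c(350, 100))
  out <- normalizeIntensities(spots, rep(100, 50))
  expect_equal(out$normalized_intensity, c(3.5, 1.0))
  expect_warning(out10 <- normalizeIntensities(spots, rep(100, 10)),
                 "only 10")
  expect_equal(out10$normalized_intensity, c(3.5, 1.0))
  expect_error(normalizeIntensities(spots, numeric(0)), "at least one")
  expect_error(normalizeIntensities(spots, rep(0, 50)), "> 0")
})

test_that("calibration densities and fits follow the dilution arithmetic", {
  # 500 ug/mL in a 2 uL drop over 1e6 um^2 is exactly 1 pg/um^2
  std <- data.frame(concentration_ug_per_ml = c(500, 250, 125),
                    volume_ul = 2, area_um2 = 1e6,
                    normalized_intensity = NA)
  dens <- std$concentration_ug_per_ml * std$volume_ul * 1000 / std$area_um2
  expect_equal(dens, c(1, 0.5, 0.25))
  std$normalized_intensity <- 2 * dens + 0.1
  model <- fitCalibration(std)
  expect_equal(calSlope(model), 2, tolerance = 1e-12)
  expect_equal(calIntercept(model), 0.1, tolerance = 1e-12)
  expect_equal(model@rSquared, 1, tolerance = 1e-12)

  expect_error(fitCalibration(std[1:2, ]), "at least 3")
  flat <- std; flat$area_um2 <- 1e6
  flat$concentration_ug_per_ml <- 500
  expect_error(fitCalibration(flat), "distinct densities")
})

test_that("noisy calibration recovers the generating slope", {
  cfg <- smallConfig()
  std <- makeCalibrationStandards(cfg, n_replicates = 5, noise_frac = 0.05)
  model <- fitCalibration(std)
  fit_se <- {
    dens <- std$true_density_pg_um2
    fit <- lm(std$normalized_intensity ~ dens)
    summary(fit)$coefficients[2, 2]
  }
  expect_lt(abs(calSlope(model) - cfg@calibSlope), 3 * fit_se)
  expect_gte(model@rSquared, 0.9)
})

test_that("spot quantification applies the inverse standard curve", {
  model <- new("CalibrationModel", slope = 1, intercept = 1,
               rSquared = 1, densityRange = c(0, 1), nStandards = 3L)
  spots <- data.frame(matched_well = c(7L, 8L),
                      normalized_intensity = c(1.005, 1),
                      pixel_area = c(300, 100))
  rec <- quantifySpots(spots, model, um_per_px = 2)
  expect_equal(rec$area_um2, c(1200, 400))
  expect_equal(rec$pg_per_cell, c(0.005 * 1200, 0))
  expect_equal(rec$clamped, c(FALSE, FALSE))
  # below-intercept intensities clamp to zero and are flagged
  dim_spot <- data.frame(matched_well = 1L, normalized_intensity = 0.9,
                         pixel_area = 50)
  rec2 <- quantifySpots(dim_spot, model, 2)
  expect_equal(rec2$pg_per_cell, 0)
  expect_true(rec2$clamped)

  unmatched <- data.frame(matched_well = NA_integer_,
                          normalized_intensity = 2, pixel_area = 10)
  expect_error(quantifySpots(unmatched, model, 2), "unmatched")
  bad <- new("CalibrationModel", slope = -1, intercept = 0, rSquared = 1,
             densityRange = c(0, 1), nStandards = 3L)
  expect_error(quantifySpots(spots, bad, 2), "slope")
})

test_that("pg is monotone in intensity at fixed area and in area at fixed density", {
  model <- new("CalibrationModel", slope = 2, intercept = 1, rSquared = 1,
               densityRange = c(0, 1), nStandards = 3L)
  ni <- seq(1.1, 3, length.out = 10)
  rec <- quantifySpots(data.frame(matched_well = 1:10,
                                  normalized_intensity = ni,
                                  pixel_area = 200), model, 2)
  expect_true(all(diff(rec$pg_per_cell) > 0))
  rec2 <- quantifySpots(data.frame(matched_well = 1:10,
                                   normalized_intensity = 2,
                                   pixel_area = seq(50, 500, length.out = 10)),
                        model, 2)
  expect_true(all(diff(rec2$pg_per_cell) > 0))
})

test_that("fragmented spots merge area-weighted onto their well", {
  ly <- wellLayout(8, 8, pitch_px = 50)
  tf <- gridTransform()
  ctr <- wellCenters(ly)[42, ]
  spots <- data.frame(x = c(ctr[1] - 2, ctr[1] + 2, 5000),
                      y = c(ctr[2], ctr[2], 5000),
                      pixel_area = c(200, 100, 50),
                      mean_intensity = c(3, 6, 9),
                      roundness = c(0.9, 0.8, 1))
  out <- matchSpotsToWells(spots, tf, ly)
  merged <- out[!is.na(out$matched_well), ]
  expect_equal(nrow(merged), 1)
  expect_equal(merged$matched_well, 42)
  expect_equal(merged$pixel_area, 300)
  expect_equal(merged$mean_intensity, 4)  # (200*3 + 100*6) / 300
  # the off-chip spot is retained but unmatched
  expect_equal(sum(is.na(out$matched_well)), 1)
})

test_that("scaling the whole membrane leaves pg estimates unchanged", {
  cfg <- smallConfig(n_cells = 15, seed = 77)
  assay <- simulateAssay(cfg)
  quantify_at <- function(k) {
    img <- assay@psaImage * k
    spots <- segmentSpots(img)
    spots <- matchSpotsToWells(spots, assay@transform, assay@layout)
    spots <- spots[!is.na(spots$matched_well), ]
    bg_ids <- setdiff(seq_len(nWells(assay@layout)),
                      assayTruth(assay)$well_id)[1:30]
    bg <- measureMembraneBackground(img, assay@transform, assay@layout,
                                    bg_ids)
    spots <- normalizeIntensities(spots, bg, n_background = 30)
    model <- fitCalibration(assay@standards)
    quantifySpots(spots, model, cfg@umPerPx)
  }
  base <- quantify_at(1)
  for (k in c(0.5, 2)) {
    scaled <- quantify_at(k)
    expect_equal(scaled$well_id, base$well_id)
    expect_lt(max(abs(scaled$pg_per_cell - base$pg_per_cell) /
                    pmax(base$pg_per_cell, 1e-12)), 1e-9)
  }
})
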