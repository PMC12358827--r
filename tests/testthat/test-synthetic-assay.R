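test_that("ground truth is deterministic and respects the config", {
  cfg <- smallConfig(n_cells = 10, seed = 1)
  a <- makeGroundTruth(cfg)
  b <- makeGroundTruth(cfg)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 10)
  expect_false(anyDuplicated(a$truth$well_id) > 0)
  expect_true(all(a$truth$secretion_pg >= 0))
  # secretors get uniform secretion inside the configured interval
  sec <- a$truth$secretion_pg[a$truth$secretion_pg > 0]
  expect_true(all(sec >= cfg@secretionPgRange[1] &
                    sec <= cfg@secretionPgRange[2]))
  # a different seed moves the cells
  c2 <- makeGroundTruth(smallConfig(n_cells = 10, seed = 2))
  expect_false(identical(a$truth$well_id, c2$truth$well_id))
})

test_that("degenerate and forced configurations behave", {
  empty <- makeGroundTruth(smallConfig(n_cells = 0))
  expect_equal(nrow(empty$truth), 0)
  expect_s4_class(empty$layout, "WellLayout")

  leuk <- makeGroundTruth(smallConfig(n_cells = 50,
                                      phenotype_mix = pureMix("leukocyte")))
  expect_equal(nrow(leuk$truth), 50)
  expect_true(all(leuk$truth$secretion_pg == 0))
  expect_true(all(leuk$truth$phenotype == "leukocyte"))

  expect_error(assayConfig(n_rows = 4, n_cols = 4, n_cells = 17),
               "exceeds")
  expect_error(assayConfig(phenotype_mix = c(pureMix("leukocyte") * 2)),
               "sum to 1")
  expect_error(assayConfig(transform_scale = 0), "degenerate|scale")
})

test_that("noiseless chip render carries exact truth intensities", {
  cfg <- smallConfig(n_cells = 3, noise_sd = 0, seed = 5)
  gt <- makeGroundTruth(cfg)
  imgs <- renderChipImages(gt$truth, gt$layout, cfg)
  centers <- wellCenters(gt$layout)
  r <- gt$layout@wellRadiusPx
  for (i in seq_len(nrow(gt$truth))) {
    ctr <- centers[gt$truth$well_id[i], ]
    px <- discPixels(ctr[1], ctr[2], r, nrow(imgs$calcein), ncol(imgs$calcein))
    expect_equal(unique(imgs$calcein[px]),
                 cfg@chipBackground + gt$truth$calcein[i])
    expect_equal(unique(imgs$cd45[px]),
                 cfg@chipBackground + gt$truth$cd45[i])
  }
  # off-well pixels are pure background
  expect_equal(imgs$calcein[1, 1], cfg@chipBackground)
})

test_that("noisy chip render means are close to truth", {
  cfg <- smallConfig(n_cells = 5, noise_sd = 30, seed = 6)
  gt <- makeGroundTruth(cfg)
  imgs <- renderChipImages(gt$truth, gt$layout, cfg)
  centers <- wellCenters(gt$layout)
  r <- gt$layout@wellRadiusPx
  for (i in seq_len(nrow(gt$truth))) {
    ctr <- centers[gt$truth$well_id[i], ]
    px <- discPixels(ctr[1], ctr[2], r, nrow(imgs$psma), ncol(imgs$psma))
    expect_lt(abs(mean(imgs$psma[px]) - cfg@chipBackground - gt$truth$psma[i]),
              3 * cfg@noiseSd)
  }
})

test_that("empty truth renders to pure background", {
  cfg <- smallConfig(n_cells = 0, noise_sd = 0)
  gt <- makeGroundTruth(cfg)
  imgs <- renderChipImages(gt$truth, gt$layout, cfg)
  expect_true(all(imgs$calcein == cfg@chipBackground))
  mem <- renderMembraneImages(gt$truth, gt$layout, cfg)
  expect_true(all(mem$psa == cfg@membraneBackground))
})

test_that("membrane secretion discs follow the true standard curve", {
  cfg <- smallConfig(n_cells = 8, noise_sd = 0, seed = 9)
  gt <- makeGroundTruth(cfg)
  mem <- renderMembraneImages(gt$truth, gt$layout, cfg)
  sec <- gt$truth[gt$truth$secretion_pg > 0, ]
  mapped <- applyTransform(mem$transform, wellCenters(gt$layout))
  for (i in seq_len(nrow(sec))) {
    ctr <- mapped[sec$well_id[i], ]
    area <- pi * sec$spot_radius_um[i]^2
    ni <- cfg@calibIntercept + cfg@calibSlope * sec$secretion_pg[i] / area
    # sample the spot center pixel: value is NI * membrane background
    expect_equal(mem$psa[round(ctr[1]), round(ctr[2])],
                 ni * cfg@membraneBackground, tolerance = 1e-12)
  }
  # label bookkeeping: one rendered disc per secretor
  spots <- segmentSpots(mem$psa, threshold = "absolute",
                        absolute = cfg@membraneBackground * 1.01,
                        min_area = 5)
  expect_equal(nrow(spots), nrow(sec))
})

test_that("imprint lattice lands on the analytically transformed centers", {
  cfg <- smallConfig(n_cells = 0, noise_sd = 0,
                     transform_rotation_deg = 2,
                     transform_translation_px = c(12.3, -7.8),
                     transform_scale = 1)
  gt <- makeGroundTruth(cfg)
  mem <- renderMembraneImages(gt$truth, gt$layout, cfg)
  spots <- detectImprintSpots(mem$imprint)
  expect_equal(nrow(spots), nWells(gt$layout))
  expected <- applyTransform(mem$transform, wellCenters(gt$layout))
  # order detected centroids by nearest expected center
  d <- as.matrix(dist(rbind(expected, cbind(spots$x, spots$y))))
  n <- nrow(expected)
  nearest <- apply(d[(n + 1):(2 * n), 1:n, drop = FALSE], 1, which.min)
  expect_true(all(sort(nearest) == seq_len(n)))
  err <- sqrt(rowSums((cbind(spots$x, spots$y) - expected[nearest, ])^2))
  expect_lt(max(err), 0.5)
  # nearest-neighbour spacing of the lattice equals the pitch within rounding
  nn <- apply(d[1:n, 1:n] + diag(Inf, n), 1, min)
  expect_equal(unname(nn), rep(gt$layout@pitchPx * cfg@transformScale, n),
               tolerance = 1e-6)
})

test_that("event tables are deterministic mixtures with valid degenerates", {
  ev <- makeEventTable(500, seed = 3)
  expect_identical(ev, makeEventTable(500, seed = 3))
  expect_equal(nrow(ev), 500)
  expect_true(all(ev$ck_intensity >= 0 & ev$psma_intensity >= 0))
  expect_equal(nrow(makeEventTable(0)), 0)
  expect_error(makeEventTable(10, populations =
    defaultEventPopulations()[0, ]), "empty")
  bad <- defaultEventPopulations()
  bad$proportion <- bad$proportion * 2
  expect_error(makeEventTable(10, populations = bad), "sum to 1")
})

test_that("a strongly double-positive population gates almost entirely CK+PSMA+", {
  pops <- eventPopulation("dp", 1, ck_meanlog = log(500),
                          psma_meanlog = log(2000),
                          ck_sdlog = 0.3, psma_sdlog = 0.3)
  ev <- makeEventTable(1000, populations = pops, seed = 4)
  res <- classifyEvents(ev)
  expect_gte(res$counts$n_ck_pos_psma_pos / 1000, 0.99)
})
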