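test_that("threshold boundaries are inclusive and CD45/DAPI gates exclude", {
  ev <- data.frame(
    ck_intensity = c(50, 49, 500, 500, 10),
    psma_intensity = c(100, 250, 500, 500, 10),
    dapi_positive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    cd45_positive = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  res <- classifyEvents(ev)
  expect_equal(res$events$label,
               c("CK+PSMA-", "CK-PSMA+", "excluded", "CK+PSMA+", "excluded"))
  expect_equal(res$counts$n_ck_pos_psma_pos, 1)
  expect_equal(res$counts$n_excluded, 2)
})

test_that("numeric CD45 gating variant works for chip-style tables", {
  ev <- data.frame(ck_intensity = c(100, 100), psma_intensity = c(300, 300),
                   dapi_positive = TRUE, cd45_intensity = c(10, 900))
  res <- classifyEvents(ev, gateThresholds(cd45_max = 500))
  expect_equal(res$events$label, c("CK+PSMA+", "excluded"))
})

test_that("missing columns are reported by name", {
  expect_error(classifyEvents(data.frame(ck_intensity = 1)),
               "psma_intensity")
  expect_error(classifyEvents(data.frame(ck_intensity = 1,
                                         psma_intensity = 1)),
               "dapi_positive")
})

test_that("gate counts partition the event table", {
  for (seed in 1:5) {
    ev <- makeEventTable(2000, seed = seed)
    res <- classifyEvents(ev)
    expect_equal(sum(unlist(res$counts)), 2000)
    expect_equal(sum(table(res$events$label)), 2000)
  }
})

test_that("raising the PSMA threshold never increases PSMA+ counts", {
  ev <- makeEventTable(2000, seed = 7)
  prev <- Inf
  for (cut in c(50, 200, 800, 3200)) {
    res <- classifyEvents(ev, gateThresholds(psma_min = cut))
    n_psma <- res$counts$n_ck_pos_psma_pos + res$counts$n_ck_neg_psma_pos
    expect_lte(n_psma, prev)
    prev <- n_psma
  }
})

test_that("log-log OLS matches the normal-equations oracle", {
  set.seed(11)
  counts <- data.frame(ck_pos = round(10^runif(12, 0.5, 3)),
                       psma_pos = round(10^runif(12, 0.5, 3)))
  fit <- fitLogLogRegression(counts)
  oracle <- olsOracle(log10(counts$ck_pos), log10(counts$psma_pos))
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
})

test_that("noiseless points on a log-log line are recovered exactly", {
  x <- c(5, 20, 80, 320, 1280)
  counts <- data.frame(ck_pos = x, psma_pos = 10^(0.45 * log10(x) + 0.35))
  fit <- fitLogLogRegression(counts)
  expect_equal(fit$slope, 0.45, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.35, tolerance = 1e-12)
  expect_equal(fit$spearman_rho, 1)
})

test_that("rank reversal gives rho -1 and degenerate inputs error", {
  counts <- data.frame(ck_pos = c(10, 20, 40, 80),
                       psma_pos = c(80, 40, 20, 10))
  expect_equal(fitLogLogRegression(counts)$spearman_rho, -1)

  same <- data.frame(ck_pos = rep(50, 5), psma_pos = rep(10, 5))
  expect_error(fitLogLogRegression(same), "slope undefined")
  expect_error(fitLogLogRegression(data.frame(ck_pos = c(1, 2),
                                              psma_pos = c(1, 2))),
               "at least 3")
  expect_warning(
    fitLogLogRegression(data.frame(ck_pos = c(0, 5, 20, 80, 320),
                                   psma_pos = c(9, 5, 20, 80, 320))),
    "zero counts")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(13)
  counts <- data.frame(ck_pos = sample(1:500, 15),
                       psma_pos = sample(1:500, 15))
  base <- fitLogLogRegression(counts)$spearman_rho
  warped <- data.frame(ck_pos = exp(counts$ck_pos / 100),
                       psma_pos = counts$psma_pos^3)
  expect_equal(fitLogLogRegression(warped)$spearman_rho, base)
})
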