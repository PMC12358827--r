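obs_fixture <- function() {
  data.frame(well_id = 1:8,
             phenotype = c("psma_pos_ctc", "psma_neg_ctc", "psma_pos_ctc",
                           "psma_neg_ctc", "leukocyte", "empty",
                           "psma_pos_ctc", "empty"))
}

test_that("cells join into the four PSMA/PSA groups", {
  sec <- data.frame(well_id = c(1L, 2L, 6L), pg_per_cell = c(6.0, 4.2, 3.0))
  cells <- assembleCells(obs_fixture(), sec, "p1")
  expect_equal(cells$group[1:4],
               c("PSMA+PSA+", "PSMA-PSA+", "PSMA+PSA-", "PSMA-PSA-"))
  expect_equal(cells$pg_per_cell[1:2], c(6.0, 4.2))
  expect_equal(cells$pg_per_cell[3:4], c(0, 0))
  # leukocyte and empty wells never carry secretion values
  expect_true(all(is.na(cells$pg_per_cell[cells$phenotype %in%
                                            c("leukocyte", "empty")])))
  # secretion at an empty well is an anomaly, excluded from groups
  expect_true(cells$anomaly[cells$well_id == 6])
  expect_equal(cells$group[cells$well_id == 6], "empty")
})

test_that("duplicate well ids are rejected", {
  obs <- obs_fixture()
  expect_error(assembleCells(rbind(obs, obs[1, ]),
                             data.frame(well_id = integer(0),
                                        pg_per_cell = numeric(0)), "p"),
               "duplicate")
  expect_error(assembleCells(obs,
                             data.frame(well_id = c(1L, 1L),
                                        pg_per_cell = c(1, 2)), "p"),
               "duplicate")
})

test_that("patient summaries count groups and secretion percentages", {
  cells <- data.frame(
    patient_id = "p1",
    well_id = 1:10,
    phenotype = "psma_pos_ctc",
    pg_per_cell = c(5, 6, 7, 4.2, 0, 0, 0, 0, 0, 0),
    group = c(rep("PSMA+PSA+", 3), "PSMA-PSA+", rep("PSMA+PSA-", 4),
              rep("PSMA-PSA-", 2)),
    anomaly = FALSE)
  s <- summarizePatient(cells, serum_psa = 128.3, screening_ctc = 24)
  expect_equal(s$n_ctc, 10)
  expect_equal(s$pct_secreting, 40)
  expect_equal(s$mean_pg, mean(c(5, 6, 7, 4.2)))
  expect_equal(s$median_pg, median(c(5, 6, 7, 4.2)))
  expect_equal(s$serum_psa, 128.3)

  none <- cells
  none$group <- "PSMA+PSA-"
  none$pg_per_cell <- 0
  s0 <- summarizePatient(none)
  expect_equal(s0$pct_secreting, 0)
  expect_true(is.na(s0$mean_pg) && is.na(s0$median_pg))

  s_empty <- summarizePatient(cells[0, ])
  expect_equal(s_empty$n_ctc, 0)
  expect_true(is.na(s_empty$pct_secreting))
})

test_that("group counts are conserved and order-invariant", {
  sec <- data.frame(well_id = c(1L, 2L), pg_per_cell = c(6.0, 4.2))
  obs <- obs_fixture()
  cells <- assembleCells(obs, sec, "p1")
  counts <- table(cells$group)
  expect_equal(sum(counts), nrow(obs))
  shuffled <- assembleCells(obs[sample(nrow(obs)), ], sec, "p1")
  expect_equal(summarizePatient(shuffled)$pct_secreting,
               summarizePatient(cells)$pct_secreting)
})

test_that("cohort statistics pool cells or average per patient", {
  cells <- rbind(
    data.frame(patient_id = "a", well_id = 1:2, phenotype = "psma_pos_ctc",
               pg_per_cell = c(2, 4), group = "PSMA+PSA+", anomaly = FALSE),
    data.frame(patient_id = "b", well_id = 1L, phenotype = "psma_pos_ctc",
               pg_per_cell = 9, group = "PSMA+PSA+", anomaly = FALSE))
  pooled <- summarizeCohort(cells, "pooled")
  expect_equal(pooled$mean_pg, mean(c(2, 4, 9)))
  byp <- summarizeCohort(cells, "patient")
  expect_equal(byp$mean_pg, mean(c(3, 9)))
  expect_equal(pooled$n_patients_with_secretors, 2L)
})

test_that("serum correlation needs three varying patients with secretors", {
  summaries <- data.frame(serum_psa = c(10, 50, 200, 400),
                          mean_pg = c(2, 4, 6, 11))
  expect_equal(correlateSerum(summaries)$spearman_rho, 1)
  rev <- summaries
  rev$mean_pg <- rev(rev$mean_pg)
  expect_equal(correlateSerum(rev)$spearman_rho, -1)
  # patients without secretors (mean_pg NA) are excluded
  with_na <- rbind(summaries, data.frame(serum_psa = 77, mean_pg = NA))
  expect_equal(correlateSerum(with_na)$n_used, 4)
  expect_error(correlateSerum(summaries[1:2, ]), "at least 3")
  const <- summaries
  const$mean_pg <- 5
  expect_error(correlateSerum(const), "zero variance")
})
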