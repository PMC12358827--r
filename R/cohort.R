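# Cohort assembly: join chip phenotypes with secretion records into the
# four-group classification and summarise per patient and across patients.

CELL_GROUPS <- c("PSMA+PSA+", "PSMA-PSA+", "PSMA+PSA-", "PSMA-PSA-")

#' Join chip phenotypes with secretion records into per-cell records
#'
#' Left-joins classified well observations with secretion records on
#' `well_id`. Candidate CTCs (PSMA+/- phenotype) with a secretion record
#' above `min_pg` become PSA+, those without become PSA-, giving the four
#' groups PSMA+/-PSA+/-. Secretion recorded at leukocyte or empty wells is
#' biologically inconsistent (no viable tumor cell to secrete) and is
#' flagged as an anomaly and excluded from the groups.
#'
#' @param observations classified well observations (from [classifyWells()];
#'   columns `well_id`, `phenotype`).
#' @param secretion secretion records (from [quantifySpots()]; columns
#'   `well_id`, `pg_per_cell`).
#' @param patient_id identifier stamped on every record.
#' @param min_pg minimum pg/cell for a PSA+ call (default 0: any retained
#'   matched spot with positive clamped density counts as secretion).
#' @return data.frame of cell records: `patient_id`, `well_id`, `phenotype`,
#'   `pg_per_cell` (0 for candidate non-secretors, `NA` for
#'   leukocyte/empty), `group` (four groups, `"leukocyte"`, or `"empty"`),
#'   `anomaly`.
#' @export
assembleCells <- function(observations, secretion, patient_id,
                          min_pg = 0) {
  stopIfMissingCols(observations, c("well_id", "phenotype"), "observations")
  stopIfMissingCols(secretion, c("well_id", "pg_per_cell"), "secretion")
  if (anyDuplicated(observations$well_id))
    stop("duplicate well_id in observations")
  if (anyDuplicated(secretion$well_id))
    stop("duplicate well_id in secretion records")
  idx <- match(observations$well_id, secretion$well_id)
  pg <- secretion$pg_per_cell[idx]
  has_spot <- !is.na(idx) & !is.na(pg) & pg > min_pg
  phen <- observations$phenotype
  candidate <- phen %in% c("psma_pos_ctc", "psma_neg_ctc")
  group <- rep(NA_character_, nrow(observations))
  group[phen == "leukocyte"] <- "leukocyte"
  group[phen == "empty"] <- "empty"
  psma_pos <- phen == "psma_pos_ctc"
  group[candidate & has_spot & psma_pos] <- "PSMA+PSA+"
  group[candidate & has_spot & !psma_pos] <- "PSMA-PSA+"
  group[candidate & !has_spot & psma_pos] <- "PSMA+PSA-"
  group[candidate & !has_spot & !psma_pos] <- "PSMA-PSA-"
  out_pg <- ifelse(candidate, ifelse(has_spot, pg, 0), NA_real_)
  data.frame(patient_id = patient_id,
             well_id = observations$well_id, phenotype = phen,
             pg_per_cell = out_pg, group = group,
             anomaly = !candidate & has_spot)
}

#' Summarise one patient's cell records
#'
#' Counts the four PSMA/PSA groups, the secreting percentage
#' (`100 x PSA+ / four-group total`) and the mean/median secretion over
#' secreting cells. With no candidate cells, counts are zero and the
#' percentage and secretion statistics are reported as missing.
#'
#' @param cells cell records from [assembleCells()] (a single patient).
#' @param serum_psa serum PSA (ng/mL) at screening, carried into the
#'   summary.
#' @param screening_ctc CTC count per 7.5 mL blood at screening.
#' @return one-row data.frame: `patient_id`, the four group counts
#'   (`n_psma_pos_psa_pos`, ...), `n_ctc`, `pct_secreting`, `mean_pg`,
#'   `median_pg`, `serum_psa`, `screening_ctc`.
#' @export
summarizePatient <- function(cells, serum_psa = NA_real_,
                             screening_ctc = NA_real_) {
  stopIfMissingCols(cells, c("patient_id", "group", "pg_per_cell"), "cells")
  pid <- if (nrow(cells) > 0L) cells$patient_id[1] else NA
  if (nrow(cells) > 0L && length(unique(cells$patient_id)) > 1L)
    stop("cells must share a single patient_id")
  n <- vapply(CELL_GROUPS, function(g)
    sum(cells$group == g, na.rm = TRUE), integer(1))
  total <- sum(n)
  secretors <- cells[!is.na(cells$group) &
                       cells$group %in% c("PSMA+PSA+", "PSMA-PSA+"), ,
                     drop = FALSE]
  data.frame(patient_id = pid,
             n_psma_pos_psa_pos = n[["PSMA+PSA+"]],
             n_psma_neg_psa_pos = n[["PSMA-PSA+"]],
             n_psma_pos_psa_neg = n[["PSMA+PSA-"]],
             n_psma_neg_psa_neg = n[["PSMA-PSA-"]],
             n_ctc = total,
             pct_secreting = if (total > 0) 100 * nrow(secretors) / total
                             else NA_real_,
             mean_pg = if (nrow(secretors) > 0)
               mean(secretors$pg_per_cell) else NA_real_,
             median_pg = if (nrow(secretors) > 0)
               stats::median(secretors$pg_per_cell) else NA_real_,
             serum_psa = serum_psa, screening_ctc = screening_ctc)
}

#' Pooled or per-patient cohort secretion statistics
#'
#' Mean and median secretion over secreting cells across a cohort, either
#' pooling all secreting cells (`"pooled"`, the default) or averaging the
#' per-patient means (`"patient"`).
#'
#' @param cells stacked cell records from [assembleCells()] (any number of
#'   patients).
#' @param mode `"pooled"` or `"patient"`.
#' @return one-row data.frame: `mean_pg`, `median_pg`, `n_secretors`,
#'   `n_patients_with_secretors`.
#' @export
summarizeCohort <- function(cells, mode = c("pooled", "patient")) {
  mode <- match.arg(mode)
  sec <- cells[!is.na(cells$group) &
                 cells$group %in% c("PSMA+PSA+", "PSMA-PSA+"), ,
               drop = FALSE]
  n_pat <- length(unique(sec$patient_id))
  if (nrow(sec) == 0L)
    return(data.frame(mean_pg = NA_real_, median_pg = NA_real_,
                      n_secretors = 0L, n_patients_with_secretors = 0L))
  if (mode == "pooled") {
    data.frame(mean_pg = mean(sec$pg_per_cell),
               median_pg = stats::median(sec$pg_per_cell),
               n_secretors = nrow(sec), n_patients_with_secretors = n_pat)
  } else {
    per <- tapply(sec$pg_per_cell, sec$patient_id, mean)
    data.frame(mean_pg = mean(per), median_pg = stats::median(per),
               n_secretors = nrow(sec), n_patients_with_secretors = n_pat)
  }
}

#' Correlate serum PSA with mean per-cell CTC secretion
#'
#' Spearman rank correlation (midrank ties) between serum PSA and the mean
#' per-cell secretion across patients; patients without secreting cells are
#' excluded, mirroring the restriction of such analyses to patients in whom
#' secreting CTCs were identified.
#'
#' @param summaries stacked rows from [summarizePatient()] (columns
#'   `serum_psa`, `mean_pg`).
#' @return list: `spearman_rho`, `n_used`.
#' @export
correlateSerum <- function(summaries) {
  stopIfMissingCols(summaries, c("serum_psa", "mean_pg"), "summaries")
  use <- !is.na(summaries$mean_pg) & !is.na(summaries$serum_psa)
  x <- summaries$serum_psa[use]
  y <- summaries$mean_pg[use]
  if (length(x) < 3L)
    stop("at least 3 patients with secreting cells required")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance")
  list(spearman_rho = stats::cor(x, y, method = "spearman"),
       n_used = length(x))
}
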