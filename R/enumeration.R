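# Event-level CTC enumeration: gate marker intensities into CK/PSMA groups
# and quantify the concordance between CK- and PSMA-defined counts.

#' Event gating thresholds for CTC enumeration
#'
#' Inclusive mean-intensity cutoffs for CK and PSMA positivity (defaults 50
#' and 200, set on prostate cell lines), plus the categorical requirements
#' that an event be DAPI-positive and CD45-negative. `cd45_max` supports the
#' numeric-CD45 variant used when reusing chip intensity tables: events with
#' `cd45_intensity >= cd45_max` are excluded.
#'
#' @param ck_min,psma_min inclusive positivity thresholds.
#' @param require_dapi exclude events that are not DAPI-positive.
#' @param exclude_cd45 exclude CD45-positive events.
#' @param cd45_max numeric CD45 exclusion threshold (used when the event
#'   table has `cd45_intensity` instead of a logical `cd45_positive`).
#' @return named list of gate settings.
#' @export
gateThresholds <- function(ck_min = 50, psma_min = 200, require_dapi = TRUE,
                           exclude_cd45 = TRUE, cd45_max = NULL) {
  if (ck_min < 0 || psma_min < 0) stop("thresholds must be >= 0")
  list(ck_min = ck_min, psma_min = psma_min, require_dapi = require_dapi,
       exclude_cd45 = exclude_cd45, cd45_max = cd45_max)
}

#' Gate an event table into CK/PSMA CTC groups
#'
#' Events failing the DAPI-positive or CD45-negative gates are excluded;
#' the remainder are labelled by inclusive thresholds into `"CK+PSMA+"`,
#' `"CK+PSMA-"`, `"CK-PSMA+"`, or `"CK-PSMA-"` (the last counted separately
#' as unclassified, not a CTC group).
#'
#' @param events data.frame with columns `ck_intensity`, `psma_intensity`,
#'   and `dapi_positive` (logical) / `cd45_positive` (logical) or
#'   `cd45_intensity` (numeric, gated against `thresholds$cd45_max`).
#' @param thresholds list from [gateThresholds()].
#' @return list with `events` (input plus a `label` column; excluded events
#'   labelled `"excluded"`) and `counts`, a one-row data.frame:
#'   `n_ck_pos_psma_pos`, `n_ck_pos_psma_neg`, `n_ck_neg_psma_pos`,
#'   `n_unclassified`, `n_excluded`.
#' @examples
#' ev <- data.frame(ck_intensity = c(50, 49, 500),
#'                  psma_intensity = c(100, 250, 500),
#'                  dapi_positive = TRUE,
#'                  cd45_positive = c(FALSE, FALSE, TRUE))
#' classifyEvents(ev)$events$label
#' @export
classifyEvents <- function(events, thresholds = gateThresholds()) {
  stopIfMissingCols(events, c("ck_intensity", "psma_intensity"),
                    "event table")
  n <- nrow(events)
  excluded <- rep(FALSE, n)
  if (thresholds$require_dapi) {
    stopIfMissingCols(events, "dapi_positive", "event table")
    excluded <- excluded | !events$dapi_positive
  }
  if (thresholds$exclude_cd45) {
    if (!is.null(thresholds$cd45_max)) {
      stopIfMissingCols(events, "cd45_intensity", "event table")
      excluded <- excluded | events$cd45_intensity >= thresholds$cd45_max
    } else {
      stopIfMissingCols(events, "cd45_positive", "event table")
      excluded <- excluded | events$cd45_positive
    }
  }
  ck <- events$ck_intensity >= thresholds$ck_min
  psma <- events$psma_intensity >= thresholds$psma_min
  label <- rep("excluded", n)
  label[!excluded & ck & psma] <- "CK+PSMA+"
  label[!excluded & ck & !psma] <- "CK+PSMA-"
  label[!excluded & !ck & psma] <- "CK-PSMA+"
  label[!excluded & !ck & !psma] <- "CK-PSMA-"
  events$label <- label
  counts <- data.frame(n_ck_pos_psma_pos = sum(label == "CK+PSMA+"),
                       n_ck_pos_psma_neg = sum(label == "CK+PSMA-"),
                       n_ck_neg_psma_pos = sum(label == "CK-PSMA+"),
                       n_unclassified = sum(label == "CK-PSMA-"),
                       n_excluded = sum(label == "excluded"))
  list(events = events, counts = counts)
}

#' Log-log regression and rank correlation between CK+ and PSMA+ counts
#'
#' Ordinary least squares of `log10(PSMA+ count)` on `log10(CK+ count)`
#' across samples, together with the Spearman rank correlation (midrank
#' ties) of the raw counts. Samples with a zero count on either axis are
#' dropped with a warning (the log is undefined and no pseudocount is
#' applied).
#'
#' @param counts data.frame with per-sample columns `ck_pos` and `psma_pos`.
#' @return list: `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `spearman_rho`, `r_squared`, `n_used`.
#' @examples
#' x <- c(10, 40, 160, 640)
#' fitLogLogRegression(data.frame(ck_pos = x,
#'                                psma_pos = 10^(0.45 * log10(x) + 0.35)))
#' @export
fitLogLogRegression <- function(counts) {
  stopIfMissingCols(counts, c("ck_pos", "psma_pos"), "count table")
  usable <- counts$ck_pos > 0 & counts$psma_pos > 0
  if (any(!usable))
    warning(sprintf("dropping %d sample(s) with zero counts from the log-log fit",
                    sum(!usable)))
  counts <- counts[usable, , drop = FALSE]
  if (nrow(counts) < 3L)
    stop("at least 3 samples with positive CK+ and PSMA+ counts required")
  lx <- log10(counts$ck_pos)
  ly <- log10(counts$psma_pos)
  if (stats::var(lx) == 0)
    stop("slope undefined: no variance in CK+ counts")
  fit <- stats::lm(ly ~ lx)
  # exactly collinear inputs fit perfectly; summary.lm warns about that
  sm <- suppressWarnings(summary(fit))
  rho <- stats::cor(counts$ck_pos, counts$psma_pos, method = "spearman")
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = sm$coefficients[2, 2],
       intercept_se = sm$coefficients[1, 2],
       spearman_rho = rho, r_squared = sm$r.squared, n_used = nrow(counts))
}

#' Describe an event population for the synthetic event generator
#'
#' Marker intensities are drawn log-normally per population; DAPI and CD45
#' positivity are Bernoulli. Intensity locations/scales are on the log
#' scale (`meanlog`/`sdlog`).
#'
#' @param name population label (kept as hidden truth in the table).
#' @param proportion mixture weight.
#' @param ck_meanlog,ck_sdlog,psma_meanlog,psma_sdlog log-normal parameters
#'   of the CK and PSMA intensity distributions.
#' @param dapi_prob,cd45_prob per-event probability of DAPI and CD45
#'   positivity.
#' @return a one-row data.frame describing the population.
#' @export
eventPopulation <- function(name, proportion, ck_meanlog, psma_meanlog,
                            ck_sdlog = 0.5, psma_sdlog = 0.5,
                            dapi_prob = 1, cd45_prob = 0) {
  data.frame(name = name, proportion = proportion, ck_meanlog = ck_meanlog,
             ck_sdlog = ck_sdlog, psma_meanlog = psma_meanlog,
             psma_sdlog = psma_sdlog, dapi_prob = dapi_prob,
             cd45_prob = cd45_prob)
}

#' Default event populations for enumeration simulations
#'
#' Three DAPI+ CD45- tumor-cell populations straddling the CK/PSMA gates
#' (double-positive, CK-only, PSMA-only) plus a CD45+ leukocyte carryover
#' population, with intensity scales loosely modelled on prostate cell
#' lines (strongly PSMA-positive lines express far above the 200 cutoff;
#' CK-positive lines far above 50).
#'
#' @param p_double,p_ck_only,p_psma_only,p_leukocyte mixture weights.
#' @return data.frame of stacked [eventPopulation()] rows.
#' @export
defaultEventPopulations <- function(p_double = 0.45, p_ck_only = 0.3,
                                    p_psma_only = 0.1, p_leukocyte = 0.15) {
  rbind(
    eventPopulation("CKposPSMApos", p_double, ck_meanlog = log(400),
                    psma_meanlog = log(1500)),
    eventPopulation("CKposPSMAneg", p_ck_only, ck_meanlog = log(400),
                    psma_meanlog = log(20)),
    eventPopulation("CKnegPSMApos", p_psma_only, ck_meanlog = log(8),
                    psma_meanlog = log(1500)),
    eventPopulation("leukocyte", p_leukocyte, ck_meanlog = log(8),
                    psma_meanlog = log(20), cd45_prob = 1))
}

#' Generate a synthetic enumeration event table
#'
#' Draws `n` events from a mixture of populations, each with log-normal
#' CK/PSMA intensity distributions and Bernoulli DAPI/CD45 positivity.
#' Deterministic given `seed`.
#'
#' @param n number of events.
#' @param populations data.frame of [eventPopulation()] rows; proportions
#'   must sum to 1.
#' @param seed integer RNG seed.
#' @return data.frame: `ck_intensity`, `psma_intensity`, `dapi_positive`,
#'   `cd45_positive`, `population` (hidden truth label).
#' @export
makeEventTable <- function(n, populations = defaultEventPopulations(),
                           seed = 1L) {
  if (nrow(populations) == 0L) stop("empty population mixture")
  if (abs(sum(populations$proportion) - 1) > 1e-8)
    stop("population proportions must sum to 1")
  n <- as.integer(n)
  withSeed(seed, {
    idx <- if (n > 0L)
      sample.int(nrow(populations), n, replace = TRUE,
                 prob = populations$proportion) else integer(0)
    p <- populations[idx, , drop = FALSE]
    data.frame(
      ck_intensity = stats::rlnorm(n, p$ck_meanlog, p$ck_sdlog),
      psma_intensity = stats::rlnorm(n, p$psma_meanlog, p$psma_sdlog),
      dapi_positive = stats::runif(n) < p$dapi_prob,
      cd45_positive = stats::runif(n) < p$cd45_prob,
      population = p$name)
  })
}
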