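---
title: "Quantifying single-cell secretion in nanowell membrane assays"
author: "nanospot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell secretion in nanowell membrane assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanospot)
```

## The assay and what this package computes

Circulating tumor cells (CTCs) are rare tumor-derived cells in peripheral
blood. In prostate cancer, serum PSA is the standard monitoring biomarker,
yet serum levels pool the output of an unknown number of cells: whether
most tumor cells secrete PSA, and how much each secretes, cannot be read
off a serum value. Nanowell secretion assays address this at single-cell
resolution. Viable, antibody-stained cells (calcein viability dye, PSMA-PE
tumor marker, CD45-APC leukocyte marker) are seeded one-per-well onto a
chip of 6,400 microwells, each with a pore at its base. An anti-PSA capture
membrane pressed against the chip collects, over a 24-hour incubation, the
protein secreted through each pore; an anti-IgG imprint printed through the
same pores provides the registration pattern that links every membrane spot
back to a well number, and therefore to the phenotype of the cell inside.

`nanospot` implements the full quantification chain:

1. **Chip analysis** — per-well channel intensities on the multi-channel
   chip scan, and gating into PSMA+/PSMA- CTC candidates, leukocytes and
   empty wells (`measureWells()`, `classifyWells()`).
2. **Membrane registration** — detection of the imprint lattice and a
   similarity-transform fit mapping chip coordinates to membrane
   coordinates (`detectImprintSpots()`, `fitGridTransform()`,
   `mapPointToWell()`).
3. **Spot quantification** — segmentation of secretion spots with
   particle-analysis filters, normalization against background wells,
   standard-curve calibration, and conversion to pg/cell
   (`segmentSpots()`, `normalizeIntensities()`, `fitCalibration()`,
   `quantifySpots()`).
4. **Cohort assembly** — the four-group PSMA+/-PSA+/- classification,
   per-patient summaries and serum correlations (`assembleCells()`,
   `summarizePatient()`, `correlateSerum()`).
5. **Enumeration statistics** — inclusive-threshold gating of event tables
   into CK/PSMA groups with log-log concordance regression
   (`classifyEvents()`, `fitLogLogRegression()`).

Because no raw patient images are publicly deposited for assays of this
kind, the package ships a first-class synthetic generator
(`simulateAssay()`) that emulates every input with known ground truth; all
quantitative guarantees below are validated against it.

## The quantification model

For each secretion spot the chain from pixels to picograms is:

$$\mathrm{NI} = \frac{\bar{I}_{\mathrm{spot}}}{\bar{I}_{\mathrm{bg}}},
\qquad
\rho = \max\!\left(0, \frac{\mathrm{NI} - \beta_0}{\beta_1}\right)
\ \left[\mathrm{pg}/\mu m^2\right],
\qquad
\mathrm{pg/cell} = \rho \cdot A \ \left[\mu m^2\right],$$

where $\bar{I}_{\mathrm{bg}}$ is the mean membrane intensity at reference
wells (leukocyte-occupied and no-cell wells, 50 by default), $(\beta_0,
\beta_1)$ are the intercept and slope of the standard curve, and $A$ is the
segmented spot area converted through the pixel scale. The standard curve
is an ordinary least-squares line of normalized intensity on surface
density fitted on a dilution series: a drop of concentration $c$
($\mu$g/mL) and volume $v$ ($\mu$L) spread over area $A_s$ has density
$c \cdot v \cdot 10^3 / A_s$ pg/$\mu m^2$ (so 2 $\mu$L of 500 $\mu$g/mL
over $10^6\,\mu m^2$ is exactly 1 pg/$\mu m^2$).

Two design choices deserve comment:

* **Normalization by division.** "Normalizing to the average background"
  is implemented as fold-over-background division rather than subtraction.
  Division makes NI unit-free, so multiplying every membrane intensity by a
  constant $k$ (illumination, exposure, gain) cancels exactly, provided the
  standards are normalized against the same background — which the package
  does identically for standards and patient spots. A subtraction mode is
  not the default because it would re-introduce the illumination
  dependence. The invariance is asserted to $10^{-9}$ relative in the test
  suite for $k \in \{0.5, 2, 10\}$.
* **Clamping at zero.** Spots whose normalized intensity falls below the
  fitted intercept would imply negative secretion; density is clamped at
  zero and the record flagged, since secretion cannot be negative.

## Registration

The chip-to-membrane mapping is a similarity transform (isotropic scale,
rotation, translation): membrane contact printing preserves angles, so a
full affine model would only add variance. The fit is an iterated
nearest-neighbor loop: detected imprint centroids are mapped back to the
chip frame under the current estimate, matched analytically to the nearest
lattice point, pairs with residuals beyond 0.4 pitch are rejected, and the
closed-form least-squares similarity (SVD/Procrustes) is refit; five
refinement iterations are used. The loop is seeded by a lattice-aware
initialization — nearest-neighbor vectors between imprint spots run along
the rotated grid axes, so their angles folded into $(-45^\circ, 45^\circ]$
estimate the rotation and their lengths the scaled pitch. Without this
initialization a zero-rotation start leaves edge spots matched to the
wrong wells for rotations beyond a few degrees; with it, recovery is
accurate across the whole supported range ($|\theta| \le 10^\circ$,
$|t| \le$ one pitch, which covers manual clamping tolerances). Registration
aborts when fewer than three inliers survive or the RMS residual exceeds
0.25 pitch.

A membrane point maps to a well when its chip-frame position lies within
0.5 pitch of that well's center; a point exactly equidistant between wells
resolves to the lowest well id — a documented tie-break that is
unreachable in the presence of any noise.

## Segmentation

Spots are connected components (8-connectivity) above a global threshold,
filtered by a pixel-area window and by roundness in $[0.64, 1]$, the
particle-analysis convention $4 A / (\pi \cdot \mathrm{major\ axis}^2)$
with the major axis taken from the moment ellipse. The default threshold
is the robust background rule median + 5 MAD: secretion spots are sparse
(well under 1% of pixels) and span a wide brightness range, a regime in
which a two-class Otsu split can place the threshold *between* dim and
bright spots and silently drop the weakest secretors; Otsu and absolute
thresholds remain available (`threshold = "otsu"` / `"absolute"`). The
imprint image, by contrast, is genuinely bimodal (6,400 equal-brightness
spots), and imprint detection uses Otsu by default.

Fragmented spots that map to the same well are merged — areas summed,
intensities area-weighted — rather than dropped, since fragmentation is a
segmentation artifact, and how a real analysis handles two spots over one
well is not otherwise specified. Moment-based roundness of rasterised
shapes is discretization-limited below roughly 8 px (discs) / 14 px
(ellipse major semi-axis); at the assay's secretion-spot scale
(7.5–12.5 px radius at 2 $\mu$m/px) discs measure well above the 0.64
filter floor.

## Gating

Event-level enumeration uses inclusive thresholds (CK $\ge$ 50,
PSMA $\ge$ 200, matching the "intensity $\ge$" convention such gates are
stated in), after excluding events that are not DAPI-positive or are
CD45-positive. Samples with zero counts on either axis are dropped from
the log-log concordance regression with a warning — the log is undefined
and no pseudocount convention is assumed. Chip-side phenotype thresholds
(calcein/PSMA/CD45 at 500 counts by default) are configuration: the real
assay sets them by eye against an intensity bar, so the defaults here are
calibrated once against the synthetic generator's intensity scale.

Per-patient summaries report the four-group counts, the secreting
percentage, and mean/median pg/cell over secretors. Cohort-level secretion
statistics can pool all secreting cells (default) or average per-patient
means first (`summarizeCohort(mode = "patient")`); pooling is the default
because per-cell values, not patients, are the assay's unit of
observation, and the two conventions are otherwise ambiguous. Serum
correlations exclude patients without secreting cells, since their mean
secretion is undefined.

## The synthetic generator

`assayConfig()` defaults define the emulated study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_rows` x `n_cols` | 80 x 80 | 6,400 wells; the lattice arrangement is a free parameter of such chips, taken square |
| `pitch_um` | 100 | 8 mm field / 80 wells |
| `um_per_px` | 2 | keeps the full field at 4,000 x 4,000 px; real optics resolve finer, which only helps |
| `phenotype_mix` | 23/8/49/15/5 % | PSMA+/- secretors, PSMA+/- non-secretors, leukocytes: representative subpopulation frequencies for DLA-derived samples (72% PSMA+, 31% secreting) |
| `secretion_pg_range` | 2–15 pg/cell | brackets per-cell secretion averages of 4–11.7 pg/cell |
| `spot_radius_range_um` | 15–25 | drawn independently of pg, so density and area vary separately, as in the two-factor quantification |
| `calib_slope`, `calib_intercept` | 200, 1 | NI per pg/$\mu m^2$; intercept 1 = background fold at zero density |
| `noise_sd` | 40 counts | additive Gaussian on all images; the dimmest default spot then sits near 10x noise |
| `transform_*` | 1.005 / 1.5° / (8, -5) px | within clamping tolerance |

Cells render as discs filling the well footprint, so a well-disc mean
recovers the generating intensity exactly in the noiseless limit.
Secretion spots render at $\mathrm{NI} \times$ membrane background, with
$\mathrm{NI}$ on the true standard curve. Calibration standards default to
a noiseless two-fold dilution table (500 down to 31.25 $\mu$g/mL, 2 $\mu$L
drops spreading to $\approx 2 \times 10^7\,\mu m^2$, i.e. a $\approx$5 mm
drop on PVDF — chosen so the standard densities, 0.003–0.05 pg/$\mu m^2$,
bracket single-cell spot densities); intensity noise is layered on
explicitly where a test calls for it. Every output is a pure function of
the configuration and its seed.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate — includes: optical point-spread and tile-stitching
artifacts, diffusion bleed between adjacent wells, cellular debris with
nonspecific staining, partial well occupancy by multiple cells, membrane
coating inhomogeneity beyond a global scale factor, and non-rigid membrane
deformation. On real data the chip-side thresholds and the spot threshold
mode are the parameters most likely to need adjustment.

## Validation and problem sizes

The test suite validates each stage against independent oracles:
segmentation areas against a brute-force flood fill and roundness against
analytic values on 50 shapes; registration against 100 random similarity
transforms (|rotation| $\le 5^\circ$, |translation| $\le$ 50 px, scale
0.98–1.02, 0.2 px centroid jitter) on the full 80 x 80 lattice, requiring
recovery within 0.05° / 0.3 px / 0.003 and exact well assignment;
calibration against its generating line, noiseless and at 5% intensity
noise over 100 replicates; the complete pipeline on a 30 x 30 chip with
~200 secretors spanning 2–15 pg/cell at 10x SNR, requiring a median
relative pg error $\le$ 5%, a maximum $\le$ 25% and zero
secreting/non-secreting confusion; illumination invariance at
$k \in \{0.5, 2, 10\}$; and gating partition, exact log-log recovery and
Spearman unbiasedness (Gaussian copula, $\rho_S = 0.3$, $n = 200$, 100
replicates) on the statistics side. Desk-scale lattices (12 x 12 to
30 x 30 wells at the full 2 $\mu$m/px scale) are used so the suite runs in
about a minute; the geometry per well is identical to the 80 x 80 chip,
and the registration stage — the only stage whose difficulty grows with
lattice size — is exercised at the full 6,400-well size.

## A worked example

```{r example, eval = FALSE}
cfg <- assayConfig(n_rows = 16, n_cols = 16, n_cells = 40, seed = 11)
assay <- simulateAssay(cfg)
res <- analyzeAssay(chipImages(assay), assay@imprintImage, assay@psaImage,
                    assay@layout, assay@standards,
                    um_per_px = cfg@umPerPx, patient_id = "p1")
res$transform    # fitted chip-to-membrane transform
res$calibration  # fitted standard curve
res$summary      # four-group counts, secreting fraction, mean/median pg
```

## Known limitations

* One cell per well is assumed in synthesis and analysis; doublets would
  be quantified as a single cell's secretion.
* The pg/cell value is a 24-hour endpoint divided by nothing — no kinetic
  model; time-resolved secretion is out of scope.
* Quantification below the fitted calibration range is extrapolation of
  the linear curve; with real reagents linearity at very low densities is
  an assumption, which is why background-well normalization and the
  intercept matter.
* Debris rejection relies entirely on intensity thresholds and spot shape
  filters; no morphology model.
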