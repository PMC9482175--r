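---
title: "Spatial immune scoring in tumour-proximity zones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immune scoring in tumour-proximity zones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periscore)
```

## The scientific problem

The prognostic value of the peritumoral immune infiltrate in colorectal
cancer is usually assessed through CD8+ T-lymphocyte density. Downstream
indicators of *effective* immune activation — granzyme B (GZMB), released
by activated cytotoxic cells, and CD68, marking phagocytic macrophages —
may reflect the quality of the antitumoral response better than the mere
presence of CD8+ cells. Testing this requires measuring, on multiplex
brightfield IHC of tissue-microarray (TMA) cores, the density of CD8+,
GZMB+, CD68+ and CD163+ cells in the stroma at controlled distances from
tumour cell areas, and relating patient-level summaries to outcome.

`periscore` implements that measurement chain end to end:

1. **Stain unmixing** — brightfield RGB to four stain-concentration
   channels (haematoxylin + three chromogens) with a non-negative
   group-sparsity model;
2. **Segmentation** — tissue detection, PanCK-based tumour–stroma split,
   watershed nucleus detection, threshold classification, rule-based
   artefact exclusion;
3. **Tumour-proximity (TP) zones** — stromal cell densities within 10,
   25, 50, 100 µm of tumour, and in the total stroma, pooled per patient
   by area-weighted means;
4. **Scoring** — median dichotomization per marker, and the combined
   GZMB/CD68 score (`high` only if *both* marker densities exceed their
   cohort medians);
5. **Statistics** — χ²/Fisher association battery, log-density
   comparisons, Kaplan–Meier, log-rank and Cox proportional hazards.

Because TMA patient data of this kind are access-restricted, the package
ships a first-class synthetic cohort generator with known ground truth;
every stage is validated against it.

## Stain unmixing

### Model

A pixel's transmitted intensity follows the Beer–Lambert law,
$I_c = I_0 \cdot 10^{-\mathrm{OD}_c}$ per RGB channel $c$, with optical
density $\mathrm{OD} = D\,a$, where the columns of
$D \in \mathbb{R}^{3\times4}$ are unit-norm stain OD vectors and
$a \ge 0$ are stain concentrations. Concentrations are estimated per
pixel by the group-sparse objective

$$\min_{a \ge 0}\; \tfrac12\,\lVert \mathrm{OD} - D\,a\rVert^2
  + \lambda \sum_g \lVert a_g \rVert,$$

with one stain per group, so the penalty reduces to a non-negative lasso
over four concentrations. Default $\lambda = 0.1$. The solver is cyclic
coordinate descent with soft-threshold updates (tolerance $10^{-8}$, at
most 1000 sweeps), vectorized across pixels, followed by a relaxed-lasso
*debias* refit: plain least squares restricted to the selected support,
which removes the soft-threshold shrinkage from the reported
concentrations. Pixels with total OD below `od_floor` (default 0.02) are
background and skipped.

### Identifiability and the λ = 0 limit

Four stain vectors in the 3-dimensional RGB OD space always share a
one-dimensional null space, so a zero-residual representation of a mixed
pixel is generally *not unique*: plain non-negative least squares is
under-determined for some stain supports. This is a physical property of
4-chromogen brightfield imaging, not of the solver — and it is why the
sparsity penalty is part of the model. Two design choices follow:

* The default fast red and PermaGreen vectors (measured from synthetic
  single-stain renderings; configurable, as the basis is an input) are
  chosen within their physically plausible class so that the null vector
  of $D$ has a single negative component (haematoxylin) and positive
  sum. Under that sign structure the *minimal-total-concentration*
  zero-residual solution coincides with the true sparse mixture for
  every stain combination that co-occurs in rendered tissue (up to three
  co-located stains).
* `lambda = 0` is therefore implemented as the sparsity *limit*:
  minimal residual with minimal-ℓ₁ tie-break, computed exactly by
  enumerating the 15 stain subsets and their restricted least-squares
  solutions. The residual tie tolerance ($10^{-16}$) bounds the smallest
  true coefficient the tie-break can drop at about $3\times10^{-8}$.

Pixels where **four** stains truly overlap are unidentifiable in
principle (three equations, four unknowns). The staining panels this
pipeline emulates deliberately combine non-colocalising markers, and the
generator's hard-core spacing mode (below) reproduces that property, so
round-trip validation is performed on scenes where the model's
assumptions hold.

## Segmentation

All steps run on the 4-channel concentration image and are
threshold-driven (`threshold_set()`), mirroring a manually tuned
digital-pathology workflow; separate threshold sets per cohort absorb
between-run staining differences.

* *Tissue*: summed concentration ≥ `tissue_od_min` (default 0.05),
  closed with a 5 µm disc, hole-filled.
* *Tumour vs stroma*: PanCK channel ≥ `panck_min` (default 0.3) within
  tissue, closed with a 10 µm disc to merge glands. The PanCK chromogen
  is DAB in panel 1 (PanCK/CD8/CD68) and fast red in panel 2
  (GZMB/PanCK/CD163), following the staining protocol this emulates.
* *Nuclei*: Gaussian smoothing (σ = 1 µm) of the haematoxylin channel,
  threshold `nucleus_od_min` (default 0.25), Euclidean distance
  transform, watershed with tolerance `watershed_tolerance` (default 1
  distance-map pixel; 0.5 at sub-micron resolutions), area filter 8–200
  µm². Splitting nuclei ~6 µm apart requires the distance-map saddle to
  be resolved, i.e. pixel sizes ≤ 0.5 µm (the default scan resolution is
  0.25 µm/px).
* *Compartment*: by nucleus centroid (tumour mask membership) — the
  unambiguous convention in digital pathology.
* *Phenotype*: mean marker concentration in a 3 µm disc around the
  centroid against per-marker thresholds; a double-positive cell takes
  the marker with the larger threshold-normalized intensity (a
  deterministic tie-break); neither marker above threshold gives
  `double_negative`. The 3 µm disc is this package's convention for the
  difficult cytoplasm-to-nucleus signal allocation of macrophage
  markers.
* *Artefacts*: objects saturated in ≥ 3 channels or with nucleus
  solidity < 0.5 are removed — two deterministic rules standing in for
  supervised artefact classification, sufficient to remove gross
  non-cellular objects.

## Tumour-proximity zones and pooling

Distances are Euclidean, computed on the raster grid from the tumour
mask (for normal-epithelium cores, from the epithelium mask, which plays
the geometric role of tumour there). TP zones are *cumulative* discs —
stroma with $0 < d \le r$ for $r \in \{10, 25, 50, 100\}$ µm — not
annuli, so zones nest and counts/areas are monotone in the radius by
construction; `total` is the whole stroma. A core enters analysis only
if it has **more than 10** stromal cells and a tumour area fraction
**above 1%** (both strict). Patient-level densities are pooled counts
over pooled areas, the unique convention under which pooling commutes
with merging cores; a patient with no eligible core is missing (assumed
missing at random downstream).

## Scoring

Groups are formed per cohort and per (region, radius) stratum at the
median of the non-missing patient densities; `high` means *strictly
above* the median, so ties at the median go to `low` (the only reading
under which "at least one below the median" is the exact complement).
The combined GZMB/CD68 score is `high` iff both marker groups are
`high`. Ratio scores use a +1 offset in numerator and denominator (the
same offset that guards the log transform); the CD68−CD163 difference
is plain.

## Statistical conventions

* 2×2 χ² tests use the **Yates continuity correction** — the convention
  under which the five published cross-table p-values that this package
  reproduces (0.036, 0.037, 0.004, 0.006, 0.001) match to three
  decimals; larger tables are uncorrected.
* Fisher's exact test replaces χ² whenever any expected count is
  below 5; the choice is recorded per test. For large r×c tables a
  flagged Monte-Carlo fallback is used.
* Densities are compared and correlated on the `log(x + 1)` scale.
* Scale variables use the pooled-variance Student t (parametric) or
  Kruskal–Wallis (non-parametric), per the variable-type assignment
  passed by the caller.
* Survival: Kaplan–Meier product-limit curves, median follow-up by
  reverse Kaplan–Meier, two-group log-rank, and Cox regression with the
  **Efron** tie approximation (Breslow available). The log-rank χ²
  equals the Cox score test at β = 0 on tie-free data, a cross-check in
  the test suite.
* All tests are two-sided at α = 0.05 with **no multiple-testing
  correction** — a deliberate match to the single-hypothesis framing of
  per-row association tables, and a caveat for any wider use.

The Yates and exact-test conventions are conservative in small samples;
the suite's null-calibration check therefore runs at 400 patients per
replicate (500 replicates × 4 tests), where every expected count is far
above the χ² validity boundary and the empirical rejection rate sits
within the binomial band around 5%.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: TMA cores
of 0.6 mm (primary-cohort-like) or 1.0 mm (validation-cohort-like)
diameter, two cores per region and patient, four annotated regions
(tumour centre CT, tumour front FR, microenvironment ME, normal
epithelium NE), and two staining panels. Defaults:

* **Geometry** — circular tissue disc; tumour blobs are the upper
  quantile of a Gaussian random field (smoothing length 40 µm) occupying
  `tumour_fraction` (default 0.35) of tissue in CT/FR, 40% of that in
  ME, none in NE (where epithelium blobs serve as distance reference).
* **Cells** — inhomogeneous Poisson placement. Base densities are
  order-of-magnitude choices informed by the published density
  distributions, which are reported only graphically: CD8 300, GZMB
  100, CD68 400, CD163 350, marker-negative 800 per mm² at CT, declining
  toward NE; tumour nuclei 1500 per mm². Marker intensities within 25 µm
  of tumour are multiplied by `proximity_enrichment` (default 3 for CD8,
  GZMB, CD68) in latent *high* patients only. An optional Matérn-II
  hard-core mode (`min_cell_spacing`) thins proposals below a minimum
  spacing while inflating the proposal intensity
  ($-\log(1-\lambda\pi s^2)/(\pi s^2)$) so realized densities still
  match the configuration; at spacing ≥ 7.5 µm different-chromogen
  deposits can never overlap, emulating the non-colocalising panel
  design.
* **Rendering** — nuclei are Gaussian discs (σ = 2 µm, truncated at
  4 µm), marker chromogens perinuclear flat discs (3.5 µm), PanCK a
  smoothed template over the tumour mask, plus a faint diffuse
  haematoxylin background (0.12) over the tissue disc so tissue is
  detectable between nuclei. Amplitudes are sized to keep summed OD
  inside the 8-bit dynamic range ($\log_{10} 255 \approx 2.4$).
  Transmitted intensities are Beer–Lambert with optional Gaussian OD
  noise; images stay continuous in memory and are quantized only on PNG
  export.
* **Outcome** — each patient draws a balanced latent low/high group;
  survival is exponential with hazard
  $h_0 \cdot \mathrm{HR}^{\mathbb{1}\{\text{high}\}}$ (defaults
  $h_0 = 0.02$/month, HR = 0.25, matching the strong effects this kind
  of score shows), censoring mixes an administrative horizon (120
  months) with random censoring (rate 0.3). Clinical covariates follow
  the published cohort tables' marginal frequencies (TNM stage
  17.5/39.2/23.7/19.6%, pT4 16.2%, venous invasion 42%) and are
  independent of the latent group unless confounding is requested.

What the generator does **not** emulate: realistic histomorphology,
nuclear texture, chromatic aberration, staining gradients, folds or
out-of-focus cores. Passing tests therefore demonstrate correctness of
the measurement chain under the model's assumptions, not robustness to
every real-world artefact; on real material the threshold sets and the
artefact rules would need cohort-specific tuning, as manual workflows
do.

## Numerical choices and degenerate inputs

* Coordinate descent: tolerance $10^{-8}$ on the maximum coefficient
  change, 1000-sweep cap; basis vectors with pairwise cosine above
  $1-10^{-6}$ are rejected as ill-conditioned.
* Subset enumeration (λ = 0): residual tie tolerance $10^{-16}$,
  ℓ₁ tie tolerance $10^{-12}$.
* Zero margins in contingency tables give p = 1 with a warning;
  zero-variance inputs to t/correlation tests are flagged rather than
  raised; log-rank with no events and Cox under complete separation
  return flagged results.
* A centroid on a pixel boundary belongs to that pixel (half-open
  membership), eliminating double counting; all coordinates are
  core-local micrometres, origin top-left, y downward.
* Seeds: one master seed fans out to per-core seeds through a Lehmer
  step kept below $2^{31}-1$; identical seed + configuration is
  byte-identical end to end.

## Problem sizes used in validation

The shipped validation suite exercises: cores of 400–600 µm at 1–2 µm/px
(sub-micron resolution only for the nucleus-splitting checks); 50
synthetic cores for the zone-count oracle; 1000 pixels for the NNLS
oracle; 200 random tables for the Fisher enumeration oracle; 50
simulated cohorts of n = 200 for Cox/log-rank recovery and power; 500
null cohorts of n = 400 (2000 tests) for type-I calibration. These sizes
were chosen to give stable Monte-Carlo margins while keeping the suite
quick to run; all scale up through the same functions.

## Known limitations

* Four co-located stains per pixel are unidentifiable from RGB (see
  above); concentrations at such pixels follow the sparsity tie-break.
* The watershed cannot split nuclei closer than ~5 µm at coarse pixel
  sizes; counts at 2 µm/px run ~5–13% low on dense pure-Poisson scenes,
  within the documented tolerance but biased low.
* Zone areas intersect the dilation with the stroma mask; whether
  non-tissue background inside the dilation should count toward the
  area is a convention, and this package excludes it.
* Median cut-offs are crude (no ROC optimization, matching the design
  this emulates), so effect sizes are conservative.
* The artefact rules are deterministic stand-ins, not a trained
  classifier.
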