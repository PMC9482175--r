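# periscore

Spatial immune scoring of multiplex brightfield immunohistochemistry in
colorectal-cancer tissue microarrays (TMAs): from RGB core images to
patient-level prognostic scores and their statistical evaluation.

## The problem

The density of CD8+ T lymphocytes near tumour cells is the established
immune prognostic marker in colorectal cancer, but it measures presence,
not effect. Granzyme B (GZMB, effector protease of activated cytotoxic
cells) and CD68 (phagocytic macrophages) indicate *active* antitumoral
function. Evaluating them spatially requires measuring stromal cell
densities of CD8+, GZMB+, CD68+ and CD163+ cells within fixed distances
of tumour cell areas — tumour-proximity (TP) zones of radius 10, 25, 50
and 100 µm — across annotated tissue regions (tumour centre, front,
microenvironment, normal epithelium), then dichotomizing patients at the
cohort median and testing association and survival. The headline score
is the **combined GZMB/CD68 group**: a patient is *high* only if both
the GZMB and the CD68 density in the TP25µm zone exceed their cohort
medians.

`periscore` implements the whole measurement chain for users in digital
pathology and tumour-immunology biostatistics:

* **Unmixing** — brightfield RGB → 4 stain channels via a non-negative
  group-sparsity model: per pixel, `min ½‖OD − D·a‖² + λ·Σ‖a_g‖` with
  one stain per group (λ = 0.1, non-negativity), OD from Beer–Lambert
  (`OD_c = log10(I0/I_c)`), solved by coordinate descent with a
  debiasing refit; λ = 0 gives the exact sparsity-limit solution.
* **Segmentation** — threshold-driven tissue detection, PanCK-based
  tumour–stroma split, watershed nucleus detection, marker
  classification, rule-based artefact exclusion (EBImage under the
  hood).
* **TP-zone quantification** — Euclidean distance transform from the
  tumour mask; cumulative zones `0 < d ≤ r`; strict core QC (> 10
  stromal cells, > 1 % tumour area); patient pooling by pooled counts
  over pooled areas.
* **Scoring and statistics** — strict-median dichotomization, combined
  GZMB/CD68 group, ratio scores; χ² (Yates for 2×2) with the
  expected-count < 5 Fisher rule, log(x+1) density comparisons,
  Kaplan–Meier, log-rank, Cox regression (Efron ties).
* **Synthetic cohort generator** — TMA cores with known ground truth
  (geometry, cell placement, rendering, survival model), because the
  tissue data this methodology targets are access-restricted; every
  stage is validated against it.

## Worked example

```r
library(periscore)

cfg <- simulation_config(
  seed = 42, n_patients = 60, cores_per_patient = 2,
  core_diameter = 600, pixel_size = 2, blob_scale = 40, regions = "CT",
  proximity_enrichment = c(CD8 = 3, GZMB = 3, CD68 = 3, CD163 = 1))

res <- run_pipeline(cfg, "demo_out")

head(res$pooled[res$pooled$radius == "25", ], 4)
#>    patient_id region marker radius cell_count zone_area_mm2 density_per_mm2
#> 3       P0001     CT    CD8     25         41        0.1109           369.6
#> 4       P0001     CT   CD68     25         34        0.1109           306.5
#> 13      P0001     CT   GZMB     25         14        0.1297           107.9
#> 14      P0001     CT  CD163     25         57        0.1297           439.3

res$scores[1:4, c("patient_id", "cd8_group", "gzmb_group",
                  "cd68_group", "combined_gzmb_cd68")]
#>   patient_id cd8_group gzmb_group cd68_group combined_gzmb_cd68
#> 1      P0001       low        low        low                low
#> 2      P0002       low        low        low                low
#> 3      P0003       low        low        low                low
#> 4      P0004       low        low        low                low

res$survival_tests
#>                group logrank_p    hr     hr_p
#> 1          cd8_group  3.23e-05 0.229 0.000109
#> 2         gzmb_group  3.23e-05 0.229 0.000109
#> 3         cd68_group  3.23e-05 0.229 0.000109
#> 4 combined_gzmb_cd68  3.23e-05 0.229 0.000109
```

Each patient's TP25µm densities are pooled over that patient's cores
(counts over areas), dichotomized at the cohort median, and tested
against outcome: the simulated hazard ratio of 0.25 for high-density
patients is recovered at 0.229 with log-rank p = 3×10⁻⁵. At this effect
size every marker's median split recovers the latent ground-truth group
exactly, so the four rows coincide — with weaker enrichment they
separate.

A single association test, as used for the clinicopathological tables:

```r
chi_square_test(matrix(c(52, 16, 62, 6), 2))
#> chi_square: statistic = 4.392344, df = 1, p = 0.0361
```

The full image path is available with `run_pipeline(..., image_stages =
TRUE)` (render → unmix → segment per core), and stage functions
(`render_brightfield`, `unmix_core`, `segment_core`, `quantify_core`,
`score_patients`, `cox_fit`, ...) are exported individually.

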