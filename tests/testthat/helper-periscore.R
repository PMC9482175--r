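# small shared fixtures, built once per test run

tiny_config <- function(seed = 11, n_patients = 4L, ...) {
  simulation_config(seed = seed, n_patients = n_patients,
                    cores_per_patient = 1L,
                    core_diameter = 400, pixel_size = 2, blob_scale = 30,
                    regions = c("CT", "NE"), ...)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# a rendered + unmixed + segmented CT core (panel 1, noiseless)
seg_fixture <- function() {
  cached("seg_fixture", {
    cfg <- simulation_config(seed = 21, core_diameter = 400, pixel_size = 1,
                             blob_scale = 30, min_cell_spacing = 7.5)
    sc <- simulate_core(cfg, "P1", "CT", panel = 1)
    rb <- render_brightfield(sc, noise_sd = 0)
    conc <- unmix_core(rb$rgb, config = unmix_config())
    seg <- segment_core(conc, threshold_set(watershed_tolerance = 0.5),
                        pixel_size = 1, panel = 1)
    list(cfg = cfg, scene = sc, render = rb, conc = conc, seg = seg)
  })
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_p_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force zone counts: exact Euclidean pixel-centre distances from each
# cell's pixel to the nearest source-mask pixel, no distance transform
brute_zone_counts <- function(scene, marker, radii, pixel_size) {
  src <- scene$tumour_mask
  if (!any(src)) src <- scene$reference_mask
  sp <- which(src, arr.ind = TRUE)
  cells <- scene$cells
  sel <- cells$compartment == "stroma" & cells$phenotype == marker
  xs <- floor(cells$x_um[sel] / pixel_size) + 1
  ys <- floor(cells$y_um[sel] / pixel_size) + 1
  dmin <- vapply(seq_along(xs), function(i) {
    sqrt(min((sp[, 1] - xs[i])^2 + (sp[, 2] - ys[i])^2)) * pixel_size
  }, numeric(1))
  # cells on stroma pixels always have distance > 0
  counts <- vapply(radii, function(r) sum(dmin > 0 & dmin <= r), numeric(1))
  c(counts, total = length(dmin))
}

# survival-only cohort draw used by power / recovery tests
draw_survival <- function(n, hr, seed, baseline = 0.02, censor = 0.2,
                          horizon = 120) {
  cfg <- simulation_config(seed = seed, n_patients = n,
                           hazard_ratio_high_vs_low = hr,
                           baseline_hazard = baseline, censor_rate = censor,
                           follow_up_horizon = horizon)
  ch <- simulate_cohort(cfg, include_scenes = FALSE)
  merge(ch$survival, ch$clinical[, c("patient_id", "group_true")],
        by = "patient_id")
}
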