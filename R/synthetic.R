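#' Default expected stromal cell densities per marker and tissue region
#'
#' Order-of-magnitude densities (cells per mm^2 of stroma) for the four
#' immune markers and for marker-negative stromal cells, in each annotated
#' tissue region: tumour centre (CT), tumour front (FR), microenvironment
#' (ME) and normal epithelium (NE). Immune infiltrates are densest at the
#' tumour centre/front and sparse in normal mucosa; granzyme-B-positive
#' cells are roughly an order of magnitude rarer than CD8-positive cells.
#'
#' @return numeric matrix, rows `CD8, GZMB, CD68, CD163, negative`,
#'   columns `CT, FR, ME, NE`, unit 1/mm^2.
#' @export
default_base_densities <- function() {
  m <- rbind(
    CD8      = c(CT = 300, FR = 250, ME = 200, NE = 100),
    GZMB     = c(CT = 100, FR = 80,  ME = 60,  NE = 20),
    CD68     = c(CT = 400, FR = 350, ME = 300, NE = 100),
    CD163    = c(CT = 350, FR = 300, ME = 250, NE = 80),
    negative = c(CT = 800, FR = 800, ME = 800, NE = 800)
  )
  m
}

#' Simulation configuration for a synthetic TMA cohort
#'
#' Bundles and validates all parameters of the synthetic tissue-microarray
#' generator: core geometry, per-region expected cell densities, tumour
#' geometry, proximity enrichment of immune cells near tumour, and the
#' survival model linking a latent high/low density group to outcome.
#'
#' @param seed integer master seed; identical seed and configuration give
#'   byte-identical output.
#' @param n_patients number of patients.
#' @param cores_per_patient cores per tissue region per patient.
#' @param core_diameter core diameter in micrometres (600 emulates a
#'   0.6 mm primary-cohort core, 1000 a 1.0 mm validation-cohort core).
#' @param pixel_size raster resolution in micrometres per pixel.
#' @param regions subset of `c("CT","FR","ME","NE")` to generate.
#' @param base_densities marker-by-region matrix of expected stromal
#'   densities (1/mm^2); see [default_base_densities()].
#' @param tumour_fraction fraction of tissue area occupied by tumour blobs
#'   in CT/FR cores (strictly between 0 and 1); ME uses 0.4 of this value,
#'   NE has no tumour (an epithelium mask of the same fraction is generated
#'   instead and serves as the distance reference).
#' @param tumour_cell_density nuclei per mm^2 inside tumour/epithelium.
#' @param proximity_enrichment named multiplicative density factor per
#'   marker applied within 25 micrometres of the tumour mask (scenes of
#'   latent "high" patients only).
#' @param hazard_ratio_high_vs_low hazard ratio of the latent high group
#'   relative to the low group (> 0).
#' @param baseline_hazard exponential hazard of the low group, 1/month.
#' @param censor_rate probability that a patient receives a random (rather
#'   than administrative) censoring time.
#' @param follow_up_horizon administrative censoring time, months.
#' @param blob_scale smoothing length (micrometres) of the Gaussian random
#'   field whose upper quantile forms the tumour blobs.
#' @param min_cell_spacing hard-core minimum distance (micrometres)
#'   between stromal cell centres; 0 (default) keeps the pure Poisson
#'   process. A positive value applies Matern-II thinning with the
#'   proposal intensity inflated so the realized density still matches
#'   `base_densities`; it emulates the study's deliberately
#'   non-colocalising marker panels, guaranteeing chromogen deposits of
#'   different markers never overlap (use >= 7.5 for that guarantee).
#' @param confound_covariates if `TRUE`, clinical covariates are made to
#'   depend on the latent group; default `FALSE` keeps them independent so
#'   multivariate models are interpretable against ground truth.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 107L,
                              cores_per_patient = 2L,
                              core_diameter = 600,
                              pixel_size = 0.25,
                              regions = c("CT", "FR", "ME", "NE"),
                              base_densities = default_base_densities(),
                              tumour_fraction = 0.35,
                              tumour_cell_density = 1500,
                              proximity_enrichment = c(CD8 = 3, GZMB = 3,
                                                       CD68 = 3, CD163 = 1),
                              hazard_ratio_high_vs_low = 0.25,
                              baseline_hazard = 0.02,
                              censor_rate = 0.3,
                              follow_up_horizon = 120,
                              blob_scale = 40,
                              min_cell_spacing = 0,
                              confound_covariates = FALSE) {
  if (!is.numeric(core_diameter) || core_diameter <= 0)
    stop("`core_diameter` must be a positive length in micrometres")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a positive length in micrometres per pixel")
  if (n_patients < 0 || cores_per_patient < 1)
    stop("`n_patients` must be >= 0 and `cores_per_patient` >= 1")
  regions <- match.arg(regions, c("CT", "FR", "ME", "NE"), several.ok = TRUE)
  if (any(base_densities < 0)) stop("all base densities must be >= 0")
  if (!(tumour_fraction > 0 && tumour_fraction < 1))
    stop("`tumour_fraction` must lie strictly in (0, 1)")
  if (hazard_ratio_high_vs_low <= 0) stop("hazard ratio must be > 0")
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be > 0")
  if (censor_rate < 0 || censor_rate > 1)
    stop("`censor_rate` must lie in [0, 1]")
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              cores_per_patient = as.integer(cores_per_patient),
              core_diameter = core_diameter, pixel_size = pixel_size,
              regions = regions, base_densities = base_densities,
              tumour_fraction = tumour_fraction,
              tumour_cell_density = tumour_cell_density,
              proximity_enrichment = proximity_enrichment,
              hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              follow_up_horizon = follow_up_horizon, blob_scale = blob_scale,
              min_cell_spacing = min_cell_spacing,
              confound_covariates = isTRUE(confound_covariates))
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic per-core seed stream: Lehmer step on the master seed plus an
# index offset, kept below 2^31 - 1 so it is a valid R seed
derive_seed <- function(seed, k) {
  m <- 2147483647
  as.integer((((seed %% m) + 1) * 48271 + k) %% m)
}

# stable small integer from an identifier string (polynomial rolling hash)
id_index <- function(id) {
  v <- utf8ToInt(as.character(id))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 99991
  h
}

# chromogen role of each stain channel in the two staining panels
panel_stains <- function(panel) {
  if (panel == 1L)
    list(panck = "dab", markers = c(CD8 = "fast_red", CD68 = "perma_green"))
  else if (panel == 2L)
    list(panck = "fast_red", markers = c(GZMB = "dab", CD163 = "perma_green"))
  else stop("`panel` must be 1 or 2")
}

stain_channel_names <- function() c("haematoxylin", "dab", "fast_red", "perma_green")

# smooth random blobs covering `fraction` of the pixels where `within` is TRUE
random_blob_mask <- function(n, within, fraction, sigma_px) {
  if (fraction <= 0) return(matrix(FALSE, n, n))
  field <- matrix(rnorm(n * n), n, n)
  sm <- as.matrix(EBImage::gblur(field, sigma = max(sigma_px, 1)))
  thr <- quantile(sm[within], 1 - fraction, names = FALSE)
  within & (sm > thr)
}

# uniform points on the TRUE pixels of a mask, jittered within the pixel;
# returns x/y in micrometres (origin top-left, x rightward, y downward)
sample_points_on_mask <- function(mask, n_points, pixel_size) {
  idx <- which(mask)
  if (length(idx) == 0L || n_points == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  pick <- idx[sample.int(length(idx), n_points, replace = TRUE)]
  nr <- nrow(mask)
  ix <- ((pick - 1L) %% nr) + 1L       # first index = x (EBImage convention)
  iy <- ((pick - 1L) %/% nr) + 1L
  data.frame(x_um = (ix - runif(n_points)) * pixel_size,
             y_um = (iy - runif(n_points)) * pixel_size)
}

#' Simulate one TMA core scene
#'
#' Generates the ground-truth geometry and cell population of a single
#' tissue-microarray core: a circular tissue disc, smooth tumour blobs
#' (CT/FR; reduced in ME; an epithelium reference in NE), tumour nuclei,
#' and stromal cells placed by an inhomogeneous Poisson process whose
#' intensity is the configured per-marker density, multiplied by the
#' configured enrichment factor within 25 micrometres of the tumour mask
#' when `enrich = TRUE`.
#'
#' @param config a [simulation_config()].
#' @param patient_id,core_id identifiers stored in the scene.
#' @param region one of `"CT","FR","ME","NE"`.
#' @param panel staining panel, 1 (PanCK/CD8/CD68) or 2 (GZMB/PanCK/CD163).
#' @param enrich apply `proximity_enrichment` near tumour.
#' @param seed RNG seed for this core; defaults to a seed derived
#'   deterministically from `config$seed` and the identifiers.
#' @return a `core_scene`: list with masks (`tissue_mask`, `tumour_mask`,
#'   `stroma_mask`, `reference_mask`, logical matrices indexed x-by-y), a
#'   `cells` data frame (`x_um`, `y_um`, `compartment`, `phenotype`, per-
#'   channel intensity columns), `pixel_size` and identifiers.
#' @export
simulate_core <- function(config, patient_id, region, panel = 1L,
                          core_id = 1L, enrich = FALSE, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  region <- match.arg(region, c("CT", "FR", "ME", "NE"))
  if (!region %in% config$regions)
    stop("region ", region, " not in config$regions")
  if (is.null(seed)) {
    ridx <- match(region, c("CT", "FR", "ME", "NE"))
    k <- (id_index(patient_id) * 64L +
            ridx * 16L + as.integer(core_id) * 4L + as.integer(panel))
    seed <- derive_seed(config$seed, k)
  }
  set.seed(seed)
  px <- config$pixel_size
  n <- ceiling(config$core_diameter / px)
  r <- config$core_diameter / 2
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  tissue <- ((xs - ctr)^2 + (ys - ctr)^2) * px^2 <= r^2

  frac <- switch(region, CT = config$tumour_fraction,
                 FR = config$tumour_fraction,
                 ME = 0.4 * config$tumour_fraction, NE = 0)
  sigma_px <- config$blob_scale / px
  tumour <- random_blob_mask(n, tissue, frac, sigma_px)
  if (region == "NE") {
    reference <- random_blob_mask(n, tissue, config$tumour_fraction, sigma_px)
  } else {
    reference <- tumour
  }
  stroma <- tissue & !reference

  # 25 um dilation of the reference mask defines the enrichment region
  enr_zone <- NULL
  if (enrich && any(reference)) {
    brush_r <- max(1L, round(25 / px))
    brush <- EBImage::makeBrush(2L * brush_r + 1L, shape = "disc")
    enr_zone <- as.matrix(EBImage::dilate(
      EBImage::Image(reference * 1), brush)) > 0.5
    enr_zone <- enr_zone & stroma
  }

  area_mm2 <- function(mask) sum(mask) * px^2 / 1e6
  chn <- stain_channel_names()
  ps <- panel_stains(panel)

  place <- function(mask, density, compartment, phenotype) {
    k <- rpois(1L, density * area_mm2(mask))
    pts <- sample_points_on_mask(mask, k, px)
    if (nrow(pts) == 0L)
      return(cbind(pts, data.frame(compartment = character(0),
                                   phenotype = character(0))))
    pts$compartment <- compartment
    pts$phenotype <- phenotype
    pts
  }

  cells <- list()
  tum_phen <- if (region == "NE") "epithelium" else "tumour"
  tum_comp <- tum_phen
  cells[[tum_phen]] <- place(reference, config$tumour_cell_density,
                             tum_comp, tum_phen)

  # hard-core spacing: inflate the proposal intensity so Matern-II
  # thinning still realizes the configured densities
  markers <- c(names(ps$markers), "negative")
  dens <- setNames(config$base_densities[markers, region], markers)
  spacing <- config$min_cell_spacing
  infl <- 1
  if (spacing > 0) {
    disc <- pi * spacing^2 / 1e6            # mm^2
    load <- sum(dens) * disc
    if (load >= 1)
      stop("total stromal density too high for `min_cell_spacing` (jamming)")
    infl <- if (load > 0) -log(1 - load) / load else 1
  }
  stromal <- list()
  for (m in markers) {
    phen <- if (m == "negative") "double_negative" else m
    part <- place(stroma, dens[[m]] * infl, "stroma", phen)
    if (!is.null(enr_zone) && m != "negative") {
      f <- config$proximity_enrichment[[m]]
      if (!is.null(f) && is.finite(f) && f > 1) {
        extra <- place(enr_zone, dens[[m]] * infl * (f - 1), "stroma", phen)
        part <- rbind(part, extra)
      }
    }
    stromal[[m]] <- part
  }
  stromal <- do.call(rbind, stromal)
  if (spacing > 0 && nrow(stromal) > 1L)
    stromal <- matern_thin(stromal, spacing)
  cells <- rbind(do.call(rbind, cells), stromal)
  rownames(cells) <- NULL

  # per-cell chromogen amplitudes (optical-density scale)
  nc <- nrow(cells)
  for (ch in chn) cells[[paste0("int_", ch)]] <- 0
  if (nc > 0L) {
    # amplitudes sized so summed optical density stays inside the 8-bit
    # dynamic range (max OD log10(255) ~ 2.4) even where stains overlap
    cells$int_haematoxylin <- rlnorm(nc, log(0.7), 0.1)
    mk <- cells$phenotype
    for (m in names(ps$markers)) {
      sel <- mk == m
      cells[[paste0("int_", ps$markers[[m]])]][sel] <-
        rlnorm(sum(sel), log(0.6), 0.1)
    }
  }

  scene <- list(patient_id = patient_id, core_id = core_id, region = region,
                panel = as.integer(panel), pixel_size = px, dim = c(n, n),
                tissue_mask = tissue, tumour_mask = tumour,
                stroma_mask = stroma, reference_mask = reference,
                cells = cells, seed = seed)
  class(scene) <- "core_scene"
  scene
}

#' @export
print.core_scene <- function(x, ...) {
  cat(sprintf("<core_scene> patient %s core %s region %s panel %d\n",
              x$patient_id, x$core_id, x$region, x$panel))
  cat(sprintf("  %d x %d px @ %.3g um/px; %d cells; tumour fraction %.3f\n",
              x$dim[1], x$dim[2], x$pixel_size, nrow(x$cells),
              sum(x$tumour_mask) / max(1, sum(x$tissue_mask))))
  invisible(x)
}

# Matern-II hard-core thinning: keep a point unless an older (lower-mark)
# point lies within `spacing` micrometres
matern_thin <- function(pts, spacing) {
  n <- nrow(pts)
  ord <- sample.int(n)                    # uniform birth marks
  pts <- pts[ord, , drop = FALSE]
  keep <- rep(TRUE, n)
  d2 <- spacing^2
  for (i in seq_len(n)[-1]) {
    dx <- pts$x_um[seq_len(i - 1L)] - pts$x_um[i]
    dy <- pts$y_um[seq_len(i - 1L)] - pts$y_um[i]
    if (any(keep[seq_len(i - 1L)] & (dx * dx + dy * dy < d2)))
      keep[i] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

# unnormalized kernels with peak 1; a sum-preserving blur would scale
# amplitudes down, which is not what a stain template needs.  Nuclei are
# Gaussian discs truncated at `radius`; marker chromogens flat discs.
stamp_kernel <- function(pixel_size, radius_um, sigma_um = NULL) {
  h <- max(1L, ceiling(radius_um / pixel_size))
  r2 <- outer(-h:h, -h:h, function(i, j) (i^2 + j^2) * pixel_size^2)
  if (is.null(sigma_um)) k <- (r2 <= radius_um^2) * 1
  else k <- exp(-r2 / (2 * sigma_um^2)) * (r2 <= radius_um^2)
  k
}

stamp_cells <- function(dims, cells_xy, amplitudes, pixel_size,
                        radius_um, sigma_um = NULL) {
  img <- matrix(0, dims[1], dims[2])
  if (nrow(cells_xy) == 0L) return(img)
  ix <- pmin(dims[1], pmax(1L, floor(cells_xy$x_um / pixel_size) + 1L))
  iy <- pmin(dims[2], pmax(1L, floor(cells_xy$y_um / pixel_size) + 1L))
  for (i in seq_along(ix)) img[ix[i], iy[i]] <- img[ix[i], iy[i]] + amplitudes[i]
  k <- stamp_kernel(pixel_size, radius_um, sigma_um)
  out <- as.matrix(EBImage::filter2(img, k, boundary = 0))
  out[out < 0] <- 0                 # FFT convolution ripple
  out
}

#' Render a brightfield RGB image of a core scene
#'
#' Rasterizes stain-concentration templates (haematoxylin Gaussian discs at
#' every nucleus, PanCK chromogen over the tumour/epithelium mask,
#' marker chromogens as perinuclear discs at marker-positive cells) and
#' converts them to transmitted RGB intensity through the Beer-Lambert law
#' `I_c = I0 * 10^(-sum_s conc_s * d_s,c)`, optionally adding Gaussian
#' noise on the optical-density scale.
#'
#' Values are returned as continuous intensities in `[0, I0]`; quantization
#' to 8 bits happens only on file output (see [write_rgb_png()]).
#'
#' @param scene a `core_scene` from [simulate_core()].
#' @param basis a [stain_basis()] (3 x 4 matrix of unit optical-density
#'   vectors).
#' @param noise_sd standard deviation of additive optical-density noise.
#' @param I0 background (blank) intensity per channel.
#' @param conc_scale concentration of the PanCK template over tumour.
#' @param bg_haematoxylin diffuse haematoxylin concentration over the
#'   whole tissue disc (cytoplasmic counterstain background); makes the
#'   tissue area detectable between nuclei.
#' @return list with `rgb` (x-by-y-by-3 array of intensities) and
#'   `concentrations` (x-by-y-by-4 ground-truth array, channels named).
#' @export
render_brightfield <- function(scene, basis = stain_basis(), noise_sd = 0,
                               I0 = 255, conc_scale = 0.5,
                               bg_haematoxylin = 0.12) {
  stopifnot(inherits(scene, "core_scene"))
  chn <- stain_channel_names()
  stopifnot(identical(colnames(basis), chn))
  dims <- scene$dim
  px <- scene$pixel_size
  conc <- array(0, c(dims, 4L), dimnames = list(NULL, NULL, chn))

  if (bg_haematoxylin > 0 && any(scene$tissue_mask)) {
    bg <- as.matrix(EBImage::gblur(scene$tissue_mask * bg_haematoxylin,
                                   sigma = max(1, 0.5 / px)))
    bg[bg < 0] <- 0
    conc[, , "haematoxylin"] <- bg
  }
  cells <- scene$cells
  if (nrow(cells) > 0L) {
    # nuclei: Gaussian discs of radius ~4 um; markers: perinuclear flat
    # discs of radius 3.5 um (inside the nucleus footprint)
    conc[, , "haematoxylin"] <- conc[, , "haematoxylin"] +
      stamp_cells(dims, cells, cells$int_haematoxylin, px,
                  radius_um = 4, sigma_um = 2)
    ps <- panel_stains(scene$panel)
    for (m in names(ps$markers)) {
      ch <- ps$markers[[m]]
      sel <- cells$phenotype == m
      if (any(sel))
        conc[, , ch] <- conc[, , ch] +
          stamp_cells(dims, cells[sel, , drop = FALSE],
                      cells[[paste0("int_", ch)]][sel], px,
                      radius_um = 3.5)
    }
    panck_ch <- ps$panck
    if (any(scene$reference_mask)) {
      tmpl <- as.matrix(EBImage::gblur(scene$reference_mask * conc_scale,
                                       sigma = max(1, 0.5 / px)))
      tmpl[tmpl < 0] <- 0
      conc[, , panck_ch] <- conc[, , panck_ch] + tmpl
    }
  }

  od <- array(0, c(dims, 3L))
  for (ch in 1:3) {
    o <- matrix(0, dims[1], dims[2])
    for (s in 1:4) o <- o + conc[, , s] * basis[ch, s]
    od[, , ch] <- o
  }
  if (noise_sd > 0) od <- od + array(rnorm(length(od), 0, noise_sd), dim(od))
  rgb <- I0 * 10^(-od)
  rgb[rgb < 0] <- 0
  rgb[rgb > I0] <- I0
  list(rgb = rgb, concentrations = conc)
}

simulate_survival_times <- function(n, hazard_ratio, baseline_hazard,
                                    censor_rate, horizon, group_high) {
  rate <- baseline_hazard * hazard_ratio^as.numeric(group_high)
  t_event <- rexp(n, rate)
  c_time <- ifelse(runif(n) < censor_rate, runif(n, 0, horizon), horizon)
  time <- pmin(t_event, c_time)
  data.frame(time = pmax(time, 1e-6), event = as.integer(t_event <= c_time))
}

#' Draw clinical covariates from the cohorts' marginal frequencies
#'
#' TNM stage, pT, venous invasion and adjuvant chemotherapy are sampled
#' independently of the latent density group unless `confound = TRUE`.
#'
#' @param n number of patients.
#' @param group_high logical vector, latent high-density group.
#' @param confound make stage/pT depend on the latent group.
#' @return data frame `tnm_stage`, `pT`, `venous_invasion`, `postop_chemo`.
#' @export
simulate_clinical_covariates <- function(n, group_high, confound = FALSE) {
  # marginal frequencies follow the cohort characteristics tables:
  # TNM I-IV 17.5/39.2/23.7/19.6 %, pT4 16.2 %, venous invasion 42 %
  p_tnm <- c(0.175, 0.392, 0.237, 0.196)
  tnm <- sample(1:4, n, replace = TRUE, prob = p_tnm)
  pT <- sample(3:4, n, replace = TRUE, prob = c(0.838, 0.162))
  ven <- rbinom(n, 1, 0.42)
  chemo <- rbinom(n, 1, 0.35)
  if (confound && n > 0) {
    flip <- group_high & runif(n) < 0.4
    tnm[flip] <- pmax(1L, tnm[flip] - 1L)
    pT[flip] <- 3L
  }
  data.frame(tnm_stage = tnm, pT = pT, venous_invasion = ven,
             postop_chemo = chemo)
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Assigns each patient a balanced latent low/high group, draws exponential
#' survival times whose hazard is `baseline_hazard * hazard_ratio^(high)`,
#' independent censoring, clinical covariates from the configured marginal
#' frequencies, and (optionally) per-core scenes in which "high" patients
#' receive the configured proximity enrichment of immune cells near tumour.
#'
#' @param config a [simulation_config()].
#' @param include_scenes generate image-level scenes (set `FALSE` for
#'   survival/statistics studies where only tables are needed).
#' @param panels staining panels to generate scenes for.
#' @param endpoint endpoint label stored in the survival table
#'   (`"overall"` for a primary-cohort emulation, `"disease_free"` for a
#'   validation-cohort one).
#' @return list with `scenes` (list of `core_scene`, possibly empty),
#'   `clinical` (data frame with `patient_id`, covariates, latent
#'   `group_true`) and `survival` (data frame `patient_id`, `time`,
#'   `event`, `endpoint`).
#' @export
simulate_cohort <- function(config, include_scenes = TRUE, panels = 1:2,
                            endpoint = c("overall", "disease_free")) {
  stopifnot(inherits(config, "simulation_config"))
  endpoint <- match.arg(endpoint)
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0L) {
    return(list(scenes = list(),
                clinical = data.frame(patient_id = character(0)),
                survival = data.frame(patient_id = character(0),
                                      time = numeric(0), event = integer(0),
                                      endpoint = character(0))))
  }
  pid <- sprintf("P%04d", seq_len(n))
  group <- sample(rep(c("low", "high"), length.out = n))
  surv <- simulate_survival_times(n, config$hazard_ratio_high_vs_low,
                                  config$baseline_hazard, config$censor_rate,
                                  config$follow_up_horizon, group == "high")
  clin <- simulate_clinical_covariates(n, group == "high",
                                       config$confound_covariates)
  clinical <- cbind(data.frame(patient_id = pid, group_true = group), clin)
  survival <- data.frame(patient_id = pid, time = surv$time,
                         event = surv$event, endpoint = endpoint)

  scenes <- list()
  if (include_scenes) {
    for (i in seq_len(n)) for (rg in config$regions)
      for (co in seq_len(config$cores_per_patient)) for (pl in panels) {
        sc <- simulate_core(config, pid[i], rg, panel = pl, core_id = co,
                            enrich = group[i] == "high")
        scenes[[length(scenes) + 1L]] <- sc
      }
  }
  list(scenes = scenes, clinical = clinical, survival = survival)
}
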