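#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> (render -> unmix -> segment) -> QC -> quantify ->
#' pool -> score -> associate -> survive and writes every stage's tables
#' to `out_dir`, together with a manifest of file hashes. Rerunning with
#' the same configuration reproduces identical tables.
#'
#' With `image_stages = FALSE` the image stages are skipped and the
#' generator's ground-truth masks and cell labels feed the quantification
#' directly; this is the fast path for statistical studies, while
#' `image_stages = TRUE` exercises the complete image-analysis chain.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @param image_stages run rendering, unmixing and segmentation instead
#'   of using generator ground truth.
#' @param thresholds a [threshold_set()] for segmentation.
#' @param unmix a [unmix_config()].
#' @param zones a [zone_spec()].
#' @param region,radius stratum used for scoring and survival analysis.
#' @param noise_sd optical-density noise for rendering.
#' @param write_images also write per-core PNG/TIFF images (slower,
#'   larger output).
#' @return invisibly, a list with `densities`, `qc`, `pooled`, `scores`,
#'   `associations`, `survival_tests`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, image_stages = FALSE,
                         thresholds = threshold_set(),
                         unmix = unmix_config(), zones = zone_spec(),
                         region = "CT", radius = "25", noise_sd = 0.02,
                         write_images = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- simulate_cohort(config)
  write_table_csv(cohort$clinical, file.path(out_dir, "clinical.csv"))
  write_table_csv(cohort$survival, file.path(out_dir, "survival.csv"))

  dens <- list(); qc <- list()
  for (sc in cohort$scenes) {
    if (image_stages) {
      rb <- render_brightfield(sc, noise_sd = noise_sd)
      conc <- unmix_core(rb$rgb, config = unmix)
      seg <- segment_core(conc, thresholds, sc$pixel_size, sc$panel)
      seg$reference_mask <- if (any(seg$tumour_mask)) seg$tumour_mask
                            else sc$reference_mask
      seg$panel <- sc$panel
      seg$pixel_size <- sc$pixel_size
      if (write_images) {
        base <- sprintf("%s_%s_c%s_p%d", sc$patient_id, sc$region,
                        sc$core_id, sc$panel)
        write_rgb_png(rb$rgb, file.path(out_dir, paste0(base, "_rgb.png")))
        write_channels_tiff(conc, file.path(out_dir,
                                            paste0(base, "_conc.tif")))
        write_mask_png(seg$tumour_mask,
                       file.path(out_dir, paste0(base, "_tumour.png")))
      }
      src <- seg
    } else {
      src <- sc
    }
    q <- core_qc(src)
    q$patient_id <- sc$patient_id; q$core_id <- sc$core_id
    q$region <- sc$region; q$panel <- sc$panel
    qc[[length(qc) + 1L]] <- q
    if (!q$included) next
    d <- quantify_core(src, src$pixel_size, zones)
    if (is.null(d)) next
    d$patient_id <- sc$patient_id; d$core_id <- sc$core_id
    d$region <- sc$region; d$panel <- sc$panel
    dens[[length(dens) + 1L]] <- d
  }
  qc <- do.call(rbind, qc)
  densities <- do.call(rbind, dens)
  write_table_csv(qc, file.path(out_dir, "core_qc.csv"))
  write_table_csv(densities, file.path(out_dir, "densities.csv"))

  pooled <- pool_patient_density(densities)
  write_table_csv(pooled, file.path(out_dir, "pooled_densities.csv"))

  scores <- score_patients(pooled, region = region, radius = radius)
  write_table_csv(scores, file.path(out_dir, "patient_scores.csv"))

  assoc <- run_association_battery(
    scores, cohort$clinical,
    variable_types = c(tnm_stage = "categorical", pT = "categorical",
                       venous_invasion = "categorical",
                       postop_chemo = "categorical"))
  write_table_csv(assoc, file.path(out_dir, "associations.csv"))

  sv <- merge(scores, cohort$survival, by = "patient_id")
  stests <- list()
  for (g in c("cd8_group", "gzmb_group", "cd68_group",
              "combined_gzmb_cd68")) {
    gv <- sv[[g]]
    if (length(unique(gv[!is.na(gv)])) < 2L) next
    ok <- !is.na(gv)
    lr <- log_rank_test(sv$time[ok], sv$event[ok], gv[ok])
    cx <- cox_fit(sv$time[ok], sv$event[ok],
                  data.frame(group = gv[ok]))
    stests[[g]] <- data.frame(group = g, logrank_p = lr$p_value,
                              hr = cx$coefficients$hr[1],
                              hr_p = cx$coefficients$p_value[1])
  }
  survival_tests <- do.call(rbind, stests)
  rownames(survival_tests) <- NULL
  write_table_csv(survival_tests, file.path(out_dir, "survival_tests.csv"))

  files <- sort(list.files(out_dir, pattern = "\\.csv$", full.names = TRUE))
  manifest <- data.frame(file = basename(files), md5 = unname(md5sum(files)),
                         seed = config$seed)
  write_table_csv(manifest, file.path(out_dir, "manifest.csv"))

  invisible(list(densities = densities, qc = qc, pooled = pooled,
                 scores = scores, associations = assoc,
                 survival_tests = survival_tests, manifest = manifest))
}
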