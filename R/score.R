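#' Dichotomize patient densities at the cohort median
#'
#' `high` means strictly greater than the median of the non-missing
#' densities; ties at the median go to `low` (so "high" always means
#' strictly above the median and "low" is its exact complement). Medians
#' are meant to be computed per cohort and per (region, radius) stratum:
#' pass in exactly the densities of one such stratum.
#'
#' @param densities named numeric vector (names = patient ids), `NA`
#'   allowed.
#' @return factor with levels `low`, `high`, named like the input; `NA`
#'   densities give `NA` group.
#' @export
dichotomize_at_median <- function(densities) {
  ok <- !is.na(densities)
  if (sum(ok) < 2L) stop("need at least 2 non-missing densities")
  med <- median(densities[ok])
  grp <- ifelse(is.na(densities), NA_character_,
                ifelse(densities > med, "high", "low"))
  out <- factor(grp, levels = c("low", "high"))
  names(out) <- names(densities)
  out
}

#' Combined GZMB/CD68 group
#'
#' A patient is `high` only when both the GZMB and the CD68 density
#' group are `high`; any other combination is `low`. Missing either
#' group gives `NA`.
#'
#' @param gzmb_group,cd68_group factors/characters with values
#'   `low`/`high`.
#' @return factor with levels `low`, `high`.
#' @export
combine_gzmb_cd68 <- function(gzmb_group, cd68_group) {
  g <- as.character(gzmb_group)
  c68 <- as.character(cd68_group)
  out <- ifelse(is.na(g) | is.na(c68), NA_character_,
                ifelse(g == "high" & c68 == "high", "high", "low"))
  factor(out, levels = c("low", "high"))
}

#' Ratio and difference scores between marker densities
#'
#' The ratios guard against zero densities with the same `+ 1` offset
#' used for the log transform of densities; the difference is a plain
#' subtraction in 1/mm^2.
#'
#' @param gzmb,cd8,cd68,cd163 numeric density vectors (1/mm^2).
#' @return data frame `gzmb_cd8_ratio`, `cd68_cd163_ratio`,
#'   `cd68_minus_cd163`.
#' @export
ratio_scores <- function(gzmb, cd8, cd68, cd163) {
  data.frame(gzmb_cd8_ratio = (gzmb + 1) / (cd8 + 1),
             cd68_cd163_ratio = (cd68 + 1) / (cd163 + 1),
             cd68_minus_cd163 = cd68 - cd163)
}

#' Patient-level marker groups and combined score for one stratum
#'
#' Selects one (region, radius) stratum from pooled patient densities,
#' dichotomizes every marker at the cohort median, and derives the
#' combined GZMB/CD68 group plus ratio scores.
#'
#' @param pooled output of [pool_patient_density()] for one cohort.
#' @param region tissue region of the stratum (default `"CT"`).
#' @param radius zone radius label (default `"25"`, the TP25um zone).
#' @return data frame with one row per patient: `patient_id`, per-marker
#'   density and group columns, `combined_gzmb_cd68`, ratio scores.
#' @export
score_patients <- function(pooled, region = "CT", radius = "25") {
  sub <- pooled[pooled$region == region & pooled$radius == radius, ]
  if (nrow(sub) == 0L) stop("no densities for region ", region,
                            " radius ", radius)
  pts <- sort(unique(sub$patient_id))
  dens <- sapply(c("CD8", "GZMB", "CD68", "CD163"), function(m) {
    d <- setNames(rep(NA_real_, length(pts)), pts)
    rows <- sub[sub$marker == m, ]
    d[rows$patient_id] <- rows$density_per_mm2
    d
  })
  out <- data.frame(patient_id = pts, region = region, radius = radius)
  for (m in colnames(dens)) {
    out[[paste0(tolower(m), "_density")]] <- dens[, m]
    out[[paste0(tolower(m), "_group")]] <-
      if (sum(!is.na(dens[, m])) >= 2L) dichotomize_at_median(dens[, m])
      else factor(rep(NA_character_, length(pts)), levels = c("low", "high"))
  }
  out$combined_gzmb_cd68 <- combine_gzmb_cd68(out$gzmb_group,
                                              out$cd68_group)
  out <- cbind(out, ratio_scores(dens[, "GZMB"], dens[, "CD8"],
                                 dens[, "CD68"], dens[, "CD163"]))
  rownames(out) <- NULL
  out
}
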