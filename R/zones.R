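#' Tumour-proximity zone specification
#'
#' Zones are cumulative discs around the tumour: the stroma within
#' distance r of tumour for r in `radii` (default 10, 25, 50, 100 um),
#' plus the unrestricted total stroma area.
#'
#' @param radii strictly increasing positive radii in micrometres.
#' @return list of class `zone_spec`; `$levels` holds the radius labels
#'   (`"10"`, ..., `"total"`).
#' @export
zone_spec <- function(radii = c(10, 25, 50, 100)) {
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("`radii` must be positive and strictly increasing")
  structure(list(radii = radii,
                 levels = c(as.character(radii), "total")),
            class = "zone_spec")
}

#' Euclidean distance (um) to the nearest tumour pixel
#'
#' Inside the tumour the distance is 0. For cores without tumour (normal
#' epithelium region) the distances are measured from the epithelium
#' reference mask instead; if both masks are empty the zones cannot be
#' computed and `NULL` is returned with a warning.
#'
#' @param tumour_mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param reference_mask fallback mask when `tumour_mask` is empty.
#' @return numeric matrix of distances in micrometres, or `NULL`.
#' @export
tumour_distance_map <- function(tumour_mask, pixel_size,
                                reference_mask = NULL) {
  src <- tumour_mask
  if (!any(src) && !is.null(reference_mask)) src <- reference_mask
  if (!any(src)) {
    warning("no tumour or reference pixels; zone computation skipped")
    return(NULL)
  }
  # distance of each non-source pixel to the nearest source pixel
  dm <- EBImage::distmap(EBImage::Image((!src) * 1), metric = "euclidean")
  as.matrix(EBImage::imageData(dm)) * pixel_size
}

#' Binary mask of one tumour-proximity zone
#'
#' Stroma pixels with `0 < distance <= radius`; `radius = "total"` (or
#' infinite) selects the whole stroma area.
#'
#' @param distance_um distance raster from [tumour_distance_map()].
#' @param stroma_mask logical matrix.
#' @param radius numeric radius in micrometres, or `"total"`.
#' @return logical matrix.
#' @export
zone_mask <- function(distance_um, stroma_mask, radius) {
  if (identical(radius, "total") || (is.numeric(radius) && is.infinite(radius)))
    return(stroma_mask)
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be positive or \"total\"")
  stroma_mask & distance_um > 0 & distance_um <= radius
}

#' Pixel index of cell centroids
#'
#' Half-open membership: a centroid in micrometre coordinates (origin
#' top-left, x rightward, y downward) belongs to the pixel whose
#' half-open square contains it, so boundary points are never counted
#' twice.
#'
#' @param x_um,y_um centroid coordinates in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param dims raster dimensions (x, y).
#' @return two-column integer index matrix usable for matrix indexing.
#' @export
cell_pixel_index <- function(x_um, y_um, pixel_size, dims) {
  ix <- pmin(dims[1], pmax(1L, floor(x_um / pixel_size) + 1L))
  iy <- pmin(dims[2], pmax(1L, floor(y_um / pixel_size) + 1L))
  cbind(ix, iy)
}

#' Marker cell density within one zone
#'
#' Counts stromal cells of the given marker phenotype whose nucleus
#' centroid falls on a zone pixel; the density is the count over the zone
#' area (pixel count times pixel area).
#'
#' @param cells classified cell table (`x_um`, `y_um`, `compartment`,
#'   `phenotype`).
#' @param zmask zone mask from [zone_mask()].
#' @param marker phenotype to count (`"CD8"`, `"GZMB"`, `"CD68"`,
#'   `"CD163"`).
#' @param pixel_size micrometres per pixel.
#' @return one-row data frame `marker`, `cell_count`, `zone_area_mm2`,
#'   `density_per_mm2` (density `NA` when the zone is empty).
#' @export
zone_density <- function(cells, zmask, marker, pixel_size) {
  area <- sum(zmask) * pixel_size^2 / 1e6
  sel <- cells$compartment == "stroma" & cells$phenotype == marker
  count <- 0L
  if (any(sel)) {
    idx <- cell_pixel_index(cells$x_um[sel], cells$y_um[sel], pixel_size,
                            dim(zmask))
    count <- sum(zmask[idx])
  }
  data.frame(marker = marker, cell_count = count, zone_area_mm2 = area,
             density_per_mm2 = if (area > 0) count / area else NA_real_)
}

#' Quantify zone densities for one segmented core
#'
#' Computes, for every marker of the core's panel and every zone radius
#' (plus total stroma), the stromal cell count, zone area and density.
#'
#' @param scene_or_masks either a `core_scene` or a list with
#'   `tumour_mask`, `stroma_mask`, optional `reference_mask`, and `cells`.
#' @param pixel_size micrometres per pixel (taken from the scene when
#'   present).
#' @param zones a [zone_spec()].
#' @param markers marker phenotypes to quantify; defaults to the panel's
#'   markers when a scene is given, else all four.
#' @return long data frame: `marker`, `radius` (character, `"10"` ...
#'   `"total"`), `cell_count`, `zone_area_mm2`, `density_per_mm2`.
#' @export
quantify_core <- function(scene_or_masks, pixel_size = NULL,
                          zones = zone_spec(), markers = NULL) {
  x <- scene_or_masks
  if (is.null(pixel_size)) pixel_size <- x$pixel_size
  if (is.null(pixel_size)) stop("`pixel_size` is required")
  if (is.null(markers)) {
    markers <- if (!is.null(x$panel)) names(panel_stains(x$panel)$markers)
    else c("CD8", "GZMB", "CD68", "CD163")
  }
  dist <- tumour_distance_map(x$tumour_mask, pixel_size, x$reference_mask)
  if (is.null(dist)) return(NULL)
  out <- list()
  for (r in zones$levels) {
    rad <- if (r == "total") "total" else as.numeric(r)
    zm <- zone_mask(dist, x$stroma_mask, rad)
    for (m in markers) {
      zd <- zone_density(x$cells, zm, m, pixel_size)
      zd$radius <- r
      out[[length(out) + 1L]] <- zd
    }
  }
  out <- do.call(rbind, out)
  out[, c("marker", "radius", "cell_count", "zone_area_mm2",
          "density_per_mm2")]
}

#' Core-level quality control
#'
#' A core enters downstream analysis only if more than 10 cells were
#' detected in the stroma and the tumour area exceeds 1 percent of the
#' tissue area (both strict inequalities).
#'
#' @param stromal_cell_count number of stromal cells detected.
#' @param tumour_area_fraction tumour area over tissue area.
#' @return data frame `stromal_cell_count`, `tumour_area_fraction`,
#'   `included`, `reason`.
#' @export
apply_core_qc <- function(stromal_cell_count, tumour_area_fraction) {
  ok_cells <- stromal_cell_count > 10
  ok_tum <- tumour_area_fraction > 0.01
  reason <- ifelse(ok_cells & ok_tum, "",
                   trimws(paste(ifelse(ok_cells, "", "<=10 stromal cells"),
                                ifelse(ok_tum, "", "tumour area <=1%"))))
  data.frame(stromal_cell_count = stromal_cell_count,
             tumour_area_fraction = tumour_area_fraction,
             included = ok_cells & ok_tum, reason = reason)
}

#' QC result for a scene or segmentation result
#'
#' @param x a `core_scene` or [segment_core()] result.
#' @return as [apply_core_qc()].
#' @export
core_qc <- function(x) {
  n_stroma <- sum(x$cells$compartment == "stroma")
  tis <- max(1L, sum(x$tissue_mask))
  apply_core_qc(n_stroma, sum(x$tumour_mask) / tis)
}

#' Pool core densities to a patient-level weighted mean
#'
#' Area-weighted mean density per (patient, region, marker, radius):
#' pooled counts over pooled areas, which keeps pooling consistent with
#' merging the cores into one larger core.
#'
#' @param densities long data frame of per-core zone densities with at
#'   least `patient_id`, `region`, `marker`, `radius`, `cell_count`,
#'   `zone_area_mm2` (e.g. rows of [quantify_core()] results annotated
#'   with core identifiers); include only QC-passing cores.
#' @return data frame `patient_id`, `region`, `marker`, `radius`,
#'   `cell_count`, `zone_area_mm2`, `density_per_mm2`.
#' @export
pool_patient_density <- function(densities) {
  req <- c("patient_id", "region", "marker", "radius", "cell_count",
           "zone_area_mm2")
  if (!all(req %in% names(densities)))
    stop("missing columns: ", paste(setdiff(req, names(densities)),
                                    collapse = ", "))
  key <- interaction(densities$patient_id, densities$region,
                     densities$marker, densities$radius, drop = TRUE)
  counts <- tapply(densities$cell_count, key, sum)
  areas <- tapply(densities$zone_area_mm2, key, sum)
  first <- !duplicated(key)
  out <- densities[first, c("patient_id", "region", "marker", "radius")]
  k <- as.character(key[first])
  out$cell_count <- as.numeric(counts[k])
  out$zone_area_mm2 <- as.numeric(areas[k])
  out$density_per_mm2 <- ifelse(out$zone_area_mm2 > 0,
                                out$cell_count / out$zone_area_mm2, NA_real_)
  rownames(out) <- NULL
  out
}
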