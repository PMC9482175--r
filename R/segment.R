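#' Channel-intensity thresholds for segmentation and cell classification
#'
#' The segmentation stage is threshold-driven, mirroring a manually tuned
#' digital-pathology workflow: thresholds for tissue detection,
#' tumour-stroma differentiation (PanCK), watershed nucleus detection and
#' per-marker positivity. Cohorts stained in different runs need separate
#' threshold sets (overall stain intensity differs between runs), so keep
#' one `threshold_set` per cohort.
#'
#' @param tissue_od_min minimum summed stain concentration for tissue.
#' @param panck_min minimum PanCK-channel concentration for tumour.
#' @param nucleus_od_min minimum haematoxylin concentration for a nucleus.
#' @param cd8_min,cd68_min,gzmb_min,cd163_min marker positivity thresholds
#'   on mean per-cell concentration.
#' @param min_nucleus_area,max_nucleus_area accepted nucleus area, um^2.
#' @param watershed_tolerance intensity tolerance (in distance-map pixels)
#'   for splitting touching nuclei.
#' @return list of class `threshold_set`.
#' @export
threshold_set <- function(tissue_od_min = 0.05, panck_min = 0.3,
                          nucleus_od_min = 0.25,
                          cd8_min = 0.2, cd68_min = 0.2,
                          gzmb_min = 0.2, cd163_min = 0.2,
                          min_nucleus_area = 8, max_nucleus_area = 200,
                          watershed_tolerance = 1) {
  th <- list(tissue_od_min = tissue_od_min, panck_min = panck_min,
             nucleus_od_min = nucleus_od_min,
             cd8_min = cd8_min, cd68_min = cd68_min,
             gzmb_min = gzmb_min, cd163_min = cd163_min,
             min_nucleus_area = min_nucleus_area,
             max_nucleus_area = max_nucleus_area,
             watershed_tolerance = watershed_tolerance)
  if (any(unlist(th) < 0)) stop("thresholds must be >= 0")
  if (min_nucleus_area >= max_nucleus_area)
    stop("`min_nucleus_area` must be smaller than `max_nucleus_area`")
  class(th) <- "threshold_set"
  th
}

disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * max(1L, round(radius_px)) + 1L, shape = "disc")
}

#' Detect tissue from a 4-channel concentration image
#'
#' Tissue is where the summed stain concentration reaches
#' `tissue_od_min`; the mask is morphologically closed with a 5 um disc
#' and hole-filled.
#'
#' @param channels x-by-y-by-4 concentration array (see [unmix_core()]).
#' @param thresholds a [threshold_set()].
#' @param pixel_size micrometres per pixel.
#' @return logical matrix.
#' @export
detect_tissue <- function(channels, thresholds = threshold_set(),
                          pixel_size = 0.25) {
  total <- rowSums(channels, dims = 2L)
  mask <- total >= thresholds$tissue_od_min
  if (!any(mask)) return(mask)
  img <- EBImage::Image(mask * 1)
  img <- EBImage::closing(img, disc_brush(5 / pixel_size))
  img <- EBImage::fillHull(img)
  as.matrix(img) > 0.5
}

#' Split tissue into tumour and stroma by the PanCK channel
#'
#' Tumour is PanCK concentration at or above `panck_min` within tissue,
#' closed with a 10 um disc to merge adjacent glands; stroma is the
#' remaining tissue. The PanCK chromogen differs between staining panels
#' (DAB in panel 1, fast red in panel 2).
#'
#' @inheritParams detect_tissue
#' @param tissue_mask logical matrix from [detect_tissue()].
#' @param panel staining panel (1 or 2), selects the PanCK channel.
#' @return list with disjoint logical matrices `tumour_mask` and
#'   `stroma_mask`, both subsets of `tissue_mask`.
#' @export
split_tumour_stroma <- function(channels, tissue_mask,
                                thresholds = threshold_set(),
                                pixel_size = 0.25, panel = 1L) {
  panck <- channels[, , panel_stains(panel)$panck]
  tum <- panck >= thresholds$panck_min & tissue_mask
  if (any(tum)) {
    img <- EBImage::closing(EBImage::Image(tum * 1),
                            disc_brush(10 / pixel_size))
    tum <- (as.matrix(img) > 0.5) & tissue_mask
  }
  list(tumour_mask = tum, stroma_mask = tissue_mask & !tum)
}

#' Detect cell nuclei by marker-controlled watershed
#'
#' Smooths the haematoxylin channel (Gaussian, sigma 1 um), thresholds
#' nuclei, computes the Euclidean distance transform and applies a
#' watershed to split touching nuclei; objects outside the configured
#' area range are discarded.
#'
#' @inheritParams detect_tissue
#' @param haematoxylin haematoxylin concentration matrix.
#' @param tissue_mask restrict detection to tissue (optional).
#' @return data frame with `label`, `x_um`, `y_um`, `area_um2`; the
#'   watershed label image is attached as attribute `labels` (a matrix,
#'   0 = background).
#' @export
detect_cells_watershed <- function(haematoxylin, tissue_mask = NULL,
                                   thresholds = threshold_set(),
                                   pixel_size = 0.25) {
  stopifnot(all(is.finite(haematoxylin)))
  empty <- data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0))
  sm <- as.matrix(EBImage::gblur(haematoxylin,
                                 sigma = max(0.5, 1 / pixel_size)))
  mask <- sm >= thresholds$nucleus_od_min
  if (!is.null(tissue_mask)) mask <- mask & tissue_mask
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(haematoxylin),
                                    ncol(haematoxylin))
    return(empty)
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(dm, tolerance = thresholds$watershed_tolerance,
                               ext = max(1L, round(2 / pixel_size)))
  lab <- as.matrix(EBImage::imageData(labels))
  mom <- EBImage::computeFeatures.moment(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1,
                                       dimnames = list(NULL, names(shp)))
  area <- shp[, "s.area"] * pixel_size^2
  keep <- area >= thresholds$min_nucleus_area &
    area <= thresholds$max_nucleus_area
  cells <- data.frame(label = seq_len(nrow(mom))[keep],
                      x_um = (mom[keep, "m.cx"] - 0.5) * pixel_size,
                      y_um = (mom[keep, "m.cy"] - 0.5) * pixel_size,
                      area_um2 = area[keep])
  rownames(cells) <- NULL
  attr(cells, "labels") <- lab
  cells
}

marker_thresholds <- function(thresholds, panel) {
  if (panel == 1L)
    c(CD8 = thresholds$cd8_min, CD68 = thresholds$cd68_min)
  else c(GZMB = thresholds$gzmb_min, CD163 = thresholds$cd163_min)
}

# mean channel concentration in a disc of radius `radius_um` around each
# centroid
disc_mean_intensity <- function(channel, x_um, y_um, pixel_size, radius_um) {
  h <- max(1L, ceiling(radius_um / pixel_size))
  offs <- expand.grid(dx = -h:h, dy = -h:h)
  offs <- offs[offs$dx^2 + offs$dy^2 <= (radius_um / pixel_size)^2, ]
  nx <- nrow(channel); ny <- ncol(channel)
  ix <- floor(x_um / pixel_size) + 1L
  iy <- floor(y_um / pixel_size) + 1L
  out <- numeric(length(x_um))
  for (i in seq_along(x_um)) {
    px <- ix[i] + offs$dx
    py <- iy[i] + offs$dy
    ok <- px >= 1L & px <= nx & py >= 1L & py <= ny
    out[i] <- mean(channel[cbind(px[ok], py[ok])])
  }
  out
}

#' Assign compartment and marker phenotype to detected cells
#'
#' Compartment is decided by the nucleus centroid: inside the tumour mask
#' the cell is tumour, otherwise stroma. Stromal cells are classified by
#' comparing the mean marker concentration in a 3 um disc around the
#' centroid against the panel's positivity thresholds: one marker above
#' its threshold gives that phenotype, both above give the marker with the
#' larger threshold-normalized intensity, neither gives `double_negative`.
#'
#' @inheritParams detect_tissue
#' @param cells data frame from [detect_cells_watershed()].
#' @param tumour_mask logical matrix.
#' @param panel staining panel, 1 (CD8/CD68) or 2 (GZMB/CD163).
#' @return `cells` with `compartment` and `phenotype` columns added (the
#'   `labels` attribute is preserved).
#' @export
classify_cells <- function(cells, channels, tumour_mask,
                           thresholds = threshold_set(),
                           pixel_size = 0.25, panel = 1L) {
  if (!panel %in% c(1L, 2L)) stop("`panel` must be 1 or 2")
  labs <- attr(cells, "labels")
  n <- nrow(cells)
  if (n == 0L) {
    cells$compartment <- character(0)
    cells$phenotype <- character(0)
    attr(cells, "labels") <- labs
    return(cells)
  }
  ix <- pmin(nrow(tumour_mask), pmax(1L, floor(cells$x_um / pixel_size) + 1L))
  iy <- pmin(ncol(tumour_mask), pmax(1L, floor(cells$y_um / pixel_size) + 1L))
  in_tum <- tumour_mask[cbind(ix, iy)]
  cells$compartment <- ifelse(in_tum, "tumour", "stroma")
  cells$phenotype <- ifelse(in_tum, "tumour", "double_negative")

  ths <- marker_thresholds(thresholds, panel)
  ps <- panel_stains(panel)
  stromal <- which(!in_tum)
  if (length(stromal) > 0L) {
    score <- sapply(names(ths), function(m) {
      ch <- channels[, , ps$markers[[m]]]
      disc_mean_intensity(ch, cells$x_um[stromal], cells$y_um[stromal],
                          pixel_size, 3) / ths[[m]]
    })
    if (is.null(dim(score))) score <- matrix(score, nrow = 1,
                                             dimnames = list(NULL, names(ths)))
    pos <- score >= 1
    pick <- names(ths)[max.col(score, ties.method = "first")]
    phen <- ifelse(rowSums(pos) == 0L, "double_negative", pick)
    cells$phenotype[stromal] <- phen
  }
  attr(cells, "labels") <- labs
  cells
}

# per-object solidity: object area over convex hull area
object_solidity <- function(labels, label_ids) {
  out <- setNames(rep(NA_real_, length(label_ids)), label_ids)
  px <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[px]
  for (i in seq_along(label_ids)) {
    p <- px[lab == label_ids[i], , drop = FALSE]
    if (nrow(p) < 3L) { out[i] <- 1; next }
    h <- chull(p)
    hp <- p[h, , drop = FALSE]
    # shoelace area of the hull polygon, plus half the perimeter pixels
    xs <- hp[, 1]; ys <- hp[, 2]
    hull_area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    out[i] <- min(1, nrow(p) / max(hull_area, nrow(p)))
  }
  out
}

#' Rule-based artefact exclusion
#'
#' Removes detected objects that are saturated in three or more stain
#' channels (pigment, debris) or whose nucleus solidity falls below 0.5
#' (folds, scratch edges). A deterministic stand-in for supervised
#' artefact classification, sufficient to discard gross non-cellular
#' objects.
#'
#' @inheritParams detect_tissue
#' @param cells classified cells (with `labels` attribute).
#' @param saturation_od concentration treated as saturated.
#' @return filtered cells data frame; removed rows are reported in the
#'   `excluded` attribute.
#' @export
exclude_artefacts <- function(cells, channels, saturation_od = 2,
                              min_solidity = 0.5) {
  labs <- attr(cells, "labels")
  if (nrow(cells) == 0L) return(cells)
  n_sat <- rep(0L, nrow(cells))
  for (s in seq_len(dim(channels)[3])) {
    ch <- channels[, , s]
    sat_px <- ch >= saturation_od
    if (!any(sat_px)) next
    sat_labels <- unique(labs[sat_px & labs > 0L])
    n_sat <- n_sat + as.integer(cells$label %in% sat_labels)
  }
  sol <- object_solidity(labs, cells$label)
  drop <- n_sat >= 3L | sol < min_solidity
  out <- cells[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- labs
  attr(out, "excluded") <- cells[drop, , drop = FALSE]
  out
}

#' Segment one unmixed core image
#'
#' Convenience wrapper running tissue detection, tumour-stroma split,
#' watershed cell detection, classification and artefact exclusion.
#'
#' @inheritParams detect_tissue
#' @param panel staining panel (1 or 2).
#' @return list with `tissue_mask`, `tumour_mask`, `stroma_mask`, `cells`.
#' @export
segment_core <- function(channels, thresholds = threshold_set(),
                         pixel_size = 0.25, panel = 1L) {
  tissue <- detect_tissue(channels, thresholds, pixel_size)
  ts <- split_tumour_stroma(channels, tissue, thresholds, pixel_size, panel)
  cells <- detect_cells_watershed(channels[, , "haematoxylin"], tissue,
                                  thresholds, pixel_size)
  cells <- classify_cells(cells, channels, ts$tumour_mask, thresholds,
                          pixel_size, panel)
  cells <- exclude_artefacts(cells, channels)
  list(tissue_mask = tissue, tumour_mask = ts$tumour_mask,
       stroma_mask = ts$stroma_mask, cells = cells)
}
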