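# build a bare scene with cells at given positions (stroma, no tumour)
manual_scene <- function(xy, phenotype = "double_negative", n = 100,
                         px = 1, panel = 1L) {
  cells <- data.frame(x_um = xy[, 1], y_um = xy[, 2],
                      compartment = "stroma", phenotype = phenotype)
  for (ch in c("haematoxylin", "dab", "fast_red", "perma_green"))
    cells[[paste0("int_", ch)]] <- 0
  cells$int_haematoxylin <- 0.7
  tissue <- matrix(TRUE, n, n)
  structure(list(patient_id = "T", core_id = 1L, region = "CT",
                 panel = panel, pixel_size = px, dim = c(n, n),
                 tissue_mask = tissue,
                 tumour_mask = matrix(FALSE, n, n),
                 stroma_mask = tissue,
                 reference_mask = matrix(FALSE, n, n), cells = cells),
            class = "core_scene")
}

test_that("threshold sets are validated", {
  expect_s3_class(threshold_set(), "threshold_set")
  expect_error(threshold_set(min_nucleus_area = 300), "smaller")
  expect_error(threshold_set(panck_min = -1), ">= 0")
})

test_that("tissue detection finds nothing on blank and all on uniform", {
  blank <- array(0, c(20, 20, 4))
  expect_false(any(detect_tissue(blank, pixel_size = 1)))
  uniform <- array(0.2, c(20, 20, 4))
  expect_true(all(detect_tissue(uniform, pixel_size = 1)))
})

test_that("tissue mask area matches the generated disc within 5%", {
  fx <- seg_fixture()
  expect_lt(abs(sum(fx$seg$tissue_mask) / sum(fx$scene$tissue_mask) - 1),
            0.05)
})

test_that("tumour-stroma split follows the PanCK channel", {
  ch <- array(0, c(20, 20, 4))
  dimnames(ch) <- list(NULL, NULL, c("haematoxylin", "dab", "fast_red",
                                     "perma_green"))
  tissue <- matrix(TRUE, 20, 20)
  ts <- split_tumour_stroma(ch, tissue, pixel_size = 1, panel = 1)
  expect_false(any(ts$tumour_mask))
  expect_true(all(ts$stroma_mask == tissue))
  ch[, , "dab"] <- 1
  ts2 <- split_tumour_stroma(ch, tissue, pixel_size = 1, panel = 1)
  expect_true(all(ts2$tumour_mask == tissue))
  expect_false(any(ts2$stroma_mask))
})

test_that("segmented tumour mask overlaps ground truth (Jaccard >= 0.8)", {
  fx <- seg_fixture()
  jac <- sum(fx$seg$tumour_mask & fx$scene$tumour_mask) /
    sum(fx$seg$tumour_mask | fx$scene$tumour_mask)
  expect_gte(jac, 0.8)
  # masks partition tissue
  expect_false(any(fx$seg$tumour_mask & fx$seg$stroma_mask))
  expect_true(all(fx$seg$tissue_mask[fx$seg$tumour_mask]))
})

test_that("watershed detects none on blank and splits nearby nuclei", {
  blank <- matrix(0, 50, 50)
  cells <- detect_cells_watershed(blank, pixel_size = 1)
  expect_equal(nrow(cells), 0)
  # at the scanner's native resolution the distance-map saddle between
  # touching nuclei is resolved and the watershed separates them
  th <- threshold_set(watershed_tolerance = 0.5)
  for (sep in c(12, 6)) {
    sc <- manual_scene(rbind(c(40, 50), c(40 + sep, 50)), n = 200, px = 0.5)
    rb <- render_brightfield(sc, noise_sd = 0, bg_haematoxylin = 0)
    det <- detect_cells_watershed(rb$concentrations[, , "haematoxylin"],
                                  thresholds = th, pixel_size = 0.5)
    expect_equal(nrow(det), 2)
  }
})

test_that("objects outside the nucleus area range are discarded", {
  sc <- manual_scene(cbind(50, 50))
  rb <- render_brightfield(sc, noise_sd = 0, bg_haematoxylin = 0)
  hx <- rb$concentrations[, , "haematoxylin"]
  keep <- detect_cells_watershed(hx, pixel_size = 1)
  expect_equal(nrow(keep), 1)
  small <- detect_cells_watershed(hx, pixel_size = 1,
                                  thresholds = threshold_set(
                                    min_nucleus_area = 8,
                                    max_nucleus_area = 10))
  expect_equal(nrow(small), 0)
})

test_that("classification assigns compartment and phenotype by thresholds", {
  ch <- array(0, c(40, 40, 4))
  dimnames(ch) <- list(NULL, NULL, c("haematoxylin", "dab", "fast_red",
                                     "perma_green"))
  tum <- matrix(FALSE, 40, 40); tum[30:40, ] <- TRUE
  cells <- data.frame(label = 1:3, x_um = c(10, 10, 35), y_um = c(10, 30, 20),
                      area_um2 = 50)
  ch[5:15, 5:15, "fast_red"] <- 0.5        # CD8 signal around cell 1
  out <- classify_cells(cells, ch, tum, pixel_size = 1, panel = 1)
  expect_equal(out$compartment, c("stroma", "stroma", "tumour"))
  expect_equal(out$phenotype, c("CD8", "double_negative", "tumour"))
  expect_error(classify_cells(cells, ch, tum, pixel_size = 1, panel = 3),
               "panel")
  # double positive resolved by threshold-normalized maximum
  ch[5:15, 25:35, "fast_red"] <- 0.3
  ch[5:15, 25:35, "perma_green"] <- 0.6
  out2 <- classify_cells(cells, ch, tum, pixel_size = 1, panel = 1)
  expect_equal(out2$phenotype[2], "CD68")
})

test_that("every cell gets exactly one phenotype of its panel", {
  fx <- seg_fixture()
  expect_true(all(fx$seg$cells$phenotype %in%
                    c("tumour", "CD8", "CD68", "double_negative")))
  expect_true(all(fx$seg$cells$compartment[fx$seg$cells$phenotype ==
                                             "tumour"] == "tumour"))
})

test_that("artefact exclusion removes planted saturated blobs only", {
  fx <- seg_fixture()
  # clean scene: nothing removed
  clean <- exclude_artefacts(fx$seg$cells, fx$conc)
  expect_equal(nrow(clean), nrow(fx$seg$cells))
  # empty list passes through
  empty <- fx$seg$cells[0, ]
  attr(empty, "labels") <- attr(fx$seg$cells, "labels")
  expect_equal(nrow(exclude_artefacts(empty, fx$conc)), 0)
  # plant a blob saturated in 3 channels over one detected cell
  cells <- fx$seg$cells
  conc <- fx$conc
  i <- which(cells$compartment == "stroma")[1]
  ix <- round(cells$x_um[i]); iy <- round(cells$y_um[i])
  for (ch in 1:3) conc[(ix - 2):(ix + 2), (iy - 2):(iy + 2), ch] <- 3
  kept <- exclude_artefacts(cells, conc)
  expect_equal(nrow(kept), nrow(cells) - 1)
  expect_false(cells$label[i] %in% kept$label)
})

test_that("stromal counts and phenotypes recover the generated truth", {
  fx <- seg_fixture()
  truth <- fx$scene$cells
  det <- fx$seg$cells
  n_true <- sum(truth$compartment == "stroma")
  n_det <- sum(det$compartment == "stroma")
  expect_lt(abs(n_det / n_true - 1), 0.1)
  # phenotype confusion < 5%: match each detected stromal cell to the
  # nearest generated cell
  ds <- det[det$compartment == "stroma", ]
  wrong <- 0
  for (i in seq_len(nrow(ds))) {
    d2 <- (truth$x_um - ds$x_um[i])^2 + (truth$y_um - ds$y_um[i])^2
    j <- which.min(d2)
    if (truth$phenotype[j] != ds$phenotype[i]) wrong <- wrong + 1
  }
  expect_lt(wrong / nrow(ds), 0.05)
})
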