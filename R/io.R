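#' @title File formats
#' @description Readers and writers for the pipeline's table and image
#'   dialects: cells CSV (comma-separated, UTF-8, header row, coordinates
#'   in micrometres), binary mask PNG (0/255), RGB PNG (8-bit), and
#'   multichannel 32-bit float TIFF for concentration images. All writers
#'   round-trip: `read(write(x))` recovers `x` (to float precision for
#'   images).
#' @name formats
NULL

#' Write / read a cells table
#'
#' @param cells data frame with at least `x_um`, `y_um`, `compartment`,
#'   `phenotype` (identifier and intensity columns are preserved).
#' @param path CSV path.
#' @return `read_cells_csv` returns the data frame (empty files with a
#'   header give an empty table).
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a binary mask as PNG
#'
#' Masks are stored 8-bit with 0 = background, 255 = mask.
#'
#' @param mask logical matrix indexed x-by-y.
#' @param path PNG path.
#' @return `read_mask_png` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(t(mask) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  t(x > 0.5)
}

#' Write / read an RGB brightfield image as 8-bit PNG
#'
#' Continuous intensities in `[0, I0]` are scaled to `[0, 1]` and
#' quantized to 8 bits on write.
#'
#' @param rgb x-by-y-by-3 array of intensities.
#' @param path PNG path.
#' @param I0 background intensity.
#' @return `read_rgb_png` returns an x-by-y-by-3 array on the `[0, I0]`
#'   scale.
#' @export
write_rgb_png <- function(rgb, path, I0 = 255) {
  png::writePNG(aperm(rgb, c(2, 1, 3)) / I0, path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path, I0 = 255) {
  aperm(png::readPNG(path), c(2, 1, 3)) * I0
}

#' Write / read a multichannel concentration image as 32-bit float TIFF
#'
#' One TIFF directory per channel; channel names are restored on read
#' (stored in order haematoxylin, DAB, fast red, PermaGreen). Values are
#' stored on a fixed `[0, 1]` scale (concentration / `conc_scale`)
#' because TIFF float samples are defined on the unit interval.
#'
#' @param channels x-by-y-by-k array.
#' @param path TIFF path.
#' @param conc_scale fixed full-scale concentration used for storage.
#' @return `read_channels_tiff` returns the array with channel names.
#' @export
write_channels_tiff <- function(channels, path, conc_scale = 16) {
  if (max(channels) > conc_scale)
    stop("concentrations exceed the fixed storage scale of ", conc_scale)
  planes <- lapply(seq_len(dim(channels)[3]),
                   function(k) t(channels[, , k]) / conc_scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_channels_tiff
#' @export
read_channels_tiff <- function(path, conc_scale = 16) {
  planes <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(planes[[1]])[2], dim(planes[[1]])[1],
                    length(planes)))
  for (k in seq_along(planes)) arr[, , k] <- t(planes[[k]]) * conc_scale
  if (dim(arr)[3] == 4L) dimnames(arr) <- list(NULL, NULL,
                                               stain_channel_names())
  arr
}

#' Write / read generic result tables
#'
#' Plain CSV with header; numeric precision is full double precision.
#'
#' @param x data frame.
#' @param path CSV path.
#' @return `read_table_csv` returns the data frame.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
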