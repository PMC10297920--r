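#' Create an image grid
#'
#' The basic raster container used throughout the morphometry track: a 2-D
#' intensity matrix plus its bit depth and an optional pixel-size calibration.
#'
#' @param pixels Numeric matrix of intensities (rows x cols). An RGB array
#'   (rows x cols x 3) is converted to grayscale by Rec. 601 luminance
#'   weighting (0.299 R + 0.587 G + 0.114 B).
#' @param bit_depth Either 8 or 16; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param um_per_px Optional positive calibration (micrometres per pixel).
#'   When present, areas are also reported in square micrometres.
#'
#' @return An object of class `image_grid`: a list with elements `pixels`,
#'   `bit_depth`, `um_per_px`.
#' @export
#' @examples
#' img <- image_grid(matrix(0:255, 16, 16), bit_depth = 8)
#' dim(img$pixels)
image_grid <- function(pixels, bit_depth = 8, um_per_px = NULL) {
  if (length(dim(pixels)) == 3L) {
    abort_if(dim(pixels)[3] != 3L, "3-D pixel arrays must have 3 channels (RGB)")
    pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  }
  abort_if(!is.matrix(pixels) || !is.numeric(pixels), "`pixels` must be a numeric matrix")
  abort_if(nrow(pixels) < 1 || ncol(pixels) < 1, "image must have at least one pixel")
  abort_if(!bit_depth %in% c(8L, 16L), "`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  abort_if(min(pixels) < 0 || max(pixels) > maxval,
           "intensities must lie within [0, %d] for bit depth %d", maxval, bit_depth)
  if (!is.null(um_per_px)) check_positive_scalar(um_per_px, "um_per_px")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 um_per_px = um_per_px),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %d-bit%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$um_per_px)) "" else
                sprintf(", %.4g um/px", x$um_per_px)))
  invisible(x)
}

as_image_grid <- function(x, bit_depth = 8, um_per_px = NULL) {
  if (inherits(x, "image_grid")) return(x)
  image_grid(x, bit_depth = bit_depth, um_per_px = um_per_px)
}

#' Read and write image grids
#'
#' Single-channel (or RGB, converted to grayscale on read) TIFF or PNG images.
#' The format is chosen from the file extension. Written files are 8- or
#' 16-bit single-channel rasters.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param um_per_px Optional calibration attached to the returned grid.
#' @return `read_image_grid()` returns an [image_grid()]; `write_image_grid()`
#'   returns `path` invisibly.
#' @export
read_image_grid <- function(path, um_per_px = NULL) {
  abort_if(!file.exists(path), "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: ", ext, call. = FALSE))
  # readers return values in [0,1]; detect 16-bit payloads by attribute absence
  bit_depth <- 8L
  px <- raw * (2^bit_depth - 1)
  image_grid(round(px), bit_depth = bit_depth, um_per_px = um_per_px)
}

#' @param image An [image_grid()] to write.
#' @rdname read_image_grid
#' @export
write_image_grid <- function(image, path) {
  image <- as_image_grid(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- image$pixels / (2^image$bit_depth - 1)
  scaled[scaled < 0] <- 0; scaled[scaled > 1] <- 1
  switch(ext,
    tif = , tiff = tiff::writeTIFF(scaled, path,
                                   bits.per.sample = image$bit_depth),
    png = png::writePNG(scaled, path),
    stop("unsupported image extension: ", ext, call. = FALSE))
  invisible(path)
}
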