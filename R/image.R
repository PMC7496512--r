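#' Construct a STEM image object
#'
#' A `stem_image` holds a 2-D grayscale raster together with its physical
#' pixel size. Intensities are normalized gray levels in `[0, 1]`-ish units
#' (values slightly above 1 can occur before clipping on export); the physical
#' scale is carried separately so every downstream measurement can be reported
#' in nanometres.
#'
#' @param pixels numeric matrix of non-negative, finite intensities; at least
#'   16 x 16.
#' @param pixel_size physical size of one pixel in nm/px, strictly positive.
#' @param id character identifier (source file name or synthetic scene name).
#' @return an object of class `stem_image`: a list with elements `pixels`,
#'   `pixel_size`, `id`.
#' @examples
#' img <- stem_image(matrix(0.1, 32, 32), pixel_size = 30)
#' img
#' @export
stem_image <- function(pixels, pixel_size, id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16x16 pixels")
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (nm/px)")
  structure(
    list(pixels = unname(pixels), pixel_size = as.numeric(pixel_size),
         id = as.character(id)),
    class = "stem_image"
  )
}

#' @export
print.stem_image <- function(x, ...) {
  cat(sprintf("<stem_image> %s: %d x %d px, %.3g nm/px, range [%.4g, %.4g]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.stem_image <- function(x) dim(x$pixels)

as_pixels <- function(img) {
  if (inherits(img, "stem_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a `stem_image` or a numeric matrix")
}

#' Read a grayscale image from disk
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a [stem_image()]. Colour
#' images are collapsed to grayscale by channel averaging.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size physical pixel size in nm/px (not stored in the files the
#'   workflow exchanges, so it must be supplied).
#' @param id identifier; defaults to the file name.
#' @return a [stem_image()].
#' @export
read_stem_image <- function(path, pixel_size, id = basename(path)) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(m)) == 3L) m <- apply(m, c(1L, 2L), mean)
  stem_image(m, pixel_size = pixel_size, id = id)
}

#' Write a STEM image to disk
#'
#' Writes 16-bit grayscale TIFF by default (intensities clipped to `[0, 1]`),
#' or 32-bit float TIFF for probability maps and other continuous rasters.
#'
#' @param img a [stem_image()] or numeric matrix.
#' @param path output path ending in `.tif`/`.tiff`.
#' @param bits 16 (integer, clipped) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_stem_image <- function(img, path, bits = 16L) {
  m <- as_pixels(img)
  if (bits == 16L) {
    m <- pmin(pmax(m, 0), 1)
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (bits == 32L) {
    tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  } else stop("`bits` must be 16 or 32")
  invisible(path)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generator calls never perturb a session.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
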