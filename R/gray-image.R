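#' Construct a grayscale image with a declared bit depth
#'
#' A `gray_image` is an integer pixel matrix together with the logical bit
#' depth `n` of the acquisition, so that gray values live in `[0, 2^n - 1]`.
#' Medical scanners commonly emit 12-bit data stored in 16-bit containers;
#' keeping `n` explicit lets histograms, thresholds and quality metrics use
#' the true dynamic range `L = 2^n` rather than the container's.
#'
#' @param pixels integer matrix (rows x cols) of non-negative gray values.
#' @param bit_depth integer bit depth `n`; gray levels are `L = 2^n`.
#' @return An object of class `gray_image` with fields `pixels` and
#'   `bit_depth`.
#' @export
gray_image <- function(pixels, bit_depth) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  stopifnot(is.numeric(bit_depth), length(bit_depth) == 1L)
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 16L)
    stop("bit_depth must be in 1..16", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0L))
    stop("pixel values must be non-negative integers", call. = FALSE)
  if (any(pixels > 2^bit_depth - 1))
    stop("pixel value exceeds 2^bit_depth - 1: bit-depth mismatch",
         call. = FALSE)
  structure(list(pixels = pixels, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit (L = %d), range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              gray_levels(x), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Number of representable gray levels of an image
#' @param image a `gray_image`.
#' @return `L = 2^bit_depth`.
#' @export
gray_levels <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  as.integer(2^image$bit_depth)
}

#' Remap an image to a higher bit depth
#'
#' Gray values are left-shifted by the bit-depth difference (multiplied by
#' `2^(target_n - n)`), the histogram-stretch mapping used to lift 8-bit
#' material into a 12-bit range. Downscaling is refused.
#'
#' @param image a `gray_image`.
#' @param target_n target bit depth, `>= image$bit_depth`.
#' @return A `gray_image` of bit depth `target_n`.
#' @export
remap_bit_depth <- function(image, target_n) {
  stopifnot(inherits(image, "gray_image"))
  target_n <- as.integer(target_n)
  if (target_n < image$bit_depth)
    stop("cannot downscale bit depth (target_n < bit_depth)", call. = FALSE)
  if (target_n == image$bit_depth) return(image)
  shift <- 2^(target_n - image$bit_depth)
  gray_image(image$pixels * shift, target_n)
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8-bit images come from PNG; 12- and 16-bit images come from TIFF with a
#' 16-bit unsigned container, `bit_depth` declaring how many of those bits
#' carry signal. Stored sample values are taken verbatim (no rescaling).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth logical bit depth of the data (8, 12 or 16).
#' @return A `gray_image`.
#' @export
read_gray_image <- function(path, bit_depth) {
  bit_depth <- as.integer(bit_depth)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    container_max <- 255
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path)
    container_max <- 65535
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]  # drop extra channels
  gray_image(round(raw * container_max), bit_depth)
}

#' Write a grayscale image to PNG or TIFF
#'
#' The container is chosen from the extension: PNG stores 8-bit samples,
#' TIFF stores 16-bit samples. Values are written verbatim into the
#' container, so a 12-bit image occupies the low 12 bits of a 16-bit TIFF.
#'
#' @param image a `gray_image`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (image$bit_depth > 8L)
      stop("PNG container holds at most 8-bit data here; use TIFF",
           call. = FALSE)
    png::writePNG(image$pixels / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}
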