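#' Construct a grayscale image
#'
#' Images throughout the package are plain numeric matrices of intensities in
#' `[0, L - 1]` with the level count `L` stored as an attribute. This
#' constructor validates the range and attaches `L`.
#'
#' @param pixels Numeric matrix (rows = image rows).
#' @param L Integer number of intensity levels (default 256, i.e. 8-bit).
#' @return A numeric matrix of class `grayscale_image` with attribute `L`.
#' @export
grayscale_image <- function(pixels, L = 256L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  L <- as.integer(L)
  if (L < 2L) stop("`L` must be >= 2", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("image contains non-finite pixels", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > L - 1) {
    stop("pixel values must lie in [0, L - 1]", call. = FALSE)
  }
  structure(pixels, L = L, class = c("grayscale_image", class(pixels)))
}

img_levels <- function(img) {
  L <- attr(img, "L")
  if (is.null(L)) 256L else as.integer(L)
}

#' Convert a raster to grayscale
#'
#' Three-channel rasters are reduced with BT.601 luma weights
#' (0.299, 0.587, 0.114); single-channel inputs pass through unchanged.
#'
#' @param image A numeric matrix (already grayscale) or an M x N x 3 array
#'   with channel values in `[0, L - 1]`.
#' @param L Intensity level count.
#' @return A [grayscale_image()].
#' @export
to_grayscale <- function(image, L = 256L) {
  if (is.matrix(image)) {
    return(grayscale_image(unclass(image), L = L))
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] != 3L) {
      stop("3-D input must have exactly 3 channels", call. = FALSE)
    }
    w <- c(0.299, 0.587, 0.114)
    gray <- w[1] * image[, , 1] + w[2] * image[, , 2] + w[3] * image[, , 3]
    dim(gray) <- dim(image)[1:2]
    return(grayscale_image(gray, L = L))
  }
  stop("input must be a 2-D matrix or an M x N x 3 array", call. = FALSE)
}

#' Read an image file as a grayscale matrix
#'
#' Supports PNG and TIFF (8- and 16-bit). Values are rescaled from the
#' decoder's `[0, 1]` range to `[0, L - 1]`; RGB images are converted with
#' [to_grayscale()].
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param L Intensity level count of the returned image.
#' @return A [grayscale_image()].
#' @export
read_image <- function(path, L = 256L) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG and TIFF are supported)",
         call. = FALSE)
  )
  raw <- raw * (L - 1)
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
    to_grayscale(raw, L = L)
  } else {
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    to_grayscale(as.matrix(raw), L = L)
  }
}

#' Write a grayscale matrix to an image file
#'
#' @param img Numeric matrix in `[0, L - 1]`.
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @param L Intensity level count used to rescale to the encoder's `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, L = img_levels(img)) {
  scaled <- pmin(pmax(unclass(img) / (L - 1), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(scaled, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(scaled, where = path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# Bilinear resize to a square side; thin wrapper kept so the resize rule is a
# single documented choice.
resize_bilinear <- function(img, side) {
  m <- unclass(img)
  if (nrow(m) == side && ncol(m) == side) return(m)
  EBImage::resize(m, w = side, h = side, filter = "bilinear")
}
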