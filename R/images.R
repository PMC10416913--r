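# Images are plain numeric matrices (grayscale, intensities in [0, 255],
# rows = image rows) or H x W x 3 arrays (RGB, same scale).

#' Validate a grayscale image
#'
#' Checks that `img` is a numeric matrix with intensities in [0, 255] and at
#' least 8 pixels on each side, the working contract shared by the
#' enhancement and quality-metric functions.
#'
#' @param img object to validate.
#' @param min_dim minimum number of rows and columns.
#' @return `img`, invisibly, after validation.
#' @export
check_gray_image <- function(img, min_dim = 8L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Clamp and quantize intensities to 8-bit levels
#'
#' @param x numeric matrix or array on the 0-255 scale.
#' @return the input rounded to whole levels and clamped to [0, 255].
#' @export
quantize_gray <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Is this an RGB array?
#' @param img image object.
#' @return logical.
#' @export
is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

#' Convert RGB to grayscale luminance
#'
#' Rec. 601 luma weights; a no-op for matrices already grayscale.
#'
#' @param img matrix or H x W x 3 array on the 0-255 scale.
#' @return grayscale matrix.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is_rgb_image(img)) stop("expected a matrix or an H x W x 3 array")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Bilinear resize
#'
#' @param img grayscale matrix or RGB array, 0-255 scale.
#' @param height,width target size in pixels.
#' @return resized image of the same kind.
#' @export
resize_image <- function(img, height, width) {
  if (is_rgb_image(img)) {
    out <- array(0, dim = c(height, width, 3L))
    for (ch in 1:3) out[, , ch] <- resize_image(img[, , ch], height, width)
    return(out)
  }
  if (nrow(img) == height && ncol(img) == width) return(img)
  EBImage::resize(img, w = height, h = width)
}

# Reflect an index vector into 1..n (mirror boundary, no repeated edge pixel
# for n > 1); used by the geometric augmentations.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i <- ifelse(i >= n, period - i, i)
  i + 1L
}

# Sample img at fractional coordinates (r, c) with bilinear interpolation and
# mirror boundary handling. r, c are numeric vectors of equal length.
bilinear_sample <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  n <- nrow(img); m <- ncol(img)
  i00 <- cbind(reflect_index(r0,      n), reflect_index(c0,      m))
  i01 <- cbind(reflect_index(r0,      n), reflect_index(c0 + 1L, m))
  i10 <- cbind(reflect_index(r0 + 1L, n), reflect_index(c0,      m))
  i11 <- cbind(reflect_index(r0 + 1L, n), reflect_index(c0 + 1L, m))
  img[i00] * (1 - fr) * (1 - fc) + img[i01] * (1 - fr) * fc +
    img[i10] * fr * (1 - fc) + img[i11] * fr * fc
}

#' Read a fundus image from PNG
#'
#' @param path file path to an 8-bit PNG.
#' @return grayscale matrix or RGB array on the 0-255 scale.
#' @export
read_fundus <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- a[, , 1:3] else a <- a[, , 1]
  }
  a * 255
}

#' Write a fundus image as PNG
#'
#' @param img grayscale matrix or RGB array, 0-255 scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fundus <- function(img, path) {
  png::writePNG(quantize_gray(img) / 255, path)
  invisible(path)
}
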