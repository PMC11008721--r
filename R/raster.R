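#' Raster image containers and sampling utilities
#'
#' Images are plain numeric arrays of dimension H x W x 3 with channel values
#' in [0, 1]. The pixel grid is continuous and 0-based: x runs right along
#' columns, y runs down along rows, so pixel (row i, col j) sits at
#' (x, y) = (j - 1, i - 1). PNG files are read and written with the png
#' package; JPEG reading is delegated to EBImage when available.
#'
#' @name raster
NULL

#' Validate (and coerce) an H x W x 3 raster image
#'
#' @param img numeric array H x W x 3, or H x W matrix (replicated to 3
#'   channels), values in [0, 1]
#' @return the validated H x W x 3 array
#' @export
as_raster <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("raster image must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("raster image must have H >= 1 and W >= 1")
  if (!all(is.finite(img))) stop("raster image contains non-finite values")
  if (min(img) < 0 || max(img) > 1)
    stop("raster image values must lie in [0, 1]")
  img
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Per-pixel channel maximum of a raster image
#' @param img H x W x 3 array
#' @return H x W matrix
#' @export
channel_max <- function(img) pmax(img[, , 1], img[, , 2], img[, , 3])

#' Mean luminance (channel mean) of a raster image
#' @param img H x W x 3 array
#' @return H x W matrix
#' @keywords internal
channel_mean <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

gaussian_kernel1d <- function(sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense matrix realizing 1D convolution with reflected (mirror, no repeat)
# borders: row i holds the kernel centred at i with out-of-range taps folded
# back inside. Applied as K %*% M (down columns) or M %*% t(K) (along rows).
conv_matrix_reflect <- function(n, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - radius):(i + radius)
    # reflect about the edges: 0 -> 2, -1 -> 3, n+1 -> n-1, ...
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + kernel[j]
  }
  K
}

#' Gaussian blur of a matrix with reflected borders
#'
#' Separable Gaussian low-pass filter (truncated at 3 sigma) with mirror
#' boundary handling, so a constant input is returned unchanged.
#'
#' @param mat numeric matrix
#' @param sigma standard deviation in pixels, > 0
#' @return blurred matrix of the same size
#' @export
blur_gaussian <- function(mat, sigma) {
  stopifnot(is.matrix(mat), sigma > 0)
  k <- gaussian_kernel1d(sigma)
  Kr <- conv_matrix_reflect(nrow(mat), k)
  Kc <- conv_matrix_reflect(ncol(mat), k)
  Kr %*% mat %*% t(Kc)
}

#' Bilinear sampling of a raster image at continuous coordinates
#'
#' Queries use the package's 0-based continuous pixel frame. Samples falling
#' outside the image evaluate to `fill`.
#'
#' @param img H x W x 3 array
#' @param xq,yq numeric matrices (equal size) of query coordinates
#' @param fill scalar or length-3 border fill value
#' @return array dim(xq) x 3
#' @export
bilinear_sample <- function(img, xq, yq, fill = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (length(fill) == 1L) fill <- rep(fill, 3L)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  inside <- xq >= 0 & xq <= w - 1 & yq >= 0 & yq <= h - 1
  # clamp corner indices so arithmetic stays in range; masked after
  cx0 <- pmin(pmax(x0, 0), w - 1); cx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  cy0 <- pmin(pmax(y0, 0), h - 1); cy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  idx <- function(rm, cm) cbind(as.vector(rm) + 1, as.vector(cm) + 1)
  i_00 <- idx(cy0, cx0); i_01 <- idx(cy0, cx1)
  i_10 <- idx(cy1, cx0); i_11 <- idx(cy1, cx1)
  out <- array(0, dim = c(dim(xq), 3L))
  for (ch in 1:3) {
    m <- img[, , ch]
    v <- (1 - fy) * ((1 - fx) * m[i_00] + fx * m[i_01]) +
      fy * ((1 - fx) * m[i_10] + fx * m[i_11])
    v[!inside] <- fill[ch]
    out[, , ch] <- v
  }
  out
}

#' Read an image file into an H x W x 3 raster array
#'
#' 8-bit PNG is read natively; JPEG requires the EBImage package. Grayscale
#' images are replicated across channels and any alpha plane is dropped.
#'
#' @param path file path (.png, .jpg, .jpeg)
#' @return H x W x 3 array in [0, 1]
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package")
    e <- EBImage::readImage(path)
    d <- dim(e)
    img <- if (length(d) == 2L) t(as.array(e)) else aperm(as.array(e), c(2, 1, 3))
  } else stop("unsupported image format: ", ext)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  as_raster(clamp01(img))
}

#' Write a raster image to PNG (8-bit)
#' @param img H x W x 3 array in [0, 1]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  img <- as_raster(img)
  png::writePNG(round(img * 255) / 255, path)
  invisible(path)
}
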