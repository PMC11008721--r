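#' Low-light image enhancement by Retinex decomposition and adaptive gamma
#'
#' The image is modelled as the pixel-wise product of a smooth illumination
#' (luminance) field and a reflectance field: I_c(x,y) = R_c(x,y) * L(x,y)
#' for each channel c in {r, g, b}. Enhancement touches only the luminance:
#' a per-level gamma exponent gamma(l) = 1 - weightedCDF(l) is derived from
#' the luminance histogram, dark levels receive exponents close to 0 (strong
#' brightening) and bright levels exponents close to 1 (little change), the
#' corrected luminance L_en = L^gamma is recombined with the untouched
#' reflectance, and the result is clamped back to [0, 1].
#'
#' @name illumination
NULL

#' Configuration for the enhancement pipeline
#'
#' @param blur_sigma Gaussian scale (pixels) of the illumination low-pass;
#'   default 15. The luminance field is assumed smooth at this scale.
#' @param bins number of histogram levels B over [0, 1]; default 256,
#'   matching 8-bit imagery.
#' @param eps_floor lower clamp for the luminance field so reflectance
#'   division is defined; default 1e-6.
#' @param clamp_output clamp the recomposed image to [0, 1]? Reflectance can
#'   exceed 1 wherever a channel is brighter than the luminance estimate.
#' @return list of class `enhance_config`
#' @export
enhance_config <- function(blur_sigma = 15, bins = 256L, eps_floor = 1e-6,
                           clamp_output = TRUE) {
  stopifnot(blur_sigma > 0, bins >= 2L, eps_floor > 0)
  structure(list(blur_sigma = blur_sigma, bins = as.integer(bins),
                 eps_floor = eps_floor, clamp_output = isTRUE(clamp_output)),
            class = "enhance_config")
}

#' Estimate the smooth luminance (illumination) field of an image
#'
#' Single-scale Retinex convention: the per-pixel channel maximum (avoiding
#' hue bias) is low-pass filtered with a Gaussian of scale `blur_sigma`
#' (reflected borders) and clamped to [eps_floor, 1].
#'
#' @param img H x W x 3 raster
#' @param cfg an [enhance_config()]
#' @return H x W luminance matrix in [eps_floor, 1]
#' @export
estimate_illumination <- function(img, cfg = enhance_config()) {
  img <- as_raster(img)
  L <- blur_gaussian(channel_max(img), cfg$blur_sigma)
  pmin(pmax(L, cfg$eps_floor), 1)
}

#' Separate reflectance from an image given its luminance field
#'
#' @param img H x W x 3 raster
#' @param L H x W luminance matrix, >= eps_floor everywhere
#' @return H x W x 3 reflectance array R_c = I_c / L (can exceed 1)
#' @export
decompose_retinex <- function(img, L) {
  img <- as_raster(img)
  if (!is.matrix(L) || !all(dim(L) == dim(img)[1:2]))
    stop("luminance map shape does not match image")
  if (min(L) <= 0) stop("luminance map must be strictly positive")
  sweep(img, c(1, 2), L, "/")
}

# 0-based histogram level of luminance values in [0,1]: floor(min(x,1-ulp)*B)
luminance_level <- function(x, bins) {
  as.integer(floor(pmin(pmax(x, 0), 1 - .Machine$double.eps) * bins))
}

#' Build the per-level adaptive gamma table from a luminance field
#'
#' Luminance is quantised to B levels. With n_l the pixel count at level l and
#' n_p the total count, P(l) = n_l / n_p, the weights are the min-max
#' normalised probabilities P_w(l) = (P(l) - P_min) / (P_max - P_min) taken
#' over all B levels, sp = sum_l P_w(l) is the global normaliser, and
#' gamma(l) = 1 - cumsum(P_w)(l) / sp, a value in [0, 1] that is monotone
#' nonincreasing in l. A degenerate histogram (flat, or a single occupied
#' level, where the min-max normalisation is undefined or would send every
#' pixel to white) yields the identity table gamma(l) = 1.
#'
#' @param L H x W luminance matrix
#' @param cfg an [enhance_config()]
#' @return list of class `gamma_table` with fields `levels` (0..B-1),
#'   `counts`, `n_p`, `pdf`, `weights`, `sp`, `gamma`, `degenerate`, `bins`
#' @export
build_gamma_table <- function(L, cfg = enhance_config()) {
  if (length(L) == 0L) stop("empty luminance map")
  B <- cfg$bins
  lev <- luminance_level(L, B)
  counts <- tabulate(lev + 1L, nbins = B)
  n_p <- sum(counts)
  pdf <- counts / n_p
  p_max <- max(pdf); p_min <- min(pdf)
  degenerate <- (p_max == p_min) || sum(counts > 0L) == 1L
  if (degenerate) {
    weights <- rep(0, B); sp <- 0; gam <- rep(1, B)
  } else {
    weights <- (pdf - p_min) / (p_max - p_min)
    sp <- sum(weights)
    gam <- 1 - cumsum(weights) / sp
    gam <- pmin(pmax(gam, 0), 1)
  }
  structure(list(levels = 0:(B - 1L), counts = counts, n_p = n_p, pdf = pdf,
                 weights = weights, sp = sp, gamma = gam,
                 degenerate = degenerate, bins = B),
            class = "gamma_table")
}

#' @export
print.gamma_table <- function(x, ...) {
  occ <- sum(x$counts > 0L)
  cat("Adaptive gamma table:", x$bins, "levels,", x$n_p, "pixels,",
      occ, "occupied level(s)\n")
  if (x$degenerate) cat("  degenerate histogram: identity transform\n")
  else cat(sprintf("  gamma range [%.4f, %.4f], sp = %.4f\n",
                   min(x$gamma), max(x$gamma), x$sp))
  invisible(x)
}

#' Write a gamma table to CSV (columns level, n_l, P, P_w, gamma)
#' @param tab a `gamma_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_gamma_table <- function(tab, path) {
  utils::write.csv(
    data.frame(level = tab$levels, n_l = tab$counts, P = tab$pdf,
               P_w = tab$weights, gamma = tab$gamma),
    path, row.names = FALSE)
  invisible(path)
}

#' Apply a gamma table to the luminance field it was built from
#'
#' L_en(x,y) = L(x,y)^gamma(level(x,y)). Because gamma(l) lies in [0, 1] and
#' L <= 1, the transform only ever brightens: L_en >= L elementwise.
#'
#' @param L H x W luminance matrix
#' @param tab a [build_gamma_table()] result using the same quantisation
#' @return H x W enhanced luminance matrix in [0, 1]
#' @export
apply_gamma <- function(L, tab) {
  if (tab$degenerate) return(L)
  lev <- luminance_level(L, tab$bins)
  out <- L^tab$gamma[lev + 1L]
  matrix(pmin(pmax(out, 0), 1), nrow(L), ncol(L))
}

#' Recombine reflectance with an enhanced luminance field
#'
#' @param R H x W x 3 reflectance array
#' @param L_en H x W enhanced luminance matrix
#' @param cfg an [enhance_config()]; controls output clamping
#' @return H x W x 3 raster
#' @export
recompose <- function(R, L_en, cfg = enhance_config()) {
  if (!is.matrix(L_en) || !all(dim(L_en) == dim(R)[1:2]))
    stop("luminance shape does not match reflectance")
  out <- sweep(R, c(1, 2), L_en, "*")
  if (cfg$clamp_output) out <- clamp01(out)
  out
}

#' Full low-light enhancement of an image
#'
#' Composition of [estimate_illumination()], [decompose_retinex()],
#' [build_gamma_table()], [apply_gamma()] and [recompose()]. Deterministic;
#' a uniform image passes through unchanged (degenerate histogram).
#'
#' @param img H x W x 3 raster
#' @param cfg an [enhance_config()]
#' @return enhanced H x W x 3 raster, with the gamma table attached as
#'   attribute `"gamma_table"`
#' @export
enhance <- function(img, cfg = enhance_config()) {
  img <- as_raster(img)
  L <- estimate_illumination(img, cfg)
  R <- decompose_retinex(img, L)
  tab <- build_gamma_table(L, cfg)
  out <- recompose(R, apply_gamma(L, tab), cfg)
  attr(out, "gamma_table") <- tab
  out
}
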