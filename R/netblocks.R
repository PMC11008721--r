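#' Training-free reference implementations of detection-network blocks
#'
#' Deterministic tensor operations matching the forward semantics of the
#' building blocks used in lightweight single-stage detectors: efficient
#' channel attention (ECA) with its adaptive kernel-size rule, coordinate
#' attention (CA), fast spatial pyramid pooling (SPPF), the Focus
#' space-to-depth slice, the complete-IoU (CIoU) box regression loss, and the
#' composite detection loss. Feature tensors are numeric arrays of dimension
#' C x H x W. No training occurs: where a block carries parameters, a seeded
#' deterministic initialiser is provided and tests rely on structural
#' properties only.
#'
#' @name netblocks
NULL

as_feature_tensor <- function(t) {
  if (!is.array(t) || length(dim(t)) != 3L)
    stop("feature tensor must be a C x H x W array")
  if (!all(is.finite(t))) stop("feature tensor contains non-finite values")
  t
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Adaptive ECA kernel size from the channel count
#'
#' k is the odd integer nearest to (log2(C_in) + 1) / 2, with a minimum of 1;
#' exact midpoints between two odd integers round to the larger one.
#'
#' @param c_in number of input channels, >= 1
#' @return odd positive integer kernel size
#' @export
eca_kernel_size <- function(c_in) {
  if (length(c_in) != 1L || !is.finite(c_in) || c_in < 1)
    stop("c_in must be a positive integer")
  t <- (log2(c_in) + 1) / 2
  lower <- 2 * floor((t - 1) / 2) + 1   # largest odd <= t (or t itself if odd)
  upper <- lower + 2
  k <- if ((t - lower) > (upper - t)) upper
       else if ((t - lower) < (upper - t)) lower
       else upper                        # midpoint: take the larger odd
  max(as.integer(k), 1L)
}

circular_conv1d <- function(x, kernel) {
  n <- length(x); k <- length(kernel); r <- (k - 1L) %/% 2L
  idx <- outer(seq_len(n), -r:r, "+")
  idx <- ((idx - 1L) %% n) + 1L
  as.numeric(matrix(x[idx], n, k) %*% kernel)
}

#' Efficient channel attention forward pass
#'
#' Channel descriptors are obtained by global average pooling, mixed by a 1D
#' convolution across channels (circular padding) and squashed through a
#' sigmoid; each input channel is then rescaled by its attention factor,
#' which lies in (0, 1).
#'
#' @param t C x H x W feature tensor
#' @param kernel odd-length numeric kernel; default is a uniform kernel of
#'   the adaptive size from [eca_kernel_size()]
#' @return tensor of the same shape
#' @export
eca_forward <- function(t, kernel = NULL) {
  t <- as_feature_tensor(t)
  C <- dim(t)[1]
  if (is.null(kernel)) {
    k <- eca_kernel_size(C)
    kernel <- rep(1 / k, k)
  }
  if (length(kernel) %% 2L == 0L) stop("ECA kernel length must be odd")
  means <- apply(t, 1, mean)
  scales <- sigmoid(circular_conv1d(means, kernel))
  t * array(scales, dim = dim(t))   # scales recycle along the channel dim
}

#' Seeded parameters for the coordinate-attention reference forward
#'
#' @param c_in input channels
#' @param r channel reduction ratio (mid width is ceiling(c_in / r))
#' @param seed RNG seed for the deterministic initialisation
#' @return list of weight matrices `w_mix` (Cm x C), `w_h`, `w_w` (C x Cm)
#' @export
ca_params <- function(c_in, r = 8, seed = 1) {
  if (r > c_in) stop("reduction ratio r must not exceed the channel count")
  cm <- as.integer(ceiling(c_in / r))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(w_mix = matrix(stats::rnorm(cm * c_in, sd = 0.1), cm, c_in),
       w_h = matrix(stats::rnorm(c_in * cm, sd = 0.1), c_in, cm),
       w_w = matrix(stats::rnorm(c_in * cm, sd = 0.1), c_in, cm))
}

#' Zero-weight ("identity-like") coordinate-attention parameters
#'
#' All convolution weights are zero, so every pre-sigmoid activation is 0 and
#' both attention factors equal sigmoid(0) = 0.5: the block returns
#' input x 0.25.
#'
#' @inheritParams ca_params
#' @return parameter list as in [ca_params()]
#' @export
ca_identity_params <- function(c_in, r = 8) {
  if (r > c_in) stop("reduction ratio r must not exceed the channel count")
  cm <- as.integer(ceiling(c_in / r))
  list(w_mix = matrix(0, cm, c_in), w_h = matrix(0, c_in, cm),
       w_w = matrix(0, c_in, cm))
}

#' Coordinate attention forward pass
#'
#' The input is average-pooled along each spatial axis (kernels (1, W) and
#' (H, 1)), the two pooled descriptors are concatenated along the spatial
#' axis and mixed by a 1x1 convolution down to ceiling(C/r) channels with a
#' ReLU, split back into the H- and W-branches, expanded to C channels by
#' per-branch 1x1 convolutions with sigmoids, and multiplied elementwise onto
#' the input: out[c,y,x] = in[c,y,x] * a_h[c,y] * a_w[c,x], with both
#' attention factors in (0, 1).
#'
#' @param t C x H x W feature tensor
#' @param r channel reduction ratio; must not exceed C
#' @param params parameter list from [ca_params()] or
#'   [ca_identity_params()]; default seeds fresh parameters with `seed`
#' @param seed seed for default parameters
#' @return tensor of the same shape
#' @export
ca_forward <- function(t, r = 8, params = NULL, seed = 1) {
  t <- as_feature_tensor(t)
  C <- dim(t)[1]; H <- dim(t)[2]; W <- dim(t)[3]
  if (r > C) stop("reduction ratio r must not exceed the channel count")
  if (is.null(params)) params <- ca_params(C, r = r, seed = seed)
  pooled_h <- apply(t, c(1, 2), mean)          # C x H  (pool kernel (1, W))
  pooled_w <- apply(t, c(1, 3), mean)          # C x W  (pool kernel (H, 1))
  z <- cbind(pooled_h, pooled_w)               # C x (H + W)
  mid <- pmax(params$w_mix %*% z, 0)           # Cm x (H + W), ReLU
  a_h <- sigmoid(params$w_h %*% mid[, seq_len(H), drop = FALSE])       # C x H
  a_w <- sigmoid(params$w_w %*% mid[, H + seq_len(W), drop = FALSE])   # C x W
  out <- t
  for (c in seq_len(C))
    out[c, , ] <- t[c, , ] * outer(a_h[c, ], a_w[c, ])
  out
}

# stride-1 k x k max pooling with same-size output; out-of-image taps act as
# -Inf. Separable: running max along rows, then along columns.
running_max_1d <- function(M, k, along) {
  r <- (k - 1L) %/% 2L
  out <- M
  n <- if (along == "row") nrow(M) else ncol(M)
  for (s in setdiff(-r:r, 0L)) {
    src <- seq_len(n) + s
    ok <- src >= 1L & src <= n
    if (along == "row") out[ok, ] <- pmax(out[ok, ], M[src[ok], , drop = FALSE])
    else out[, ok] <- pmax(out[, ok], M[, src[ok], drop = FALSE])
  }
  out
}

#' Stride-1 max pooling with same-size padding
#'
#' @param t C x H x W feature tensor
#' @param k odd pooling kernel size
#' @return tensor of the same shape; every value is the max over the k x k
#'   window centred at its position (border windows are truncated, the
#'   padding behaving as negative infinity)
#' @export
maxpool_same <- function(t, k) {
  t <- as_feature_tensor(t)
  stopifnot(k >= 1, k %% 2 == 1)
  H <- dim(t)[2]; W <- dim(t)[3]
  out <- t
  for (c in seq_len(dim(t)[1])) {
    m <- running_max_1d(matrix(t[c, , ], H, W), k, "row")
    out[c, , ] <- running_max_1d(m, k, "col")
  }
  out
}

#' Fast spatial pyramid pooling (SPPF) forward pass
#'
#' The input is max-pooled at receptive fields 5, 9 and 13 (stride 1,
#' same-size padding), the input and the three pooled maps are concatenated
#' along the channel axis (4C channels), and a 1x1 convolution projects back
#' to C channels. With `proj = NULL` the raw 4C concatenation is returned,
#' exposing the pyramid for testing.
#'
#' @param t C x H x W feature tensor
#' @param proj optional projection matrix (C_out x 4C) applied as a 1x1
#'   convolution; NULL returns the concatenation
#' @return 4C x H x W concatenation, or C_out x H x W projection
#' @export
sppf_forward <- function(t, proj = NULL) {
  t <- as_feature_tensor(t)
  C <- dim(t)[1]; H <- dim(t)[2]; W <- dim(t)[3]
  cat4 <- array(0, dim = c(4L * C, H, W))
  cat4[seq_len(C), , ] <- t
  cat4[C + seq_len(C), , ] <- maxpool_same(t, 5L)
  cat4[2L * C + seq_len(C), , ] <- maxpool_same(t, 9L)
  cat4[3L * C + seq_len(C), , ] <- maxpool_same(t, 13L)
  if (is.null(proj)) return(cat4)
  stopifnot(is.matrix(proj), ncol(proj) == 4L * C)
  flat <- matrix(cat4, nrow = 4L * C)   # channels x (H*W)
  array(proj %*% flat, dim = c(nrow(proj), H, W))
}

#' Seeded SPPF projection matrix (C x 4C)
#' @param c_in input channel count C
#' @param seed RNG seed
#' @return C x 4C matrix
#' @export
sppf_params <- function(c_in, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  matrix(stats::rnorm(c_in * 4L * c_in, sd = 0.1), c_in, 4L * c_in)
}

#' Focus space-to-depth slice
#'
#' Rearranges a C x H x W tensor (H, W even) into 4C x H/2 x W/2 by taking
#' the four 2x2 sub-grids; channel blocks are ordered top-left, top-right,
#' bottom-left, bottom-right. Every input value appears exactly once.
#'
#' @param t C x H x W feature tensor with even H and W
#' @return 4C x H/2 x W/2 tensor
#' @export
focus_slice <- function(t) {
  t <- as_feature_tensor(t)
  C <- dim(t)[1]; H <- dim(t)[2]; W <- dim(t)[3]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("focus slice requires even H and W")
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  out <- array(0, dim = c(4L * C, H %/% 2L, W %/% 2L))
  out[seq_len(C), , ] <- t[, ro, co, drop = FALSE]            # top-left
  out[C + seq_len(C), , ] <- t[, ro, ce, drop = FALSE]        # top-right
  out[2L * C + seq_len(C), , ] <- t[, re, co, drop = FALSE]   # bottom-left
  out[3L * C + seq_len(C), , ] <- t[, re, ce, drop = FALSE]   # bottom-right
  out
}

#' Axis-aligned box in centre/width/height form
#' @param x,y centre coordinates
#' @param w,h strictly positive extents
#' @return named numeric vector of class `box_cwh`
#' @export
box_cwh <- function(x, y, w, h) {
  if (!all(is.finite(c(x, y, w, h)))) stop("box parameters must be finite")
  if (w <= 0 || h <= 0) stop("box width and height must be positive")
  structure(c(x = x, y = y, w = w, h = h), class = "box_cwh")
}

cwh_corners <- function(b)
  c(x1 = b[["x"]] - b[["w"]] / 2, y1 = b[["y"]] - b[["h"]] / 2,
    x2 = b[["x"]] + b[["w"]] / 2, y2 = b[["y"]] + b[["h"]] / 2)

#' Complete-IoU (CIoU) bounding-box regression loss
#'
#' L = 1 - IoU + rho^2 / c^2 + alpha v, where rho is the distance between the
#' two box centres, c the diagonal of the tightest box enclosing both, the
#' aspect-consistency term v = (4 / pi^2) (atan(w_gt / h_gt) - atan(w / h))^2
#' and the trade-off alpha = v / ((1 - IoU) + v) (defined as 0 when both the
#' numerator and denominator vanish, i.e. identical aspect at full overlap).
#' Non-overlapping boxes have IoU 0.
#'
#' @param pred,gt boxes from [box_cwh()] (or numeric c(x, y, w, h))
#' @return list of class `ciou_terms`: `iou`, `rho`, `c` (enclosing
#'   diagonal), `v`, `alpha`, `loss`
#' @export
ciou_loss <- function(pred, gt) {
  if (!inherits(pred, "box_cwh")) pred <- box_cwh(pred[1], pred[2], pred[3], pred[4])
  if (!inherits(gt, "box_cwh")) gt <- box_cwh(gt[1], gt[2], gt[3], gt[4])
  p <- cwh_corners(pred); g <- cwh_corners(gt)
  iw <- max(0, min(p[["x2"]], g[["x2"]]) - max(p[["x1"]], g[["x1"]]))
  ih <- max(0, min(p[["y2"]], g[["y2"]]) - max(p[["y1"]], g[["y1"]]))
  inter <- iw * ih
  union <- pred[["w"]] * pred[["h"]] + gt[["w"]] * gt[["h"]] - inter
  iou <- inter / union
  rho2 <- (pred[["x"]] - gt[["x"]])^2 + (pred[["y"]] - gt[["y"]])^2
  cw <- max(p[["x2"]], g[["x2"]]) - min(p[["x1"]], g[["x1"]])
  ch <- max(p[["y2"]], g[["y2"]]) - min(p[["y1"]], g[["y1"]])
  c2 <- cw^2 + ch^2
  v <- (4 / pi^2) * (atan(gt[["w"]] / gt[["h"]]) - atan(pred[["w"]] / pred[["h"]]))^2
  denom <- (1 - iou) + v
  alpha <- if (denom == 0) 0 else v / denom
  structure(list(iou = iou, rho = sqrt(rho2), c = sqrt(c2), v = v,
                 alpha = alpha,
                 loss = 1 - iou + rho2 / c2 + alpha * v),
            class = "ciou_terms")
}

#' @export
print.ciou_terms <- function(x, ...) {
  cat(sprintf(
    "CIoU: loss = %.4f (IoU %.4f, rho %.3f, c %.3f, v %.4g, alpha %.4g)\n",
    x$loss, x$iou, x$rho, x$c, x$v, x$alpha))
  invisible(x)
}

cross_entropy_cat <- function(P, G, eps = 1e-12) {
  -sum(G * log(pmax(P, eps)))
}

cross_entropy_bin <- function(p, g, eps = 1e-12) {
  -sum(g * log(pmax(p, eps)) + (1 - g) * log(pmax(1 - p, eps)))
}

#' Composite detection loss over one batch
#'
#' L = (1/N_pos) [ CE(Cls over positives) + lambda1 CE(Obj over positives and
#' negatives) + lambda2 sum of CIoU over positives + lambda3 sum of L1
#' localization offsets over positives ], where CE is categorical
#' cross-entropy for class scores and binary cross-entropy for the IoU-aware
#' objectness. The L1 term is included only when `l1_enabled` (late-stage
#' refinement).
#'
#' @param batch list with components: `cls_pred`, `cls_gt` (N_pos x K
#'   class-probability matrices), `obj_pred`, `obj_gt` (objectness vectors
#'   over all positive and negative anchors), `box_pred`, `box_gt` (N_pos x 4
#'   centre/width/height matrices), optional `reg_pred`, `reg_gt` (N_pos x 4
#'   offsets), `lambda` (length 3, default c(1, 5, 1)), `l1_enabled` flag
#' @return list of class `composite_loss`: `total`, `n_pos`, and the
#'   breakdown `cls`, `obj`, `box`, `reg` (each already weighted and divided
#'   by N_pos, so they sum to `total`)
#' @export
composite_loss <- function(batch) {
  n_pos <- nrow(batch$cls_pred)
  if (is.null(n_pos) || n_pos < 1L)
    stop("batch has no positive samples (N_pos = 0)")
  lambda <- if (is.null(batch$lambda)) c(1, 5, 1) else batch$lambda
  stopifnot(length(lambda) == 3L)
  l1_enabled <- isTRUE(batch$l1_enabled)
  ce_cls <- cross_entropy_cat(batch$cls_pred, batch$cls_gt)
  ce_obj <- cross_entropy_bin(batch$obj_pred, batch$obj_gt)
  sum_ciou <- sum(vapply(seq_len(n_pos), function(i)
    ciou_loss(batch$box_pred[i, ], batch$box_gt[i, ])$loss, numeric(1)))
  sum_l1 <- if (l1_enabled) sum(abs(batch$reg_pred - batch$reg_gt)) else 0
  parts <- c(cls = ce_cls, obj = lambda[1] * ce_obj,
             box = lambda[2] * sum_ciou, reg = lambda[3] * sum_l1) / n_pos
  structure(list(total = sum(parts), n_pos = n_pos,
                 cls = parts[["cls"]], obj = parts[["obj"]],
                 box = parts[["box"]], reg = parts[["reg"]],
                 lambda = lambda, l1_enabled = l1_enabled),
            class = "composite_loss")
}

#' @export
print.composite_loss <- function(x, ...) {
  cat(sprintf(
    "Composite loss %.4f over %d positives (cls %.4f, obj %.4f, box %.4f, reg %.4f)\n",
    x$total, x$n_pos, x$cls, x$obj, x$box, x$reg))
  invisible(x)
}

# save/restore the global RNG state so seeded parameter builders do not
# disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
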