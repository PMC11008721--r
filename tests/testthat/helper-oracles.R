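# Independent brute-force oracles used by the test suite. These deliberately
# use explicit loops / exhaustive enumeration, never the package's own code
# paths.

# per-pixel, per-level recomputation of the adaptive gamma table
gamma_table_oracle <- function(L, bins) {
  counts <- rep(0L, bins)
  for (v in as.numeric(L)) {
    lev <- floor(min(v, 1 - .Machine$double.eps) * bins)
    counts[lev + 1L] <- counts[lev + 1L] + 1L
  }
  n_p <- length(L)
  pdf <- counts / n_p
  p_max <- max(pdf); p_min <- min(pdf)
  occupied <- sum(counts > 0L)
  if (p_max == p_min || occupied == 1L)
    return(list(pdf = pdf, weights = rep(0, bins), sp = 0,
                gamma = rep(1, bins), degenerate = TRUE))
  weights <- numeric(bins)
  for (l in seq_len(bins)) weights[l] <- (pdf[l] - p_min) / (p_max - p_min)
  sp <- 0
  for (l in seq_len(bins)) sp <- sp + weights[l]
  gam <- numeric(bins)
  acc <- 0
  for (l in seq_len(bins)) {
    acc <- acc + weights[l]
    gam[l] <- min(max(1 - acc / sp, 0), 1)
  }
  list(pdf = pdf, weights = weights, sp = sp, gamma = gam, degenerate = FALSE)
}

# grid-refinement minimizer of S(m, b) = sum w (y - (m x + b))^2
wls_grid_oracle <- function(x, y, w, m_range = c(-20, 20),
                            b_range = NULL, iters = 7L, grid_n = 41L) {
  if (is.null(b_range)) {
    span <- max(abs(x)) * max(abs(m_range)) + max(abs(y)) + 1
    b_range <- c(-span, span)
  }
  best <- c(m = mean(m_range), b = mean(b_range))
  for (it in seq_len(iters)) {
    ms <- seq(m_range[1], m_range[2], length.out = grid_n)
    bs <- seq(b_range[1], b_range[2], length.out = grid_n)
    S <- outer(ms, bs, Vectorize(function(m, b) sum(w * (y - (m * x + b))^2)))
    idx <- which(S == min(S), arr.ind = TRUE)[1, ]
    best <- c(m = ms[idx[1]], b = bs[idx[2]])
    dm <- diff(m_range) / (grid_n - 1)
    db <- diff(b_range) / (grid_n - 1)
    m_range <- best[["m"]] + c(-2, 2) * dm
    b_range <- best[["b"]] + c(-2, 2) * db
  }
  best
}

# naive stride-1 same-size max pooling (window loops, -Inf padding)
maxpool_naive <- function(t, k) {
  C <- dim(t)[1]; H <- dim(t)[2]; W <- dim(t)[3]
  r <- (k - 1L) %/% 2L
  out <- array(-Inf, dim = dim(t))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    rows <- max(1L, i - r):min(H, i + r)
    cols <- max(1L, j - r):min(W, j + r)
    out[c, i, j] <- max(t[c, rows, cols])
  }
  out
}

iou_pair <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# exhaustive optimal one-to-one assignment: maximum number of det-gt pairs
# with IoU >= iou_min
optimal_tp_oracle <- function(det_m, gt_m, iou_min) {
  nd <- nrow(det_m); ng <- nrow(gt_m)
  if (nd == 0L || ng == 0L) return(0L)
  feasible <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng))
    feasible[i, j] <- iou_pair(det_m[i, ], gt_m[j, ]) >= iou_min
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1L) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    for (j in seq_len(ng)) {
      if (!used[j] && feasible[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}

# all-points AP by exhaustive confidence-threshold enumeration: at each
# distinct confidence cutoff, detections are matched greedily in descending
# confidence and a (recall, precision) point recorded; the monotone envelope
# is integrated over recall.
ap_threshold_oracle <- function(dets, gts, iou_min) {
  gt_m <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  thresholds <- sort(unique(dets$conf), decreasing = TRUE)
  pr <- NULL
  for (th in thresholds) {
    sub <- dets[dets$conf >= th, , drop = FALSE]
    sub <- sub[order(sub$conf, decreasing = TRUE), , drop = FALSE]
    used <- rep(FALSE, nrow(gt_m))
    tp <- 0L
    for (i in seq_len(nrow(sub))) {
      ious <- vapply(seq_len(nrow(gt_m)), function(j)
        if (used[j]) -1 else iou_pair(as.numeric(sub[i, c("x1", "y1", "x2", "y2")]),
                                      gt_m[j, ]), numeric(1))
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_min) { used[j] <- TRUE; tp <- tp + 1L }
    }
    pr <- rbind(pr, c(r = tp / nrow(gt_m), p = tp / nrow(sub)))
  }
  pr <- pr[order(pr[, "r"], pr[, "p"]), , drop = FALSE]
  rs <- pr[, "r"]; ps <- pr[, "p"]
  ap <- 0; prev_r <- 0
  for (i in seq_along(rs)) {
    p_env <- max(ps[rs >= rs[i]])
    ap <- ap + (rs[i] - prev_r) * p_env
    prev_r <- rs[i]
  }
  unname(ap)
}

# small deterministic random helpers
rand_tensor <- function(C, H, W, seed) {
  set.seed(seed)
  array(rnorm(C * H * W), dim = c(C, H, W))
}

rand_boxes <- function(n, seed, span = 20, size = c(1, 6)) {
  set.seed(seed)
  cx <- runif(n, 0, span); cy <- runif(n, 0, span)
  w <- runif(n, size[1], size[2]); h <- runif(n, size[1], size[2])
  data.frame(x1 = cx - w / 2, y1 = cy - h / 2,
             x2 = cx + w / 2, y2 = cy + h / 2)
}
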