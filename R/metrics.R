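#' Detection and line-fit evaluation metrics
#'
#' Single-class detection metrics (precision, recall, F1, average precision
#' over the precision-recall curve) with VOC-style greedy one-to-one matching
#' at an IoU threshold, and the angular-error / fit-time metrics used to
#' judge crop-row line fits: Delta_theta = |atan(a1) - atan(a2)| per row,
#' averaged as n_a = (1/A) sum Delta_theta_i, and mean fit time
#' t = (1/M) sum t_m.
#'
#' @name metrics
NULL

iou_xyxy <- function(a, b) {
  iw <- pmax(0, pmin(a[3], b[3]) - pmax(a[1], b[1]))
  ih <- pmax(0, pmin(a[4], b[4]) - pmax(a[2], b[2]))
  inter <- iw * ih
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

# IoU of one box against every row of a gt matrix
iou_one_vs_many <- function(a, gt_m) {
  iw <- pmax(0, pmin(a[3], gt_m[, 3]) - pmax(a[1], gt_m[, 1]))
  ih <- pmax(0, pmin(a[4], gt_m[, 4]) - pmax(a[2], gt_m[, 2]))
  inter <- iw * ih
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_g <- (gt_m[, 3] - gt_m[, 1]) * (gt_m[, 4] - gt_m[, 2])
  inter / (area_a + area_g - inter)
}

box_matrix <- function(dets) {
  dets <- as.data.frame(dets)
  m <- as.matrix(dets[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# greedy matching in descending confidence: each detection claims the
# highest-IoU unmatched ground truth with IoU >= iou_min
greedy_match <- function(det_m, det_conf, gt_m, iou_min) {
  nd <- nrow(det_m); ng <- nrow(gt_m)
  matched_gt <- rep(FALSE, ng)
  is_tp <- rep(FALSE, nd)
  ord <- order(det_conf, decreasing = TRUE)
  for (i in ord) {
    if (ng == 0L) break
    ious <- iou_one_vs_many(det_m[i, ], gt_m)
    ious[matched_gt] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_min) {
      matched_gt[j] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  list(is_tp = is_tp, matched_gt = matched_gt, order = ord)
}

#' Match detections to ground-truth boxes and count TP/FP/FN
#'
#' Detections at or above `conf_min` are matched greedily in descending
#' confidence; each claims the unmatched ground-truth box of highest IoU,
#' provided IoU >= `iou_min` (one-to-one matching).
#'
#' @param dets data.frame with x1, y1, x2, y2 and conf
#' @param gts data.frame with x1, y1, x2, y2
#' @param iou_min IoU threshold (default 0.5)
#' @param conf_min confidence cutoff applied before matching (default 0)
#' @return list of class `confusion_counts` with TP, FP, FN
#' @export
match_detections <- function(dets, gts, iou_min = 0.5, conf_min = 0) {
  dets <- detections_df(dets)
  dets <- dets[dets$conf >= conf_min, , drop = FALSE]
  gt_m <- if (nrow(as.data.frame(gts))) box_matrix(gts) else
    matrix(0, 0, 4)
  det_m <- if (nrow(dets)) box_matrix(dets) else matrix(0, 0, 4)
  mm <- greedy_match(det_m, dets$conf, gt_m, iou_min)
  tp <- sum(mm$is_tp)
  structure(list(TP = tp, FP = nrow(det_m) - tp, FN = nrow(gt_m) - tp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP = %d, FP = %d, FN = %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts, as percentages
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), each x 100. A zero
#' denominator yields 0 with a warning.
#'
#' @param counts a [match_detections()] result (or list with TP, FP, FN)
#' @return named numeric vector c(precision, recall, f1) in percent
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) stop("confusion counts must be nonnegative")
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator); using 0"); 0 }
    else num / den
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = 100 * p, recall = 100 * r, f1 = 100 * f1)
}

#' Average precision over the precision-recall curve
#'
#' Detections are ranked by confidence; sweeping the rank cutoff traces the
#' precision-recall curve under the greedy one-to-one matching of
#' [match_detections()]. AP is the area under the monotone (nonincreasing)
#' precision envelope, integrated over recall with all-points interpolation;
#' `interpolation = "101"` instead averages the envelope at 101 evenly spaced
#' recall values.
#'
#' @param dets data.frame with x1, y1, x2, y2, conf
#' @param gts data.frame of ground-truth boxes; must be nonempty
#' @param iou_min IoU threshold (default 0.5)
#' @param interpolation "all" (default) or "101"
#' @return list of class `pr_curve`: `precision`, `recall` (cumulative,
#'   ranked), `ap` in [0, 1]
#' @export
average_precision <- function(dets, gts, iou_min = 0.5,
                              interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  gts <- as.data.frame(gts)
  if (nrow(gts) == 0L) stop("average precision undefined without ground truth")
  dets <- detections_df(dets)
  if (nrow(dets) == 0L)
    return(structure(list(precision = numeric(0), recall = numeric(0), ap = 0),
                     class = "pr_curve"))
  mm <- greedy_match(box_matrix(dets), dets$conf, box_matrix(gts), iou_min)
  tp_ranked <- mm$is_tp[mm$order]
  cum_tp <- cumsum(tp_ranked)
  k <- seq_along(tp_ranked)
  precision <- cum_tp / k
  recall <- cum_tp / nrow(gts)
  # monotone precision envelope over recall
  env_p <- rev(cummax(rev(precision)))
  if (interpolation == "all") {
    prev_r <- c(0, recall[-length(recall)])
    ap <- sum((recall - prev_r) * env_p)
  } else {
    grid <- seq(0, 1, length.out = 101L)
    ap <- mean(vapply(grid, function(r) {
      ok <- recall >= r
      if (any(ok)) max(env_p[ok]) else 0
    }, numeric(1)))
  }
  structure(list(precision = precision, recall = recall, ap = ap),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve over %d ranked detections: AP = %.4f\n",
              length(x$recall), x$ap))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(c(0, x$recall), c(1, x$precision), type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision", ...)
  invisible(x)
}

#' Angular difference between two line slopes
#'
#' Delta_theta = |atan(a1) - atan(a2)|, a pseudometric on slopes (vertical
#' lines may be passed as Inf, giving an angle of pi/2). Vectorised.
#'
#' @param a1,a2 numeric slopes
#' @return list with `radians` and `degrees` vectors
#' @export
angular_difference <- function(a1, a2) {
  rad <- abs(atan(a1) - atan(a2))
  list(radians = rad, degrees = rad * 180 / pi)
}

#' Aggregate per-row angular errors and per-image fit times
#'
#' Mean angular error n_a = (1/A) sum_i Delta_theta_i over A rows and mean
#' fit time t = (1/M) sum_m t_m over M images.
#'
#' @param delta_theta_deg per-row angular errors, degrees
#' @param times_ms per-image fit times, milliseconds (optional)
#' @return list of class `line_eval`: `n_a_deg`, `mean_time_ms`, `A`, `M`,
#'   plus the raw vectors
#' @export
aggregate_line_eval <- function(delta_theta_deg, times_ms = numeric(0)) {
  if (length(delta_theta_deg) < 1L) stop("no angular errors to aggregate")
  structure(list(n_a_deg = mean(delta_theta_deg),
                 mean_time_ms = if (length(times_ms)) mean(times_ms) else NA_real_,
                 A = length(delta_theta_deg),
                 M = length(times_ms),
                 delta_theta_deg = delta_theta_deg,
                 times_ms = times_ms),
            class = "line_eval")
}

#' @export
print.line_eval <- function(x, ...) {
  cat(sprintf("Line-fit evaluation over %d rows: mean angular error %.4f deg\n",
              x$A, x$n_a_deg))
  if (!is.na(x$mean_time_ms))
    cat(sprintf("  mean fit time over %d images: %.2f ms\n", x$M,
                x$mean_time_ms))
  invisible(x)
}
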