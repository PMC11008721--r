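#' Crop-row line fitting and navigation-line construction
#'
#' Detected plant bounding boxes are reduced to centre points, split into a
#' left and a right crop row, screened for missing-plant gaps, and each row is
#' fitted by weighted least squares: the objective is
#' S = sum_i w_i (y_i - (m x_i + b))^2, solved through the 2x2 weighted normal
#' equations. Weights downweight points far from the row centre via a Gaussian
#' kernel of the robust-scaled perpendicular residual from a preliminary
#' unweighted fit. The central navigation line passes through the intersection
#' of the two row lines with slope m_c = tan((atan(m1) + atan(m2)) / 2), the
#' tangent of the mean of the two line angles.
#'
#' @name rowfit
NULL

detections_df <- function(dets) {
  if (is.null(dets) || nrow(as.data.frame(dets)) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), conf = numeric(0)))
  dets <- as.data.frame(dets)
  stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(dets)))
  if (is.null(dets$conf)) dets$conf <- 1
  if (!all(is.finite(as.matrix(dets[, c("x1", "y1", "x2", "y2")]))))
    stop("detection coordinates must be finite")
  if (any(dets$x2 <= dets$x1) || any(dets$y2 <= dets$y1))
    stop("detection boxes must have strictly positive area")
  dets
}

#' Plant centre points from detection boxes
#'
#' @param dets data.frame with columns x1, y1, x2, y2 (pixel corners, origin
#'   top-left, y down) and optionally conf
#' @return data.frame with columns x, y (box midpoints), weight (1), gap
#'   (FALSE), order preserved; empty input gives an empty frame
#' @export
centers_from_detections <- function(dets) {
  dets <- detections_df(dets)
  data.frame(x = (dets$x1 + dets$x2) / 2, y = (dets$y1 + dets$y2) / 2,
             weight = rep(1, nrow(dets)), gap = rep(FALSE, nrow(dets)))
}

point_in_polygon <- function(px, py, poly) {
  # even-odd ray casting; poly is a matrix/data.frame with columns x, y
  xp <- poly[, 1]; yp <- poly[, 2]
  n <- length(xp)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (yp[i] > py) != (yp[j] > py)
    xint <- (xp[j] - xp[i]) * (py - yp[i]) / (yp[j] - yp[i]) + xp[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Partition plant points into left and right crop rows
#'
#' Default region: points inside the outer `margin` fraction of the image
#' border are discarded, the rest are split at the vertical midline. A custom
#' region may be given as `list(left = poly, right = poly)` with each polygon
#' a two-column (x, y) matrix; points outside both polygons are discarded.
#'
#' @param points data.frame from [centers_from_detections()]
#' @param width,height image size in pixels
#' @param margin border fraction to discard (default 0.05)
#' @param region optional polygon region list
#' @return list of class `row_assignment` with elements left, right,
#'   discarded (data.frames) and region description
#' @export
assign_rows <- function(points, width, height, margin = 0.05, region = NULL) {
  stopifnot(width > 0, height > 0)
  if (is.null(region)) {
    mx <- margin * width; my <- margin * height
    keep <- points$x >= mx & points$x <= width - mx &
      points$y >= my & points$y <= height - my
    left <- keep & points$x < width / 2
    right <- keep & !left
    desc <- sprintf("x-split at %.1f, margin %.0f%%", width / 2, margin * 100)
  } else {
    stopifnot(is.list(region), !is.null(region$left), !is.null(region$right))
    left <- point_in_polygon(points$x, points$y, region$left)
    right <- !left & point_in_polygon(points$x, points$y, region$right)
    keep <- left | right
    desc <- "polygon region"
  }
  structure(list(left = points[left, , drop = FALSE],
                 right = points[right, , drop = FALSE],
                 discarded = points[!keep, , drop = FALSE],
                 region = desc),
            class = "row_assignment")
}

#' Flag missing-plant gaps along a crop row
#'
#' Points are ordered by y ascending (ties by x); the within-row separation
#' D_{i,i+1} = |y_{i+1} - y_i| is compared against the threshold `d_thresh`
#' and the downstream point i+1 of each exceeding pair is flagged as the
#' start of a missing-plant gap.
#'
#' @param points data.frame with x, y
#' @param d_thresh gap threshold in pixels, > 0
#' @return list of class `gap_report`: `d_thresh`, `order` (sorting
#'   permutation), `distances` (D_{i,i+1} in sorted order), `flagged`
#'   (indices into the input points). Fewer than 2 points gives an empty
#'   report.
#' @export
detect_gaps <- function(points, d_thresh) {
  stopifnot(d_thresh > 0)
  n <- nrow(points)
  if (n < 2L)
    return(structure(list(d_thresh = d_thresh, order = seq_len(n),
                          distances = numeric(0), flagged = integer(0)),
                     class = "gap_report"))
  ord <- order(points$y, points$x)
  d <- diff(points$y[ord])
  flagged <- ord[which(d > d_thresh) + 1L]
  structure(list(d_thresh = d_thresh, order = ord, distances = d,
                 flagged = flagged),
            class = "gap_report")
}

# perpendicular distance of points to a line in y = m x + b form
point_line_distance <- function(points, line) {
  abs(line$m * points$x - points$y + line$b) / sqrt(line$m^2 + 1)
}

#' Centre-proximity weights for row points
#'
#' w_i = exp(-d_i^2 / (2 sigma^2)) with d_i the perpendicular distance of
#' point i to the reference line (a preliminary unweighted fit standing in
#' for the row centre) and sigma = max(1.4826 * median(|d_i|), sigma_min),
#' the median-absolute-deviation scale with a floor. Weights lie in (0, 1]
#' and decrease monotonically with distance; collinear points all get 1.
#'
#' @param points data.frame with x, y
#' @param reference a [weighted_least_squares()] fit
#' @param sigma_min scale floor in pixels (default 1)
#' @return `points` with the `weight` column replaced
#' @export
compute_weights <- function(points, reference, sigma_min = 1) {
  d <- point_line_distance(points, reference)
  sigma <- max(1.4826 * stats::median(abs(d)), sigma_min)
  points$weight <- exp(-d^2 / (2 * sigma^2))
  points
}

# closed-form weighted fit of v = m u + b via the 2x2 normal equations
solve_wls <- function(u, v, w) {
  sw <- sum(w); su <- sum(w * u); suu <- sum(w * u^2)
  sv <- sum(w * v); suv <- sum(w * u * v)
  det <- suu * sw - su^2
  scale <- max(suu * sw, su^2, 1)
  if (abs(det) <= 1e-12 * scale) return(NULL)
  m <- (suv * sw - su * sv) / det
  b <- (suu * sv - su * suv) / det
  c(m = m, b = b)
}

#' Weighted least-squares fit of a crop-row line
#'
#' Minimises S = sum_i w_i (y_i - (m x_i + b))^2 by solving the weighted
#' normal equations in closed form. Crop rows in forward-facing images are
#' near-vertical, which makes the y-on-x regression ill-conditioned, so when
#' the squared robust spread (median absolute deviation) of x is below 10%
#' of that of y the fit is performed internally as x on y and the parameters
#' are converted back to the y = m x + b form for reporting (an exactly
#' vertical row is an error). The robust spread, rather than the raw
#' variance, decides the form so that isolated clutter points cannot flip a
#' near-vertical row onto the ill-conditioned axis.
#'
#' @param points data.frame with x, y and optionally weight (default 1);
#'   weights must be nonnegative with positive sum
#' @param weights optional weight vector overriding `points$weight`
#' @param form "auto" (default) selects the internal fitting axis by the
#'   robust-spread rule; "y_of_x" or "x_of_y" forces it
#' @return list of class `fitted_line`: slope `m`, intercept `b` (always in
#'   y-of-x form), `form` (internal fitting route, "y_of_x" or "x_of_y"),
#'   `n_points` (points with positive weight), weighted residual sum `S`
#'   (in the fitted form's residuals)
#' @export
weighted_least_squares <- function(points, weights = NULL,
                                   form = c("auto", "y_of_x", "x_of_y")) {
  form <- match.arg(form)
  w <- if (!is.null(weights)) weights
       else if (!is.null(points$weight)) points$weight else rep(1, nrow(points))
  stopifnot(length(w) == nrow(points))
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) <= 0) stop("weights must have positive sum")
  use <- w > 0
  x <- points$x[use]; y <- points$y[use]; wu <- w[use]
  if (length(x) < 2L) stop("need at least 2 points with positive weight")
  if (form == "auto") {
    # robust spread (MAD) so a few clutter points cannot flip the fitting form
    sx2 <- stats::mad(x)^2
    sy2 <- stats::mad(y)^2
    if (sx2 == 0 && sy2 == 0) {
      sx2 <- stats::var(x); sy2 <- stats::var(y)   # duplicate-heavy fallback
    }
    form <- if (sx2 < 0.1 * sy2) "x_of_y" else "y_of_x"
  }
  if (form == "y_of_x") {
    sol <- solve_wls(x, y, wu)
    if (is.null(sol)) {
      sol <- solve_wls(y, x, wu)  # fall back to the transposed form
      if (is.null(sol)) stop("degenerate geometry: points admit no line fit")
      form <- "x_of_y"
    }
  } else {
    sol <- solve_wls(y, x, wu)
    if (is.null(sol)) {
      sol <- solve_wls(x, y, wu)
      if (is.null(sol)) stop("degenerate geometry: points admit no line fit")
      form <- "y_of_x"
    }
  }
  if (form == "y_of_x") {
    m <- sol[["m"]]; b <- sol[["b"]]
    S <- sum(wu * (y - (m * x + b))^2)
  } else {
    if (sol[["m"]] == 0) stop("exactly vertical row: slope not representable")
    m <- 1 / sol[["m"]]; b <- -sol[["b"]] / sol[["m"]]
    S <- sum(wu * (x - (sol[["m"]] * y + sol[["b"]]))^2)
  }
  structure(list(m = m, b = b, form = form, n_points = length(x), S = S),
            class = "fitted_line")
}

#' @export
print.fitted_line <- function(x, ...) {
  cat(sprintf("Fitted line: y = %.4f x + %.4f  (%s fit, n = %d, S = %.4g)\n",
              x$m, x$b, x$form, x$n_points, x$S))
  invisible(x)
}

#' Central navigation line between two fitted crop-row lines
#'
#' The intersection solves m1 x + b1 = m2 x + b2; the central slope is the
#' tangent of the mean of the two line angles,
#' m_c = tan((atan(m1) + atan(m2)) / 2), and b_c = y_i - m_c x_i anchors the
#' line at the intersection. Lines with |m1 - m2| < 1e-9 are treated as
#' parallel: m_c = m1 and b_c = (b1 + b2) / 2 (the midline).
#'
#' @param line_left,line_right [weighted_least_squares()] fits or numeric
#'   c(m, b) pairs
#' @return list of class `navigation_line`: m1, b1, m2, b2, xi, yi (NA when
#'   parallel), mc, bc, parallel flag
#' @export
navigation_line <- function(line_left, line_right) {
  as_mb <- function(l) if (inherits(l, "fitted_line")) c(l$m, l$b) else as.numeric(l)
  l1 <- as_mb(line_left); l2 <- as_mb(line_right)
  m1 <- l1[1]; b1 <- l1[2]; m2 <- l2[1]; b2 <- l2[2]
  if (abs(m1 - m2) < 1e-9) {
    out <- list(m1 = m1, b1 = b1, m2 = m2, b2 = b2, xi = NA_real_,
                yi = NA_real_, mc = m1, bc = (b1 + b2) / 2, parallel = TRUE)
  } else {
    xi <- (b2 - b1) / (m1 - m2)
    yi <- m1 * xi + b1
    mc <- tan((atan(m1) + atan(m2)) / 2)
    out <- list(m1 = m1, b1 = b1, m2 = m2, b2 = b2, xi = xi, yi = yi,
                mc = mc, bc = yi - mc * xi, parallel = FALSE)
  }
  structure(out, class = "navigation_line")
}

#' @export
print.navigation_line <- function(x, ...) {
  cat(sprintf("Navigation line: y = %.4f x + %.4f", x$mc, x$bc))
  if (x$parallel) cat("  (rows parallel: midline)")
  else cat(sprintf("  through intersection (%.2f, %.2f)", x$xi, x$yi))
  cat("\n")
  invisible(x)
}

fit_one_row <- function(pts, d_thresh, drop_gap_points, sigma_min, row_name) {
  if (nrow(pts) < 2L)
    stop("fewer than 2 usable points in the ", row_name, " row")
  dt <- d_thresh
  if (is.null(dt)) {
    sp <- diff(sort(pts$y))
    dt <- max(1.8 * stats::median(sp), 1e-6)
  }
  gaps <- detect_gaps(pts, dt)
  pts$gap[gaps$flagged] <- TRUE
  fit_pts <- if (drop_gap_points && length(gaps$flagged)) {
    kept <- pts[!pts$gap, , drop = FALSE]
    if (nrow(kept) < 2L)
      stop("fewer than 2 usable points in the ", row_name,
           " row after dropping gap-flagged points")
    kept
  } else pts
  prelim <- weighted_least_squares(fit_pts, weights = rep(1, nrow(fit_pts)))
  fit_pts <- compute_weights(fit_pts, prelim, sigma_min = sigma_min)
  line <- weighted_least_squares(fit_pts)
  list(line = line, prelim = prelim, gaps = gaps, points = fit_pts)
}

#' Fit both crop rows and the central navigation line
#'
#' Full pipeline: box centres, region assignment, gap flagging, preliminary
#' unweighted fit, centre-proximity weighting, weighted refit per row, and
#' navigation-line construction. Gap-flagged points are retained in the fit
#' by default (a gap start is a real plant); set `drop_gap_points = TRUE` to
#' exclude them.
#'
#' @param dets data.frame of detections (x1, y1, x2, y2, optional conf)
#' @param image_width,image_height image size in pixels
#' @param d_thresh gap threshold in pixels; NULL (default) uses 1.8x the
#'   median within-row y-spacing of each row
#' @param drop_gap_points exclude gap-flagged points from fitting?
#' @param margin border fraction discarded before the midline split
#' @param region optional polygon region (see [assign_rows()])
#' @param sigma_min weight-kernel scale floor in pixels
#' @return object of class `crop_row_fit` with components `nav`
#'   ([navigation_line()]), `lines$left/right` (weighted fits),
#'   `prelim$left/right` (unweighted fits), `gaps$left/right`
#'   ([detect_gaps()] reports), `points` (the [assign_rows()] partition with
#'   final weights), and `config`
#' @examples
#' sc <- generate_scene(scene_config(seed = 7, render = FALSE))
#' fit <- fit_crop_rows(sc$boxes, sc$config$width, sc$config$height)
#' coef(fit)
#' @export
fit_crop_rows <- function(dets, image_width, image_height, d_thresh = NULL,
                          drop_gap_points = FALSE, margin = 0.05,
                          region = NULL, sigma_min = 1) {
  pts <- centers_from_detections(dets)
  asg <- assign_rows(pts, image_width, image_height, margin = margin,
                     region = region)
  left <- fit_one_row(asg$left, d_thresh, drop_gap_points, sigma_min, "left")
  right <- fit_one_row(asg$right, d_thresh, drop_gap_points, sigma_min, "right")
  nav <- navigation_line(left$line, right$line)
  asg$left <- left$points; asg$right <- right$points
  structure(list(nav = nav,
                 lines = list(left = left$line, right = right$line),
                 prelim = list(left = left$prelim, right = right$prelim),
                 gaps = list(left = left$gaps, right = right$gaps),
                 points = asg,
                 config = list(image_width = image_width,
                               image_height = image_height,
                               d_thresh = d_thresh,
                               drop_gap_points = drop_gap_points,
                               margin = margin, sigma_min = sigma_min),
                 call = match.call()),
            class = "crop_row_fit")
}

#' @export
print.crop_row_fit <- function(x, ...) {
  cat("Crop-row fit\n")
  cat(sprintf("  left : y = %8.3f x + %9.3f  (n = %d, %d gap-flagged)\n",
              x$lines$left$m, x$lines$left$b, x$lines$left$n_points,
              length(x$gaps$left$flagged)))
  cat(sprintf("  right: y = %8.3f x + %9.3f  (n = %d, %d gap-flagged)\n",
              x$lines$right$m, x$lines$right$b, x$lines$right$n_points,
              length(x$gaps$right$flagged)))
  cat(sprintf("  nav  : y = %8.3f x + %9.3f  (angle %.2f deg%s)\n",
              x$nav$mc, x$nav$bc, atan(x$nav$mc) * 180 / pi,
              if (x$nav$parallel) ", rows parallel" else ""))
  invisible(x)
}

#' @export
summary.crop_row_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              rows = data.frame(
                row = c("left", "right"),
                n = c(object$lines$left$n_points, object$lines$right$n_points),
                slope = c(object$lines$left$m, object$lines$right$m),
                intercept = c(object$lines$left$b, object$lines$right$b),
                gap_flagged = c(length(object$gaps$left$flagged),
                                length(object$gaps$right$flagged)),
                rms_residual = c(sqrt(mean(res$left^2)),
                                 sqrt(mean(res$right^2)))),
              nav_angle_deg = atan(object$nav$mc) * 180 / pi)
  class(out) <- "summary.crop_row_fit"
  out
}

#' @export
print.summary.crop_row_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-row summary:\n")
  print(x$rows, row.names = FALSE)
  cat(sprintf("\nNavigation heading: %.3f deg from horizontal\n",
              x$nav_angle_deg))
  invisible(x)
}

#' @export
coef.crop_row_fit <- function(object, ...) {
  c(m_left = object$lines$left$m, b_left = object$lines$left$b,
    m_right = object$lines$right$m, b_right = object$lines$right$b,
    m_nav = object$nav$mc, b_nav = object$nav$bc)
}

#' Predict y-coordinates along a fitted line
#'
#' @param object a `crop_row_fit`
#' @param x numeric vector of image x-coordinates
#' @param line which line to evaluate: "nav" (default), "left" or "right"
#' @param ... unused
#' @return numeric vector y = m x + b
#' @export
predict.crop_row_fit <- function(object, x, line = c("nav", "left", "right"),
                                 ...) {
  line <- match.arg(line)
  p <- switch(line, nav = c(object$nav$mc, object$nav$bc),
              left = c(object$lines$left$m, object$lines$left$b),
              right = c(object$lines$right$m, object$lines$right$b))
  p[1] * x + p[2]
}

#' @export
residuals.crop_row_fit <- function(object, ...) {
  list(left = point_line_distance(object$points$left, object$lines$left),
       right = point_line_distance(object$points$right, object$lines$right))
}

#' @export
plot.crop_row_fit <- function(x, image = NULL, ...) {
  w <- x$config$image_width; h <- x$config$image_height
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), xlab = "x (px)",
                 ylab = "y (px)", asp = 1, ...)
  if (!is.null(image)) {
    graphics::rasterImage(grDevices::as.raster(image), 0, h, w, 0)
  }
  graphics::points(x$points$left$x, x$points$left$y, col = "forestgreen",
                   pch = 19, cex = 0.7)
  graphics::points(x$points$right$x, x$points$right$y, col = "darkgreen",
                   pch = 17, cex = 0.7)
  for (l in list(x$lines$left, x$lines$right))
    graphics::abline(a = l$b, b = l$m, col = "red", lwd = 2)
  graphics::abline(a = x$nav$bc, b = x$nav$mc, col = "blue", lwd = 2)
  invisible(x)
}
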