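#' Synthetic two-row field scenes with known ground truth
#'
#' Emulates forward-facing images of two converging crop rows of blob-like
#' plants on a soil background, with controllable missing-plant gaps, weed
#' clutter, plant-placement jitter and an axial illumination falloff (the
#' far end of a floodlit night scene being darker). Every generated quantity
#' (image, boxes, true row lines, true navigation line, gap positions) is a
#' pure function of the configuration and its seed, so detection, row
#' fitting, enhancement and the evaluation metrics are all testable without
#' a field dataset. Plants are isotropic Gaussian-profile green blobs:
#' geometry and photometry, not botany, drive every downstream algorithm.
#'
#' @name synthfield
NULL

#' Configuration of a synthetic field scene
#'
#' Row lines are specified by their x-position at the top (y = 0) and bottom
#' (y = height - 1) of the image, i.e. in the x-on-y form natural for
#' near-vertical rows; the ground-truth slope/intercept in y = m x + b form
#' is derived. Defaults give two rows converging toward a vanishing point
#' above the image, 20 plants per row, no gaps, no weeds and no falloff.
#'
#' @param width,height image size in pixels
#' @param left_x,right_x length-2 vectors c(x_top, x_bottom) of each row line
#' @param plants_per_row plants seeded per row before gaps
#' @param plant_radius blob radius in pixels (gt boxes are 2 x radius square)
#' @param spacing within-row plant spacing along y, pixels; NULL spreads the
#'   plants evenly over the usable height. Must exceed 2 x plant_radius.
#' @param gap_left,gap_right integer indices (1-based along the row, top to
#'   bottom) of plants removed to create missing-plant gaps
#' @param weeds number of off-row weed blobs
#' @param jitter standard deviation, pixels, of Gaussian plant-placement
#'   jitter (0 puts every plant centre exactly on its row line)
#' @param illum_range c(top, bottom) multiplicative illumination factors;
#'   c(0.2, 1) emulates a strong near-light falloff, c(1, 1) none
#' @param illum_profile exponent p of the axial falloff,
#'   factor(y) = min + (max - min) * (y / (H - 1))^p. p = 1 is a linear
#'   ramp; a floodlight at the bottom edge is better emulated by p > 1
#'   (inverse-square-like: most of the frame sits near the dark floor and
#'   brightness rises sharply toward the source)
#' @param render draw the image? FALSE produces geometry only (boxes, lines,
#'   gaps), which is sufficient for fitting studies
#' @param seed RNG seed making the scene deterministic
#' @return list of class `scene_config`
#' @export
scene_config <- function(width = 640, height = 480,
                         left_x = c(270, 200), right_x = c(370, 440),
                         plants_per_row = 20, plant_radius = 10,
                         spacing = NULL, gap_left = integer(0),
                         gap_right = integer(0), weeds = 0, jitter = 0,
                         illum_range = c(1, 1), illum_profile = 1,
                         render = TRUE, seed = 1) {
  stopifnot(width >= 16, height >= 16, plants_per_row >= 2, plant_radius > 0,
            length(illum_range) == 2L, all(illum_range > 0),
            all(illum_range <= 1), illum_profile > 0)
  usable <- height - 2 * (plant_radius + 2)
  if (is.null(spacing)) spacing <- usable / (plants_per_row - 1)
  if (spacing <= 2 * plant_radius)
    stop("plants would overlap: spacing must exceed 2 x plant_radius")
  if ((plants_per_row - 1) * spacing > usable)
    stop("plants_per_row x spacing exceeds the image height")
  structure(list(width = width, height = height, left_x = left_x,
                 right_x = right_x, plants_per_row = plants_per_row,
                 plant_radius = plant_radius, spacing = spacing,
                 gap_left = as.integer(gap_left),
                 gap_right = as.integer(gap_right),
                 weeds = weeds, jitter = jitter, illum_range = illum_range,
                 illum_profile = illum_profile,
                 render = isTRUE(render), seed = seed),
            class = "scene_config")
}

# y = m x + b parameters of the line through (x_top, 0) and (x_bottom, H-1)
line_from_anchors <- function(xs, height) {
  dx <- xs[2] - xs[1]
  if (abs(dx) < 1e-9) stop("exactly vertical row lines are not representable")
  m <- (height - 1) / dx
  c(m = m, b = -m * xs[1])
}

soil_color <- c(0.32, 0.25, 0.17)
plant_color <- c(0.20, 0.58, 0.16)
weed_color <- c(0.30, 0.48, 0.20)

draw_blob <- function(img, cx, cy, radius, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r3 <- ceiling(3 * radius / 1.8)
  rows <- max(1, floor(cy) - r3 + 1):min(h, ceiling(cy) + r3 + 1)
  cols <- max(1, floor(cx) - r3 + 1):min(w, ceiling(cx) + r3 + 1)
  if (!length(rows) || !length(cols)) return(img)
  yy <- rows - 1; xx <- cols - 1
  d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
  a <- exp(-d2 / (2 * (radius / 1.8)^2))
  for (ch in 1:3)
    img[rows, cols, ch] <- img[rows, cols, ch] * (1 - a) + color[ch] * a
  img
}

#' Generate a synthetic two-row field scene
#'
#' Plants are placed at fixed y-spacing along each true row line (gap indices
#' omitted), jittered if configured, and weeds are scattered away from both
#' rows. Ground-truth boxes are squares of side 2 x plant_radius centred on
#' the (jittered) plant positions; the multiplicative illumination gradient
#' is applied last. Deterministic given the config (same seed, bit-identical
#' output).
#'
#' @param cfg a [scene_config()]
#' @return list of class `synthetic_scene`: `image` (H x W x 3 raster, or
#'   NULL when `render = FALSE`), `boxes` (data.frame x1, y1, x2, y2, conf,
#'   row), `lines` (list left/right, each c(m, b)), `nav` (ground-truth
#'   [navigation_line()]), `gaps` (list left/right of omitted indices),
#'   `config`
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width; r <- cfg$plant_radius
  lineL <- line_from_anchors(cfg$left_x, H)
  lineR <- line_from_anchors(cfg$right_x, H)
  y0 <- r + 2
  ys <- y0 + (seq_len(cfg$plants_per_row) - 1) * cfg$spacing

  place_row <- function(line, gaps, row_name) {
    keep <- setdiff(seq_along(ys), gaps)
    y <- ys[keep]
    x <- (y - line[["b"]]) / line[["m"]]
    if (cfg$jitter > 0) {
      x <- x + stats::rnorm(length(x), 0, cfg$jitter)
      y <- y + stats::rnorm(length(y), 0, cfg$jitter)
    }
    data.frame(x = x, y = y, row = row_name)
  }
  pl <- place_row(lineL, cfg$gap_left, "left")
  pr <- place_row(lineR, cfg$gap_right, "right")
  plants <- rbind(pl, pr)

  weeds <- NULL
  if (cfg$weeds > 0) {
    n <- 0L; tries <- 0L
    wx <- numeric(0); wy <- numeric(0)
    while (n < cfg$weeds && tries < 100L * cfg$weeds) {
      tries <- tries + 1L
      x <- stats::runif(1, 0.06 * W, 0.94 * W)
      y <- stats::runif(1, 0.06 * H, 0.94 * H)
      dl <- abs(x - (y - lineL[["b"]]) / lineL[["m"]])
      dr <- abs(x - (y - lineR[["b"]]) / lineR[["m"]])
      if (min(dl, dr) > 2.5 * r) { wx <- c(wx, x); wy <- c(wy, y); n <- n + 1L }
    }
    weeds <- data.frame(x = wx, y = wy)
  }

  boxes <- data.frame(x1 = plants$x - r, y1 = plants$y - r,
                      x2 = plants$x + r, y2 = plants$y + r,
                      conf = 1, row = plants$row)

  img <- NULL
  if (cfg$render) {
    img <- array(rep(soil_color, each = H * W), dim = c(H, W, 3))
    tex <- matrix(stats::runif(H * W, -0.02, 0.02), H, W)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tex
    for (i in seq_len(nrow(plants)))
      img <- draw_blob(img, plants$x[i], plants$y[i], r, plant_color)
    if (!is.null(weeds))
      for (i in seq_len(nrow(weeds)))
        img <- draw_blob(img, weeds$x[i], weeds$y[i], r / 2, weed_color)
    fall <- cfg$illum_range[1] + (cfg$illum_range[2] - cfg$illum_range[1]) *
      ((seq_len(H) - 1) / (H - 1))^cfg$illum_profile
    for (ch in 1:3) img[, , ch] <- img[, , ch] * fall
    img <- clamp01(img)
  }

  structure(list(image = img, boxes = boxes,
                 lines = list(left = lineL, right = lineR),
                 nav = navigation_line(lineL, lineR),
                 gaps = list(left = cfg$gap_left, right = cfg$gap_right),
                 weeds = weeds, config = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene %dx%d: %d plants (%d/%d gaps), %d weeds%s\n",
              x$config$width, x$config$height, nrow(x$boxes),
              length(x$gaps$left), length(x$gaps$right),
              if (is.null(x$weeds)) 0L else nrow(x$weeds),
              if (is.null(x$image)) ", not rendered" else ""))
  cat(sprintf("  true nav line: y = %.4f x + %.4f\n", x$nav$mc, x$nav$bc))
  invisible(x)
}

#' Perturb ground-truth boxes into realistic detections
#'
#' Each ground-truth box centre is jittered by an isotropic Gaussian, the box
#' is dropped with probability `p_miss`, and `n_false` clutter boxes of plant
#' size are scattered uniformly inside the usable image area. Confidences
#' are drawn uniformly in (0.3, 1).
#'
#' @param scene a [generate_scene()] result
#' @param sigma_center centre jitter standard deviation, pixels
#' @param p_miss per-box miss probability in [0, 1]
#' @param n_false number of clutter (false-positive) boxes
#' @param seed RNG seed
#' @return data.frame of detections (x1, y1, x2, y2, conf)
#' @export
perturb_detections <- function(scene, sigma_center = 0, p_miss = 0,
                               n_false = 0, seed = 1) {
  stopifnot(p_miss >= 0, p_miss <= 1, sigma_center >= 0, n_false >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- scene$boxes
  W <- scene$config$width; H <- scene$config$height
  r <- scene$config$plant_radius
  keep <- stats::runif(nrow(b)) >= p_miss
  b <- b[keep, c("x1", "y1", "x2", "y2"), drop = FALSE]
  if (nrow(b)) {
    dx <- stats::rnorm(nrow(b), 0, sigma_center)
    dy <- stats::rnorm(nrow(b), 0, sigma_center)
    b$x1 <- b$x1 + dx; b$x2 <- b$x2 + dx
    b$y1 <- b$y1 + dy; b$y2 <- b$y2 + dy
  }
  if (n_false > 0) {
    cx <- stats::runif(n_false, 0.06 * W, 0.94 * W)
    cy <- stats::runif(n_false, 0.06 * H, 0.94 * H)
    b <- rbind(b, data.frame(x1 = cx - r, y1 = cy - r,
                             x2 = cx + r, y2 = cy + r))
  }
  b$conf <- stats::runif(nrow(b), 0.3, 1)
  rownames(b) <- NULL
  b
}

#' An augmentation operation
#'
#' The six single-image operations are color (per-channel additive shift),
#' brightness (global offset), contrast (gain about the image mean), noise
#' (additive Gaussian), rotation (bilinear, about the image centre, border
#' fill) and mirror (horizontal flip); mosaic composites four images into a
#' 2x2 grid. Unset parameters are drawn deterministically from `seed` within
#' the default ranges (hue shift +/-10/255, brightness +/-0.15, contrast gain
#' 0.8-1.2, noise sd 0.02, rotation +/-10 degrees).
#'
#' @param kind one of "color", "brightness", "contrast", "noise", "rotation",
#'   "mirror", "mosaic"
#' @param params optional list of explicit parameters (`shift`, `offset`,
#'   `gain`, `sigma`, `angle`, `fill`, `size`)
#' @param seed RNG seed used when parameters are drawn
#' @return list of class `augment_op`
#' @export
augment_op <- function(kind = c("color", "brightness", "contrast", "noise",
                                "rotation", "mirror", "mosaic"),
                       params = list(), seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = params, seed = seed),
            class = "augment_op")
}

#' The six single-image augmentation operations
#' @param seed base seed; op i uses seed + i
#' @return list of six [augment_op()]s (mosaic excluded)
#' @export
default_augment_ops <- function(seed = 1) {
  kinds <- c("color", "brightness", "contrast", "noise", "rotation", "mirror")
  lapply(seq_along(kinds), function(i)
    augment_op(kinds[i], seed = seed + i))
}

rotate_bilinear <- function(img, angle_deg, fill = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (angle_deg == 0) return(img)
  th <- angle_deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), w), h, w)
  # inverse map: rotate the output grid by -theta about the centre
  xs <- cos(th) * (xg - cx) + sin(th) * (yg - cy) + cx
  ys <- -sin(th) * (xg - cx) + cos(th) * (yg - cy) + cy
  bilinear_sample(img, xs, ys, fill = fill)
}

resize_bilinear <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sx <- if (out_w > 1) (w - 1) / (out_w - 1) else 0
  sy <- if (out_h > 1) (h - 1) / (out_h - 1) else 0
  xq <- matrix(rep((0:(out_w - 1)) * sx, each = out_h), out_h, out_w)
  yq <- matrix(rep((0:(out_h - 1)) * sy, out_w), out_h, out_w)
  bilinear_sample(img, xq, yq)
}

#' Apply one augmentation operation to an image
#'
#' Deterministic given the op (kind, params, seed); output is clamped to
#' [0, 1]. Mosaic is applied through [augment_mosaic()] and rejects a single
#' image.
#'
#' @param img H x W x 3 raster
#' @param op an [augment_op()]
#' @return augmented H x W x 3 raster
#' @export
augment_image <- function(img, op) {
  img <- as_raster(img)
  stopifnot(inherits(op, "augment_op"))
  if (op$kind == "mosaic")
    stop("mosaic requires a list of 4 images; use augment_mosaic()")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(op$seed)
  p <- op$params
  out <- switch(op$kind,
    color = {
      shift <- if (!is.null(p$shift)) p$shift
               else stats::runif(3, -10 / 255, 10 / 255)
      sweep(img, 3, shift, "+")
    },
    brightness = {
      offset <- if (!is.null(p$offset)) p$offset
                else stats::runif(1, -0.15, 0.15)
      img + offset
    },
    contrast = {
      gain <- if (!is.null(p$gain)) p$gain
              else stats::runif(1, 0.8, 1.2)
      mu <- mean(img)
      (img - mu) * gain + mu
    },
    noise = {
      sigma <- if (!is.null(p$sigma)) p$sigma else 0.02
      if (sigma == 0) img
      else img + array(stats::rnorm(length(img), 0, sigma), dim = dim(img))
    },
    rotation = {
      angle <- if (!is.null(p$angle)) p$angle else stats::runif(1, -10, 10)
      fill <- if (!is.null(p$fill)) p$fill else soil_color
      rotate_bilinear(img, angle, fill = fill)
    },
    mirror = img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  )
  clamp01(out)
}

#' Compose four images into a 2x2 mosaic
#'
#' Each input is resized bilinearly to half the target size and placed in a
#' quadrant (top-left, top-right, bottom-left, bottom-right, in input order).
#'
#' @param imgs list of exactly 4 rasters
#' @param size target c(height, width), default c(640, 640)
#' @return size[1] x size[2] x 3 raster
#' @export
augment_mosaic <- function(imgs, size = c(640, 640)) {
  if (!is.list(imgs) || length(imgs) != 4L)
    stop("mosaic requires exactly 4 input images")
  hh <- size[1] %/% 2L; ww <- size[2] %/% 2L
  out <- array(0, dim = c(2L * hh, 2L * ww, 3L))
  slots <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (i in 1:4) {
    tile <- resize_bilinear(as_raster(imgs[[i]]), hh, ww)
    rs <- (slots[[i]][1] - 1L) * hh + seq_len(hh)
    cs <- (slots[[i]][2] - 1L) * ww + seq_len(ww)
    out[rs, cs, ] <- tile
  }
  clamp01(out)
}

#' Six-way dataset expansion
#'
#' Applies each of the six single-image operations to every input and
#' returns originals plus variants: N inputs become N x 7 images (mosaic is
#' a training-time composite and is excluded from the expansion count).
#' Each (image, op) pair perturbs the op seed so variants differ across
#' images while remaining reproducible.
#'
#' @param images nonempty list of rasters
#' @param ops list of exactly six single-image [augment_op()]s
#' @param seed base seed combined with image and op indices
#' @return list of length `7 * length(images)`: the originals followed by
#'   the augmented variants
#' @export
expand_dataset <- function(images, ops = default_augment_ops(seed), seed = 1) {
  if (!is.list(images) || length(images) == 0L)
    stop("dataset expansion needs at least one input image")
  if (length(ops) != 6L || any(vapply(ops, function(o) o$kind, "") == "mosaic"))
    stop("expansion uses exactly the six single-image operations")
  out <- images
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    variants <- lapply(seq_along(images), function(i) {
      op_i <- augment_op(op$kind, op$params, seed = op$seed + 7919L * i)
      augment_image(images[[i]], op_i)
    })
    out <- c(out, variants)
  }
  out
}

#' Split items into train/validation/test sets
#'
#' Sizes follow the largest-remainder apportionment of N by `ratios`
#' (default 8:1:1); items are shuffled by `seed` first, and the three sets
#' are disjoint and cover the input.
#'
#' @param items list or vector of items (N >= 3)
#' @param ratios positive length-3 ratios
#' @param seed shuffle seed
#' @return list with elements train, val, test
#' @export
split_dataset <- function(items, ratios = c(8, 1, 1), seed = 1) {
  n <- length(items)
  if (n < 3L) stop("need at least 3 items to split")
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  cuts <- cumsum(base)
  list(train = items[idx[seq_len(cuts[1])]],
       val = items[idx[(cuts[1] + 1):cuts[2]]],
       test = items[idx[(cuts[2] + 1):cuts[3]]])
}
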