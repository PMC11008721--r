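test_that("box centres are midpoints with order preserved", {
  dets <- data.frame(x1 = c(0, 3), y1 = c(0, 3), x2 = c(10, 5), y2 = c(20, 5))
  pts <- centers_from_detections(dets)
  expect_equal(pts$x, c(5, 4))
  expect_equal(pts$y, c(10, 4))
  expect_equal(pts$weight, c(1, 1))
  expect_equal(nrow(centers_from_detections(NULL)), 0)
  expect_error(centers_from_detections(
    data.frame(x1 = 5, y1 = 0, x2 = 5, y2 = 2)), "positive area")
})

test_that("row assignment splits at the midline and honours margins", {
  pts <- data.frame(x = c(100, 120, 500, 520, 5), y = rep(100, 5),
                    weight = 1, gap = FALSE)
  asg <- assign_rows(pts, 640, 480)
  expect_equal(sort(asg$left$x), c(100, 120))
  expect_equal(sort(asg$right$x), c(500, 520))
  expect_equal(asg$discarded$x, 5)  # inside the 5% margin band

  one_side <- assign_rows(data.frame(x = c(100, 120), y = c(50, 60),
                                     weight = 1, gap = FALSE), 640, 480)
  expect_equal(nrow(one_side$right), 0)

  # polygon region: only points inside a polygon are kept
  region <- list(left = cbind(c(0, 300, 300, 0), c(0, 0, 480, 480)),
                 right = cbind(c(340, 640, 640, 340), c(0, 0, 480, 480)))
  asg2 <- assign_rows(pts, 640, 480, region = region)
  expect_equal(sort(asg2$left$x), c(5, 100, 120))
  expect_equal(sort(asg2$right$x), c(500, 520))
})

test_that("gap detection flags the downstream point of wide spacings", {
  pts <- data.frame(x = 1:5, y = c(0, 10, 20, 45, 55))
  rep1 <- detect_gaps(pts, 15)
  expect_equal(rep1$distances, c(10, 10, 25, 10))
  expect_equal(rep1$flagged, 4L)          # the point at y = 45

  expect_length(detect_gaps(pts, 30)$flagged, 0)
  expect_equal(sort(detect_gaps(pts, 5)$flagged), 2:5)

  # unsorted input is sorted internally; flags refer to input indices
  shuf <- pts[c(4, 1, 5, 2, 3), ]
  rownames(shuf) <- NULL
  expect_equal(detect_gaps(shuf, 15)$flagged, 1L)

  expect_length(detect_gaps(pts[1, ], 15)$flagged, 0)
})

test_that("centre-proximity weights follow the Gaussian kernel", {
  line <- weighted_least_squares(data.frame(x = 0:5, y = rep(0, 6)))
  col <- compute_weights(data.frame(x = 0:5, y = rep(0, 6)), line)
  expect_equal(col$weight, rep(1, 6))

  # residuals with median 1 give sigma = 1.4826; a point at 10 sigma
  d <- c(rep(c(1, -1), 4), 14.826)
  pts <- data.frame(x = seq_along(d), y = d)
  flat <- structure(list(m = 0, b = 0), class = "fitted_line")
  w <- compute_weights(pts, flat)$weight
  expect_lt(w[9], exp(-40))
  expect_equal(w[1], exp(-1 / (2 * 1.4826^2)))

  # weights are monotone nonincreasing in distance
  ord <- order(abs(d))
  expect_true(all(diff(w[ord]) <= 1e-15))
})

test_that("weighted least squares solves the normal equations", {
  set.seed(21)
  x <- runif(8, 0, 10); y <- 2 * x + 1
  w <- runif(8, 0.1, 2)
  fit <- weighted_least_squares(data.frame(x = x, y = y), weights = w)
  expect_equal(fit$m, 2, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$S, 0, tolerance = 1e-18)

  pts <- data.frame(x = c(0, 1, 2), y = c(0, 1, 4))
  fit2 <- weighted_least_squares(pts)
  # independent normal-equation oracle: stats::lm
  ref <- unname(coef(stats::lm(y ~ x, data = pts)))
  expect_equal(c(fit2$b, fit2$m), ref, tolerance = 1e-9)
  # independent grid-search minimizer of S
  grid <- wls_grid_oracle(pts$x, pts$y, rep(1, 3))
  expect_equal(fit2$m, grid[["m"]], tolerance = 1e-3)
  expect_equal(fit2$b, grid[["b"]], tolerance = 1e-3)

  fit3 <- weighted_least_squares(pts, weights = c(1, 1, 0))
  expect_equal(fit3$m, 1)
  expect_equal(fit3$b, 0)
  expect_equal(fit3$n_points, 2L)
})

test_that("weight scaling leaves the fitted line unchanged", {
  set.seed(4)
  pts <- data.frame(x = runif(10, 0, 10), y = runif(10, 0, 10))
  w <- runif(10, 0.2, 1)
  f1 <- weighted_least_squares(pts, weights = w)
  f2 <- weighted_least_squares(pts, weights = 17.3 * w)
  expect_equal(f1$m, f2$m, tolerance = 1e-12)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
})

test_that("near-vertical rows are fitted on the swapped axis and converted", {
  y <- seq(0, 100, 10)
  x <- 0.1 * y + 5            # x as a function of y: steep in y-of-x form
  fit <- weighted_least_squares(data.frame(x = x, y = y))
  expect_equal(fit$form, "x_of_y")
  expect_equal(fit$m, 10, tolerance = 1e-9)
  expect_equal(fit$b, -50, tolerance = 1e-9)

  expect_error(weighted_least_squares(data.frame(x = rep(3, 5), y = rep(7, 5))),
               "degenerate geometry")
  expect_error(weighted_least_squares(data.frame(x = rep(3, 5),
                                                 y = seq(0, 40, 10))),
               "vertical")
})

test_that("navigation line geometry matches hand computation", {
  nav <- navigation_line(c(1, 0), c(-1, 10))
  expect_equal(nav$xi, 5)
  expect_equal(nav$yi, 5)
  expect_equal(nav$mc, 0)
  expect_equal(nav$bc, 5)
  expect_false(nav$parallel)
  # central line passes through the intersection
  expect_lt(abs(nav$mc * nav$xi + nav$bc - nav$yi), 1e-6)

  same <- navigation_line(c(2, 3), c(2, 3))
  expect_true(same$parallel)
  expect_equal(c(same$mc, same$bc), c(2, 3))

  par <- navigation_line(c(2, 0), c(2, 4))
  expect_true(par$parallel)
  expect_equal(c(par$mc, par$bc), c(2, 2))
})

test_that("navigation line is symmetric and bisects in angle space", {
  set.seed(9)
  for (i in 1:20) {
    l1 <- c(runif(1, -5, 5), runif(1, -50, 50))
    l2 <- c(runif(1, -5, 5), runif(1, -50, 50))
    if (abs(l1[1] - l2[1]) < 1e-6) next
    a <- navigation_line(l1, l2)
    b <- navigation_line(l2, l1)
    expect_equal(a$mc, b$mc, tolerance = 1e-12)
    expect_equal(a$bc, b$bc, tolerance = 1e-9)
    expect_equal(atan(a$mc), (atan(l1[1]) + atan(l2[1])) / 2,
                 tolerance = 1e-12)
  }
})

test_that("the full pipeline recovers a noise-free scene exactly", {
  sc <- generate_scene(scene_config(seed = 3, render = FALSE))
  fit <- fit_crop_rows(sc$boxes, sc$config$width, sc$config$height)
  expect_equal(fit$nav$mc, sc$nav$mc, tolerance = 1e-6)
  expect_equal(fit$nav$bc, sc$nav$bc, tolerance = 1e-6)
  expect_equal(fit$lines$left$m, sc$lines$left[["m"]], tolerance = 1e-9)

  res <- residuals(fit)
  expect_lt(max(abs(c(res$left, res$right))), 1e-9)
})

test_that("pipeline errors name the deficient row", {
  sc <- generate_scene(scene_config(seed = 3, render = FALSE))
  left_only <- sc$boxes[sc$boxes$row == "left", ]
  expect_error(fit_crop_rows(left_only, 640, 480), "right row")
})

test_that("gap flags are carried through the pipeline fit", {
  sc <- generate_scene(scene_config(seed = 5, gap_left = 10, render = FALSE))
  fit <- fit_crop_rows(sc$boxes, 640, 480)
  expect_length(fit$gaps$left$flagged, 1)
  flagged_pt <- fit$points$left[fit$points$left$gap, ]
  expect_equal(nrow(flagged_pt), 1)

  dropped <- fit_crop_rows(sc$boxes, 640, 480, drop_gap_points = TRUE)
  expect_equal(dropped$lines$left$n_points, fit$lines$left$n_points - 1L)
  # noise-free: same line either way
  expect_equal(dropped$nav$mc, fit$nav$mc, tolerance = 1e-9)
})

test_that("crop_row_fit methods behave like a model object", {
  sc <- generate_scene(scene_config(seed = 8, render = FALSE))
  fit <- fit_crop_rows(sc$boxes, 640, 480)

  cf <- coef(fit)
  expect_named(cf, c("m_left", "b_left", "m_right", "b_right",
                     "m_nav", "b_nav"))
  expect_equal(unname(cf["m_nav"] * 100 + cf["b_nav"]), predict(fit, 100))
  expect_equal(predict(fit, c(0, 10), line = "left"),
               cf[["m_left"]] * c(0, 10) + cf[["b_left"]])

  expect_output(print(fit), "Crop-row fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.crop_row_fit")
  expect_output(print(s), "Navigation heading")
  expect_equal(s$rows$n, c(18, 18))

  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp, 200, 200)
  expect_silent(plot(fit))
  grDevices::dev.off()
  unlink(tmp)
})
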