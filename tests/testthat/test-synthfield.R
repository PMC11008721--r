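test_that("scene generation is a pure function of config and seed", {
  cfg <- scene_config(width = 96, height = 96, left_x = c(38, 28),
                      right_x = c(58, 68), plants_per_row = 4,
                      plant_radius = 4, weeds = 2, jitter = 1, seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  c <- generate_scene(scene_config(width = 96, height = 96,
                                   left_x = c(38, 28), right_x = c(58, 68),
                                   plants_per_row = 4, plant_radius = 4,
                                   weeds = 2, jitter = 1, seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("noise-free plants sit exactly on the true row lines", {
  sc <- generate_scene(scene_config(seed = 2, render = FALSE))
  pts <- centers_from_detections(sc$boxes)
  for (row in c("left", "right")) {
    sel <- sc$boxes$row == row
    line <- sc$lines[[row]]
    expect_lt(max(abs(line[["m"]] * pts$x[sel] + line[["b"]] - pts$y[sel])),
              1e-9)
  }
  # gaps remove the configured plants
  gapped <- generate_scene(scene_config(seed = 2, gap_left = c(3, 7),
                                        render = FALSE))
  expect_equal(sum(gapped$boxes$row == "left"), 18)
})

test_that("the illumination falloff produces the configured axial ratio", {
  sc <- generate_scene(scene_config(width = 128, height = 128,
                                    left_x = c(50, 36), right_x = c(78, 92),
                                    plants_per_row = 5, plant_radius = 4,
                                    illum_range = c(0.2, 1), seed = 4))
  lum <- channel_max(sc$image)
  # first and last rows see the factor endpoints (0.2 and 1.0) directly
  expect_lt(abs(mean(lum[128, ]) / mean(lum[1, ]) - 5) / 5, 0.10)
})

test_that("enhancement lifts the dark decile but keeps plants brighter", {
  sc <- generate_scene(scene_config(width = 128, height = 128,
                                    left_x = c(50, 36), right_x = c(78, 92),
                                    plants_per_row = 5, plant_radius = 4,
                                    illum_range = c(0.2, 1),
                                    illum_profile = 6, seed = 4))
  enh <- enhance(sc$image, enhance_config(blur_sigma = 8, bins = 64))
  q10 <- function(img) quantile(channel_mean(img), 0.1)
  expect_gt(q10(enh), q10(sc$image))

  pts <- centers_from_detections(sc$boxes)
  on_plant <- cbind(round(pts$y) + 1, round(pts$x) + 1)
  green <- enh[, , 2]
  plant_green <- mean(green[on_plant])
  soil_mask <- matrix(TRUE, 128, 128)
  soil_mask[on_plant] <- FALSE
  expect_gt(plant_green, mean(green[soil_mask]))
})

test_that("plant overlap is rejected at configuration time", {
  expect_error(scene_config(plants_per_row = 20, plant_radius = 10,
                            spacing = 15), "overlap")
})

test_that("detection perturbation jitters, drops and clutters as asked", {
  sc <- generate_scene(scene_config(seed = 6, render = FALSE))
  clean <- perturb_detections(sc, 0, 0, 0, seed = 1)
  expect_equal(clean[, c("x1", "y1", "x2", "y2")],
               sc$boxes[, c("x1", "y1", "x2", "y2")])
  expect_true(all(clean$conf > 0.3 & clean$conf < 1))

  expect_equal(nrow(perturb_detections(sc, 0, 1, 0, seed = 2)), 0)

  with_false <- perturb_detections(sc, 0, 0, 5, seed = 3)
  expect_equal(nrow(with_false), nrow(sc$boxes) + 5)

  # kept count is binomial: mean over 200 seeds within 4 standard errors
  p_miss <- 0.3; n <- nrow(sc$boxes)
  kept <- vapply(1:200, function(s)
    nrow(perturb_detections(sc, 0, p_miss, 0, seed = s)), numeric(1))
  se <- sqrt(n * p_miss * (1 - p_miss) / 200)
  expect_lt(abs(mean(kept) - (1 - p_miss) * n), 4 * se)
})

test_that("single-image augmentations have their closure properties", {
  sc <- generate_scene(scene_config(width = 64, height = 64,
                                    left_x = c(26, 18), right_x = c(38, 46),
                                    plants_per_row = 3, plant_radius = 3,
                                    seed = 9))
  img <- sc$image
  mir <- augment_image(img, augment_op("mirror"))
  expect_false(identical(mir, img))
  expect_equal(augment_image(mir, augment_op("mirror")), img)

  expect_equal(augment_image(img, augment_op("rotation",
                                             params = list(angle = 0))), img)
  expect_equal(augment_image(img, augment_op("contrast",
                                             params = list(gain = 1))), img)
  expect_equal(augment_image(img, augment_op("brightness",
                                             params = list(offset = 0))), img)
  expect_equal(augment_image(img, augment_op("noise",
                                             params = list(sigma = 0))), img)

  # same op and seed reproduce; different seeds differ
  a <- augment_image(img, augment_op("noise", seed = 5))
  expect_identical(a, augment_image(img, augment_op("noise", seed = 5)))
  expect_false(identical(a, augment_image(img, augment_op("noise", seed = 6))))

  rng <- range(augment_image(img, augment_op("brightness",
                                             params = list(offset = 0.5))))
  expect_lte(rng[2], 1)

  expect_error(augment_image(img, augment_op("mosaic")), "4 images")
})

test_that("mosaic composites four resized tiles on the target canvas", {
  imgs <- lapply(1:4, function(v) array(v / 5, dim = c(20, 30, 3)))
  mo <- augment_mosaic(imgs, size = c(64, 64))
  expect_equal(dim(mo), c(64, 64, 3))
  expect_equal(mo[1, 1, 1], 0.2)      # top-left tile from image 1
  expect_equal(mo[1, 64, 1], 0.4)     # top-right from image 2
  expect_equal(mo[64, 1, 1], 0.6)     # bottom-left from image 3
  expect_equal(mo[64, 64, 1], 0.8)    # bottom-right from image 4
  expect_error(augment_mosaic(imgs[1:3]), "exactly 4")
})

test_that("six-way expansion multiplies the dataset by seven", {
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_length(expand_dataset(list(img)), 7)
  ten <- lapply(1:10, function(i) array(runif(16 * 16 * 3), dim = c(16, 16, 3)))
  out <- expand_dataset(ten, seed = 3)
  expect_length(out, 70)
  for (o in out) expect_silent(as_raster(o))
  expect_identical(out[1:10], ten)    # originals retained, in order
  expect_error(expand_dataset(list()), "at least one")
  bad_ops <- c(default_augment_ops()[1:5], list(augment_op("mosaic")))
  expect_error(expand_dataset(ten, ops = bad_ops), "six single-image")
})

test_that("dataset splitting apportions 8:1:1 by largest remainder", {
  sp <- split_dataset(seq_len(5600), seed = 2)
  expect_equal(lengths(sp), c(train = 4480, val = 560, test = 560))
  expect_equal(sort(unname(unlist(sp))), seq_len(5600))

  sp10 <- split_dataset(seq_len(10), seed = 1)
  expect_equal(lengths(sp10), c(train = 8, val = 1, test = 1))

  sp11 <- split_dataset(seq_len(11), seed = 1)
  expect_equal(sum(lengths(sp11)), 11)
  expect_equal(lengths(sp11)[["train"]], 9)  # largest remainder to train

  expect_error(split_dataset(1:2), "at least 3")
})

test_that("generate-perturb-fit recovers the navigation line closely", {
  errs <- vapply(1:10, function(seed) {
    set.seed(seed)
    cfg <- scene_config(gap_left = sample(2:19, 1),
                        gap_right = sample(2:19, 1),
                        seed = seed, render = FALSE)
    sc <- generate_scene(cfg)
    dets <- perturb_detections(sc, sigma_center = 2, seed = seed + 500)
    fit <- fit_crop_rows(dets, cfg$width, cfg$height)
    angular_difference(fit$nav$mc, sc$nav$mc)$degrees
  }, numeric(1))
  expect_lt(mean(errs), 1)
})
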