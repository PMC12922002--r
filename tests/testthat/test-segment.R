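test_that("the threshold separates a two-level image", {
  img <- matrix(rep(c(0.1, 0.9), each = 128), 16, 16)
  th <- min_cross_entropy_threshold(img)
  expect_gt(th, 0.1)
  expect_lt(th, 0.9)
  expect_error(min_cross_entropy_threshold(matrix(0.5, 8, 8)),
               class = "degenerate_image_error")
})

test_that("the threshold equals exhaustive minimization of the objective", {
  set.seed(41)
  for (i in 1:50) {
    n0 <- sample(100:400, 1); n1 <- sample(100:400, 1)
    px <- c(rnorm(n0, 0.2, 0.05), rnorm(n1, 0.8, 0.05))
    px <- pmin(pmax(px, 0), 1)
    expect_identical(min_cross_entropy_threshold(matrix(px, ncol = 1)),
                     brute_force_li(px))
  }
})

test_that("ring fixtures threshold below the ring intensity", {
  set.seed(42)
  img <- matrix(abs(rnorm(200 * 200, 0, 0.01)), 200, 200)   # noise floor
  rows <- matrix(0:199, 200, 200); cols <- t(rows)
  ring <- abs(sqrt((rows - 99.5)^2 + (cols - 99.5)^2) - 70) < 2
  img[ring] <- runif(sum(ring), 0.7, 0.9)
  th <- min_cross_entropy_threshold(img)
  expect_lt(th, 0.7)
  expect_gt(th, 4 * 0.01)   # clear of the |N(0, 0.01)| background floor
  expect_gte(mean(img[ring] > th), 0.99)
})

test_that("effective threshold applies correction and clamps to bounds", {
  p <- segmentation_params()   # correction 0.7, bounds [0.02, 1]
  img <- matrix(runif(100), 10, 10)
  expect_equal(apply_threshold(img, 0.5, p)$threshold, 0.35)
  p1 <- segmentation_params(threshold_correction = 1)
  expect_equal(apply_threshold(img, 0.01, p1)$threshold, 0.02)
  p015 <- segmentation_params(threshold_correction = 0.03,
                              threshold_lower_bound = 0.015)
  expect_equal(apply_threshold(img, 0.5, p015)$threshold, 0.015)
  m <- apply_threshold(img, 0.5, p)
  expect_identical(m$mask, img > 0.35)
})

test_that("effective threshold is monotone and always within bounds", {
  raws <- seq(0, 1, by = 0.05)
  for (corr in c(0.5, 0.7, 1, 1.4)) {
    p <- segmentation_params(threshold_correction = corr)
    eff <- vapply(raws, function(r) apply_threshold(matrix(0.5, 2, 2), r, p)$threshold,
                  numeric(1))
    expect_true(all(diff(eff) >= 0))
    expect_true(all(eff >= p$threshold_lower_bound & eff <= p$threshold_upper_bound))
  }
  # monotone in the correction factor too
  effc <- vapply(c(0.3, 0.7, 1.2), function(k)
    apply_threshold(matrix(0.5, 2, 2), 0.5,
                    segmentation_params(threshold_correction = k))$threshold,
    numeric(1))
  expect_true(all(diff(effc) >= 0))
})

test_that("solidify fills closed and gapped rings to the disc area", {
  sz <- 240; rows <- matrix(0:(sz - 1), sz, sz); cols <- t(rows)
  rad <- sqrt((rows - 119.5)^2 + (cols - 119.5)^2)
  ring <- abs(rad - 100) < 0.5
  solid <- solidify(ring, segmentation_params())
  expect_lt(abs(sum(solid) / (pi * 100^2) - 1), 0.02)
  # 3-px gap: the default closing (radius 5) bridges it
  gap <- ring & !(abs(rows - 119.5) < 1.5 & cols > 119)
  solid2 <- solidify(gap, segmentation_params())
  expect_lt(abs(sum(solid2) / (pi * 100^2) - 1), 0.02)
})

test_that("solidify leaves already-solid blobs alone apart from holes", {
  blob <- disc_mask(50, 140)
  holed <- blob; holed[60:65, 60:65] <- FALSE
  out <- solidify(holed, segmentation_params())
  expect_true(all(out[blob]))          # hole refilled
  expect_lt(sum(out) - sum(blob), 50)  # no inflation beyond rounding
})

test_that("declumping keeps isolated objects whole and splits pairs", {
  p <- segmentation_params()
  one <- disc_mask(150, 400)
  inten <- 0.85 - 0.6 * gaussian_smooth(one * 1, 3)
  lm <- declump(one, inten, p)
  expect_equal(lm$n_objects, 1L)

  # two equal discs overlapping by 20% of a radius: centers 270 px apart
  H <- 500; W <- 760
  m1 <- make_shape(shape_spec("disc", 150, center = c(249.5, 244.5)), c(H, W))$mask
  m2 <- make_shape(shape_spec("disc", 150, center = c(249.5, 514.5)), c(H, W))$mask
  pair <- m1 | m2
  inten2 <- 0.85 - 0.6 * gaussian_smooth(pair * 1, 3)
  lm2 <- declump(pair, inten2, p)
  expect_equal(lm2$n_objects, 2L)
  # the dividing line must sit on the perpendicular bisector (col 379.5
  # between 0-based centers 244.5 and 514.5), within 5 px
  lab <- lm2$labels
  touch <- which(lab[, -1] > 0 & lab[, -ncol(lab)] > 0 &
                 lab[, -1] != lab[, -ncol(lab)], arr.ind = TRUE)
  expect_gt(nrow(touch), 0)
  expect_true(all(abs((touch[, 2] - 0.5) - 379.5) <= 5))

  empty <- declump(matrix(FALSE, 50, 50), matrix(0.5, 50, 50), p)
  expect_equal(empty$n_objects, 0L)
})

test_that("label maps partition the foreground with contiguous 8-connected ids", {
  set.seed(43)
  H <- 500; W <- 760
  m1 <- make_shape(shape_spec("disc", 150, center = c(249.5, 244.5)), c(H, W))$mask
  m2 <- make_shape(shape_spec("disc", 150, center = c(249.5, 514.5)), c(H, W))$mask
  pair <- m1 | m2
  lm <- declump(pair, 0.85 - 0.6 * gaussian_smooth(pair * 1, 3),
                segmentation_params())
  lab <- lm$labels
  expect_setequal(unique(as.vector(lab)), 0:lm$n_objects)
  expect_identical(lab > 0, pair)                 # union = foreground
  for (i in seq_len(lm$n_objects))                # each id one 8-conn component
    expect_equal(max(spheromorph:::label8(lab == i)), 1L)
})

test_that("diameter gates and border contact filter objects", {
  p <- segmentation_params()
  # equivalent diameter 100 < 250: removed
  small <- mask_label_map(disc_mask(50, 200))
  expect_equal(filter_objects(small, p)$n_objects, 0L)
  # interior disc radius 200 (eq. diameter 400): retained
  big <- mask_label_map(disc_mask(200, 450))
  expect_equal(filter_objects(big, p)$n_objects, 1L)
  # border-touching object: removed unless the flag is off
  touching <- make_shape(shape_spec("disc", 200, center = c(224.5, 150)),
                         c(450, 450), border_safe = FALSE)$mask
  lm <- mask_label_map(touching)
  expect_equal(filter_objects(lm, p)$n_objects, 0L)
  keep <- segmentation_params(discard_border_objects = FALSE)
  expect_equal(filter_objects(lm, keep)$n_objects, 1L)
  # survivors are relabeled contiguously
  two <- matrix(0L, 400, 400)
  two[disc_mask(30, 400)] <- 1L                       # too small, dropped
  far <- make_shape(shape_spec("disc", 130, center = c(199.5, 250)),
                    c(400, 400), border_safe = FALSE)$mask
  two[far] <- 2L
  out <- filter_objects(structure(list(labels = two, n_objects = 2L),
                                  class = "label_map"), p)
  expect_equal(out$n_objects, 1L)
  expect_setequal(unique(as.vector(out$labels)), c(0L, 1L))
})

test_that("the segment chain recovers synthetic discs of known radius", {
  for (r in c(150, 300)) {
    sz <- 2 * r + 120
    tr <- make_shape(shape_spec("disc", r, center = c((sz - 1) / 2, (sz - 1) / 2)),
                     c(sz, sz))
    img <- render_brightfield(tr, render_spec(image_size = c(sz, sz),
                                              noise_sd = 0.03, seed = r))
    res <- process_image(img, pipeline_config())
    expect_equal(nrow(res$measurements), 1L)
    expect_lt(abs(res$measurements$area / (pi * r^2) - 1), 0.05)
  }
})

test_that("pure-noise frames yield no objects", {
  for (s in 1:3) {
    img <- render_brightfield(matrix(FALSE, 300, 300),
                              render_spec(image_size = c(300, 300),
                                          noise_sd = 0.03, seed = s))
    res <- process_image(img, pipeline_config())
    expect_equal(nrow(res$measurements), 0L)
  }
})
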