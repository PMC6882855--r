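test_that("centre sampling is class-balanced and stays in its support", {
  ph <- generate_phantom(small_phantom_spec(seed = 13))
  set.seed(1)
  n <- 10000L
  fg <- 0L
  for (i in seq_len(n %/% 20)) {     # 500 draws for the support check
    ctr <- sample_centre(ph$ich, ph$cavity)
    expect_true(ph$cavity$data[ctr[1], ctr[2], ctr[3]] == 1 ||
                  ph$ich$data[ctr[1], ctr[2], ctr[3]] == 1)
  }
  # class balance over many draws: binomial 99.9% interval around 1/2
  fgmask <- ph$ich$data
  for (i in seq_len(n))
    if (fgmask[matrix(sample_centre(ph$ich, ph$cavity), 1)] == 1) fg <- fg + 1L
  expect_gt(fg / n, 0.5 - 3.3 * sqrt(0.25 / n))
  expect_lt(fg / n, 0.5 + 3.3 * sqrt(0.25 / n))
})

test_that("an empty haemorrhage mask sends every centre to background", {
  sp <- small_phantom_spec(seed = 14)
  sp$n_lesions <- 0L
  ph <- generate_phantom(sp)
  set.seed(2)
  for (i in 1:50) {
    ctr <- sample_centre(ph$ich, ph$cavity)
    expect_equal(ph$ich$data[ctr[1], ctr[2], ctr[3]], 0)
    expect_equal(ph$cavity$data[ctr[1], ctr[2], ctr[3]], 1)
  }
})

test_that("patches are concentric with the receptive-field margin", {
  # (124 - 36) / 2 = 44 voxels per side for the full-scale network
  iso <- network_spec()
  expect_identical((c(124L, 124L, 124L) - output_shape(iso, c(124, 124, 124))) %/% 2L,
                   c(44L, 44L, 44L))

  ph <- generate_phantom(small_phantom_spec(seed = 15))
  img <- normalize_hu(ph$image)
  spec <- toy_spec()
  centre <- c(24L, 24L, 24L)
  patch <- extract_patch(img, ph$ich, centre, spec, input_shape = c(20, 20, 20))
  expect_identical(dim(patch$image_tile), c(20L, 20L, 20L))
  expect_identical(dim(patch$label_tile), c(4L, 4L, 4L))
  expect_identical(patch$margin, c(8L, 8L, 8L))
  # interior patch equals a direct crop (tile spans centre - 10 .. centre + 9)
  expect_identical(patch$image_tile, img$data[14:33, 14:33, 14:33])
  expect_identical(patch$label_tile, ph$ich$data[22:25, 22:25, 22:25])
})

test_that("border patches are full-sized and zero-padded", {
  ph <- generate_phantom(small_phantom_spec(seed = 16))
  img <- normalize_hu(ph$image)
  patch <- extract_patch(img, ph$ich, c(1L, 1L, 1L), toy_spec(),
                         input_shape = c(20, 20, 20))
  expect_identical(dim(patch$image_tile), c(20L, 20L, 20L))
  # tile spans -9..10 around the corner: the first ten planes are padding
  expect_identical(patch$image_tile[1:10, , ], array(0, c(10, 20, 20)))
  expect_identical(patch$image_tile[11:20, 11:20, 11:20],
                   img$data[1:10, 1:10, 1:10])
})

test_that("weight maps obey the 2F count law", {
  # all-background tile -> all weights one
  w0 <- make_weight_map(array(0, c(4, 4, 4)))
  expect_true(all(w0 == 1))
  # all-foreground tile: F > N/2 -> all weights one
  w1 <- make_weight_map(array(1, c(4, 4, 4)))
  expect_true(all(w1 == 1))
  # F = 10 in a sizeable tile -> exactly 20 nonzero, 10 per class
  set.seed(3)
  lab <- array(0, c(12, 12, 12))
  lab[sample(length(lab), 10)] <- 1
  w <- make_weight_map(lab)
  expect_equal(sum(w != 0), 20)
  expect_equal(sum(w[lab == 1]), 10)
  expect_equal(sum(w[lab == 0]), 10)

  # property: for random tiles with 0 < F <= N/2, nonzero count is exactly 2F,
  # balanced between classes (brute-force recount)
  for (i in 1:200) {
    d <- c(sample(3:7, 1), sample(3:7, 1), sample(3:7, 1))
    F <- sample.int(floor(prod(d) / 2), 1)
    lab <- array(0, d)
    lab[sample(prod(d), F)] <- 1
    w <- make_weight_map(lab)
    expect_true(all(w %in% c(0, 1)))
    expect_equal(sum(w), 2 * F)
    expect_equal(sum(w * lab), F)
    expect_equal(sum(w * (1 - lab)), F)
  }
})

test_that("augmentation respects probability, involution and identity", {
  ph <- generate_phantom(small_phantom_spec(seed = 17))
  img <- normalize_hu(ph$image)
  spec <- toy_spec()
  centre <- c(24L, 24L, 24L)
  base <- extract_patch(img, ph$ich, centre, spec, input_shape = c(20, 20, 20))

  # probability 0 -> identity (weight map still built)
  cfg0 <- train_config(augment_probability = 0, n_patches = 1,
                       input_shape = c(20, 20, 20))
  set.seed(4)
  a0 <- augment(base, cfg0)
  expect_identical(a0$image_tile, base$image_tile)
  expect_false(a0$augmented)
  expect_false(is.null(a0$weight_tile))

  # mirroring twice restores the original tile
  m1 <- base$image_tile[20:1, , , drop = FALSE]
  expect_identical(m1[20:1, , , drop = FALSE], base$image_tile)

  # rotation by 0 degrees changes nothing beyond interpolation tolerance
  r0 <- extract_patch(img, ph$ich, centre, spec, input_shape = c(20, 20, 20),
                      angle = 0)
  expect_equal(r0$image_tile, base$image_tile, tolerance = 1e-12)
  expect_identical(r0$label_tile, base$label_tile)

  # a genuine rotation re-extracted from the source keeps values in range
  r15 <- extract_patch(img, ph$ich, centre, spec, input_shape = c(20, 20, 20),
                       angle = 15)
  expect_true(all(r15$image_tile >= 0 & r15$image_tile <= 1))
  expect_true(all(r15$label_tile %in% c(0, 1)))
  expect_true(r15$augmented)

  # augment() marks and transforms when the draw fires
  cfg1 <- train_config(augment_probability = 1, n_patches = 1,
                       input_shape = c(20, 20, 20))
  set.seed(6)
  a1 <- augment(base, cfg1, vol = img, ich = ph$ich)
  expect_true(a1$augmented)
  expect_error(augment(a1, cfg1), "already augmented")
})

test_that("weighted cross-entropy matches its closed forms", {
  y <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
  w <- array(1, c(3, 3, 3))
  perfect <- array(0, c(3, 3, 3, 2))
  perfect[, , , 2] <- y
  perfect[, , , 1] <- 1 - y
  expect_lt(weighted_cross_entropy(perfect + 1e-13, y, w), 1e-10)
  uniform <- array(0.5, c(3, 3, 3, 2))
  expect_equal(weighted_cross_entropy(uniform, y, w), log(2))
  wr <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  wr[1] <- 1
  expect_equal(weighted_cross_entropy(uniform, y, wr), log(2))
  expect_error(weighted_cross_entropy(uniform, y, array(0, c(3, 3, 3))),
               "zero")
})

test_that("training is reproducible and accepts the full-scale patch budget", {
  expect_silent(cfg <- train_config(n_patches = 50000L))
  expect_identical(cfg$n_patches, 50000L)

  co <- phantom_cohort(2, small_phantom_spec(), seed = 31)
  spec <- toy_spec()
  cfg <- train_config(n_patches = 6L, input_shape = c(20L, 20L, 20L),
                      seed = 77L)
  ck1 <- train(co, spec, cfg)
  ck2 <- train(co, spec, cfg)
  expect_identical(tail(ck1$log$loss, 1), tail(ck2$log$loss, 1))
  expect_equal(ck1$model$params, ck2$model$params)
  expect_identical(nrow(ck1$log), 6L)
})

test_that("a reduced network learns a separable phantom task", {
  co <- phantom_cohort(3, small_phantom_spec(), seed = 41)
  spec <- toy_spec()
  cfg <- train_config(n_patches = 60L, input_shape = c(28L, 28L, 28L),
                      seed = 5L)
  ck <- train(co, spec, cfg)
  sm <- stats::filter(ck$log$loss, rep(1 / 10, 10), sides = 1)
  # smoothed loss shows a decreasing trend on this separable task
  expect_lt(mean(tail(stats::na.omit(sm), 10)), mean(head(stats::na.omit(sm), 10)))
})

test_that("training rejects invalid patch geometry before starting", {
  co <- phantom_cohort(1, small_phantom_spec(), seed = 51)
  expect_error(train(co, toy_spec(),
                     train_config(n_patches = 1, input_shape = c(17, 18, 18))),
               "invalid|indivisible")
})
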