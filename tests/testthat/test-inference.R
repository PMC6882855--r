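test_that("tiled prediction covers the cavity and masks outside it", {
  ph <- generate_phantom(small_phantom_spec(seed = 61))
  img <- normalize_hu(ph$image)
  m <- build_model(toy_spec(), seed = 62)
  pm <- predict_volume(img, ph$cavity, m)
  expect_s3_class(pm, "probability_map")
  # every cavity voxel was predicted
  expect_true(all(pm$coverage[ph$cavity$data == 1]))
  # probabilities outside the cavity are zero
  expect_true(all(pm$data[ph$cavity$data == 0] == 0))
  expect_true(all(pm$data >= 0 & pm$data <= 1))
  expect_error(predict_volume(img, label_volume(array(1, c(10, 10, 10)),
                                                img$spacing, role = "cranial_cavity"), m),
               "different grids")
})

test_that("a cavity smaller than one tile is handled by a single padded tile", {
  d <- c(30L, 30L, 30L)
  vol <- ct_volume(array(0.5, d), c(1, 1, 1), normalized = TRUE)
  cav <- array(0, d)
  cav[14:18, 14:18, 14:18] <- 1
  cav <- label_volume(cav, c(1, 1, 1), role = "cranial_cavity")
  m <- build_model(toy_spec(), seed = 63)
  pm <- predict_volume(vol, cav, m)
  expect_true(all(pm$coverage[cav$data == 1]))
})

test_that("constant input gives spatially constant probabilities within a tile", {
  d <- c(40L, 40L, 40L)
  vol <- ct_volume(array(0.6, d), c(1, 1, 1), normalized = TRUE)
  cav <- label_volume(array(1, d), c(1, 1, 1), role = "cranial_cavity")
  m <- build_model(toy_spec(), seed = 64)
  pm <- predict_volume(vol, cav, m, tile_shape = c(56L, 56L, 56L))
  # one tile covers the whole grid; away from the zero-padded borders every
  # receptive field sees the same constant input, so the probabilities are
  # spatially constant there (translation invariance of the conv net)
  interior <- pm$data[10:31, 10:31, 10:31]
  expect_lt(diff(range(interior)), 1e-6)
  expect_gt(diff(range(pm$data)), 0)   # borders differ: padding is visible
})

test_that("connected components match a flood-fill reference", {
  set.seed(65)
  for (conn in c(26L, 6L)) {
    for (r in 1:5) {
      m <- array(rbinom(10 * 9 * 8, 1, 0.2), c(10, 9, 8))
      got <- connected_components(m, conn)
      want <- brute_components(m, conn)
      # same partition: label images are equal up to renumbering
      expect_identical(got > 0, want > 0)
      key <- paste(got[m == 1], want[m == 1])
      expect_equal(length(unique(key)), max(want))
    }
  }
})

test_that("post-processing applies the threshold and 0.1 mL cluster filter", {
  sp <- c(0.43, 0.43, 0.5)          # voxel volume 0.09245 mm^3
  d <- c(40L, 40L, 40L)

  mk_pm <- function(nvox, p = 0.9) {
    pr <- array(0, d)
    idx <- arrayInd(order(as.vector(blob_dist)), d)[seq_len(nvox), ]
    pr[idx] <- p
    structure(list(data = pr, spacing = sp, coverage = array(TRUE, d)),
              class = "probability_map")
  }
  ctr <- c(20, 20, 20)
  blob_dist <- array(0, d)
  for (a in 1:3) {
    v <- (seq_len(d[a]) - ctr[a])^2
    blob_dist <- blob_dist + aperm(array(v, d[c(a, setdiff(1:3, a))]),
                                   order(c(a, setdiff(1:3, a))))
  }
  # 1082 voxels = 100.03 mm^3 >= 0.1 mL -> kept
  seg_keep <- postprocess(mk_pm(1082))
  expect_equal(sum(seg_keep$data), 1082)
  # 1081 voxels = 99.94 mm^3 < 0.1 mL -> removed
  seg_drop <- postprocess(mk_pm(1081))
  expect_equal(sum(seg_drop$data), 0)

  # below-threshold probabilities yield an empty mask; ties go to foreground
  pr <- array(0.49, d)
  pm49 <- structure(list(data = pr, spacing = sp, coverage = array(TRUE, d)),
                    class = "probability_map")
  expect_equal(sum(postprocess(pm49)$data), 0)
  pr[blob_dist <= 49] <- 0.5        # exactly at threshold, ~1400 voxels
  pm50 <- structure(list(data = pr, spacing = sp, coverage = array(TRUE, d)),
                    class = "probability_map")
  expect_gt(sum(postprocess(pm50)$data), 1082)

  # two far-apart clusters: only the large one survives
  pr2 <- array(0, d)
  pr2[2:4, 2:4, 2:4] <- 1                      # 27 voxels = 2.5 mm^3
  pr2[15:35, 15:35, 15:35] <- 1                # 9261 voxels = 856 mm^3
  pm2 <- structure(list(data = pr2, spacing = sp, coverage = array(TRUE, d)),
                   class = "probability_map")
  seg2 <- postprocess(pm2)
  expect_equal(sum(seg2$data), 9261)
  expect_equal(sum(seg2$data[2:4, 2:4, 2:4]), 0)
})

test_that("post-processing is idempotent and monotone", {
  set.seed(66)
  d <- c(24L, 24L, 24L)
  sp <- c(0.43, 0.43, 0.5)
  for (r in 1:20) {
    pr <- array(runif(prod(d)), d)
    pm <- structure(list(data = pr, spacing = sp, coverage = array(TRUE, d)),
                    class = "probability_map")
    seg <- postprocess(pm)
    pm_again <- structure(list(data = seg$data, spacing = sp,
                               coverage = array(TRUE, d)),
                          class = "probability_map")
    expect_identical(postprocess(pm_again)$data, seg$data)

    # raising one voxel's probability never removes it from the pre-filter mask
    i <- sample(prod(d), 1)
    pr2 <- pr
    pr2[i] <- min(1, pr2[i] + 0.5)
    pre1 <- pr >= 0.5
    pre2 <- pr2 >= 0.5
    expect_true(all(pre2[pre1]))
  }
})

test_that("segmentation volume is count times voxel volume", {
  m <- box_mask(c(30L, 30L, 30L), c(5, 5, 5), c(14, 14, 14),
                spacing = c(0.43, 0.43, 0.5))
  expect_equal(segmentation_volume_ml(m), 1000 * 0.43 * 0.43 * 0.5 / 1000)
  empty <- label_volume(array(0, c(5, 5, 5)), c(1, 1, 1), role = "prediction")
  expect_equal(segmentation_volume_ml(empty), 0)
  # ~1 mL worth of voxels at the reference spacing
  expect_equal(10817 * prod(c(0.43, 0.43, 0.5)) / 1000, 1, tolerance = 1e-4)
})
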