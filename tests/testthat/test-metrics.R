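test_that("DSC matches overlap counting", {
  d <- c(20L, 20L, 20L)
  a <- box_mask(d, c(3, 3, 3), c(12, 12, 12))        # 10^3 cube
  expect_equal(dsc(a, a), 1)
  b <- box_mask(d, c(8, 3, 3), c(17, 12, 12))        # shifted 5 voxels in x
  expect_equal(dsc(a, b), 0.5)                       # 2*500 / (1000 + 1000)
  c_ <- box_mask(d, c(15, 15, 15), c(18, 18, 18))
  expect_equal(dsc(a, c_), 0)
  empty <- label_volume(array(0, d), c(1, 1, 1))
  expect_error(dsc(empty, empty), "empty")
})

test_that("surface voxels follow the 6-neighbourhood definition", {
  d <- c(9L, 9L, 9L)
  single <- box_mask(d, c(5, 5, 5), c(5, 5, 5))
  expect_equal(nrow(surface_voxels(single)), 1)
  cube3 <- box_mask(d, c(4, 4, 4), c(6, 6, 6))
  expect_equal(nrow(surface_voxels(cube3)), 26)      # 27 - 1 interior
  cube5 <- box_mask(d, c(3, 3, 3), c(7, 7, 7))
  expect_equal(nrow(surface_voxels(cube5)), 98)      # 125 - 27
  # volume border counts as outside: the shell of a full mask is surface,
  # only the single fully-face-enclosed centre voxel is interior
  full <- label_volume(array(1, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(nrow(surface_voxels(full)), 26)
  expect_error(surface_voxels(label_volume(array(0, d), c(1, 1, 1))), "empty")
  # agreement with the brute-force loop on random masks
  set.seed(71)
  for (r in 1:5) {
    m <- random_mask(c(7L, 8L, 6L))
    got <- surface_voxels(m)
    want <- brute_surface(m$data)
    expect_identical(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                     want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE])
  }
})

test_that("distance metrics reproduce single-pair geometry", {
  d <- c(9L, 9L, 9L)
  sp <- c(0.43, 0.43, 0.5)
  a <- box_mask(d, c(5, 5, 2), c(5, 5, 2), spacing = sp)
  b <- box_mask(d, c(5, 5, 5), c(5, 5, 5), spacing = sp, role = "ich")
  dm <- distance_metrics(a, b)
  # two single voxels 3 apart along z at 0.5 mm spacing: all four = 1.5 mm
  expect_equal(unname(dm), rep(1.5, 4))
  expect_equal(unname(distance_metrics(b, b)), rep(0, 4))
})

test_that("distance metrics equal the all-pairs brute-force oracle", {
  set.seed(72)
  spacings <- list(c(1, 1, 1), c(0.43, 0.43, 0.5), c(0.53, 0.53, 5))
  for (r in 1:25) {
    sp <- spacings[[1 + r %% 3]]
    segm <- random_mask(c(8L, 7L, 9L), p = 0.3, spacing = sp)
    refm <- random_mask(c(8L, 7L, 9L), p = 0.3, spacing = sp, role = "ich")
    got <- distance_metrics(segm, refm)
    want <- brute_distance_metrics(segm$data, refm$data, sp)
    expect_equal(got, want, tolerance = 1e-12)
    # ordering invariants and symmetry
    expect_lte(got["hd95_mm"], got["hd_mm"])
    expect_lte(got["mhd_mm"], got["hd_mm"])
    expect_lte(got["cmd_mm"], got["hd_mm"])
    expect_equal(distance_metrics(refm, segm), got[names(got)])
  }
})

test_that("scaling the spacing scales distances and leaves DSC/AVD alone", {
  set.seed(73)
  segm <- random_mask(c(8L, 8L, 8L), p = 0.3)
  refm <- random_mask(c(8L, 8L, 8L), p = 0.3, role = "ich")
  base <- distance_metrics(segm, refm)
  k <- 2.5
  segk <- label_volume(segm$data, segm$spacing * k, role = "prediction")
  refk <- label_volume(refm$data, refm$spacing * k, role = "ich")
  expect_equal(distance_metrics(segk, refk), base * k)
  expect_equal(dsc(segk, refk), dsc(segm, refm))
  expect_equal(avd(segk, refk), avd(segm, refm))
})

test_that("AVD follows its formula and is translation invariant", {
  d <- c(20L, 20L, 20L)
  ref <- box_mask(d, c(3, 3, 3), c(7, 7, 6), role = "ich")       # 100 voxels
  seg <- box_mask(d, c(3, 3, 3), c(13, 4, 7), role = "prediction")# 110 voxels
  expect_equal(sum(ref$data), 100)
  expect_equal(sum(seg$data), 110)
  expect_equal(avd(seg, ref), 10)
  expect_equal(avd(ref, ref), 0)
  shifted <- box_mask(d, c(8, 8, 8), c(18, 9, 12), role = "prediction")
  expect_equal(avd(shifted, ref), avd(seg, ref))
  expect_error(avd(seg, label_volume(array(0, d), c(1, 1, 1), role = "ich")),
               "empty")
})

test_that("pair evaluation reports failures instead of infinities", {
  d <- c(10L, 10L, 10L)
  ref <- box_mask(d, c(3, 3, 3), c(6, 6, 6), role = "ich")
  seg <- box_mask(d, c(3, 3, 3), c(6, 6, 7), role = "prediction")
  rep1 <- evaluate_pair(seg, ref, case = "a")
  expect_true(rep1$ok)
  expect_gt(rep1$dsc, 0.8)
  empty <- label_volume(array(0, d), c(1, 1, 1), role = "prediction")
  rep2 <- evaluate_pair(empty, ref, case = "b")
  expect_false(rep2$ok)
  expect_true(is.na(rep2$dsc))
  expect_match(rep2$reason, "empty")
})

test_that("cohort summaries compute mean/sd and median/IQR per metric", {
  d <- c(10L, 10L, 10L)
  ref <- box_mask(d, c(3, 3, 3), c(6, 6, 6), role = "ich")
  pairs <- list(
    p1 = list(seg = box_mask(d, c(3, 3, 3), c(6, 6, 6)), ref = ref),
    p2 = list(seg = box_mask(d, c(3, 3, 3), c(6, 6, 7)), ref = ref),
    p3 = list(seg = box_mask(d, c(3, 3, 4), c(6, 6, 7)), ref = ref))
  res <- evaluate_cohort(pairs)
  expect_equal(nrow(res$per_case), 3)
  srow <- res$summary[res$summary$metric == "dsc", ]
  v <- res$per_case$dsc
  expect_equal(srow$mean, mean(v))
  expect_equal(srow$median, median(v))
  expect_equal(srow$q25, unname(quantile(v, 0.25, type = 7)))
  expect_equal(srow$q75, unname(quantile(v, 0.75, type = 7)))
  # median/IQR of a known triple under the linear-interpolation rule
  x <- c(0.87, 0.91, 0.94)
  expect_equal(median(x), 0.91)
  expect_equal(unname(quantile(x, c(.25, .75), type = 7)), c(0.89, 0.925))

  # identical pairs give a zero-variance summary, invariant to order
  same <- list(a = pairs$p2, b = pairs$p2, c = pairs$p2)
  rs <- evaluate_cohort(same)
  expect_equal(rs$summary$sd[rs$summary$metric == "dsc"], 0)
  perm <- evaluate_cohort(same[c(3, 1, 2)])
  expect_equal(perm$summary$median, rs$summary$median)

  # failed cases are counted but excluded
  pairs$p4 <- list(seg = label_volume(array(0, d), c(1, 1, 1)), ref = ref)
  res2 <- evaluate_cohort(pairs)
  expect_equal(res2$summary$n_failed[1], 1)
  expect_equal(res2$summary$n[1], 3)
})
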