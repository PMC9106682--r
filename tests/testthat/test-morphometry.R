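make_shape_volume <- function(mask) {
  arr <- array(0L, c(2, nrow(mask), ncol(mask)))
  arr[1, , ] <- as.integer(mask)
  arr[2, , ] <- as.integer(mask)
  labeled_volume(arr, c(20, 20, 20))
}

test_that("per-slice circularity matches closed forms", {
  # digitized disk, r = 50 px
  n <- 121; ctr <- 61
  disk <- outer(1:n, 1:n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= 50^2)
  m <- per_slice_measurements(make_shape_volume(disk), 1)
  expect_gte(m$circularity, 0.98)
  expect_lte(m$circularity, 1)
  expect_equal(m$csa_um2, sum(disk) * 0.02^2)
  # 20 x 20 square: 4 pi s^2 / (4 s)^2 = pi / 4
  sq <- matrix(FALSE, 40, 40); sq[11:30, 11:30] <- TRUE
  msq <- per_slice_measurements(make_shape_volume(sq), 1)
  expect_equal(msq$circularity, pi / 4, tolerance = 0.02 / (pi / 4))
  # 40 x 20 rectangle: 4 pi * 800 / 120^2
  rc <- matrix(FALSE, 60, 90); rc[11:30, 21:60] <- TRUE
  mrc <- per_slice_measurements(make_shape_volume(rc), 1)
  expect_equal(mrc$circularity, 4 * pi * 800 / 120^2, tolerance = 0.03)
  # among fixed-area shapes the disk is the most circular
  expect_gt(m$circularity, msq$circularity)
  expect_gt(msq$circularity, mrc$circularity)
  # empty slice -> zero rows
  v <- labeled_volume(array(0L, c(2, 5, 5)))
  expect_identical(nrow(per_slice_measurements(v, 1)), 0L)
  expect_error(per_slice_measurements(v, 3), "out of range")
})

test_that("synthetic cylinder CSA recovers the configured radius", {
  for (r in c(10, 14, 20)) {
    n <- 2 * r + 5
    disk <- outer(1:n, 1:n, function(i, j)
      (i - r - 3)^2 + (j - r - 3)^2 <= r^2)
    m <- per_slice_measurements(make_shape_volume(disk), 1)
    a_true <- pi * r^2 * 0.02^2
    expect_lte(abs(m$csa_um2 - a_true) / a_true, 0.05)
  }
})

test_that("volume_weighted_mean_csa is sum(c^2)/sum(c)", {
  expect_equal(volume_weighted_mean_csa(c(2, 2, 2)), 2)
  expect_equal(volume_weighted_mean_csa(c(1, 3)), 2.5)
  expect_equal(volume_weighted_mean_csa(c(1, 2, 3)), 14 / 6)
  expect_error(volume_weighted_mean_csa(numeric(0)), "empty")
  expect_error(volume_weighted_mean_csa(c(1, -2)), "positive")
  # Cauchy-Schwarz: weighted mean >= arithmetic mean, equality iff constant
  withr::local_seed(5)
  for (i in 1:50) {
    x <- runif(sample(2:20, 1), 0.1, 5)
    expect_gte(volume_weighted_mean_csa(x) + 1e-12, mean(x))
  }
})

test_that("morphometry_table aggregates per label and volume-weights", {
  arr <- array(0L, c(4, 30, 30))
  arr <- stamp_disk(arr, 1:4, 10, 10, 4, 1L)
  arr <- stamp_disk(arr, 1:4, 22, 22, 6, 2L)
  mt <- morphometry_table(labeled_volume(arr, c(20, 20, 20)))
  expect_identical(nrow(mt$per_label), 2L)
  expect_gte(mt$volume_weighted_csa, mt$mean_csa)
  # grouping two labels into one myofibril
  mt2 <- morphometry_table(labeled_volume(arr, c(20, 20, 20)),
                           groups = c(`1` = "m1", `2` = "m2"))
  expect_identical(nrow(mt2$per_myofibril), 2L)
})

test_that("boundary_distance_map is exact and 1-Lipschitz", {
  # boundary-adjacent voxel is one spacing away
  m <- array(0L, c(5, 7, 7)); m[, 2:6, 2:6] <- 1L
  d <- boundary_distance_map(mask_volume(m, c(20, 20, 20)))
  expect_equal(d[3, 2, 4], 20)
  expect_equal(d[3, 4, 4], 60)  # center: 3 voxels from lateral background
  expect_true(all(d[m == 0L] == 0))
  # center of a 21^3 cube at 20 nm: ~10 voxels = 200 nm (within one voxel)
  big <- array(0L, c(23, 23, 23)); big[2:22, 2:22, 2:22] <- 1L
  db <- boundary_distance_map(mask_volume(big, c(20, 20, 20)))
  expect_lte(abs(db[12, 12, 12] - 200), 20 + 1e-9)
  # anisotropic spacing respected
  da <- boundary_distance_map(mask_volume(m, c(20, 10, 40)))
  expect_equal(da[3, 2, 4], 10)
  # 1-Lipschitz along each axis (random mask)
  withr::local_seed(6)
  rm <- array(as.integer(runif(10 * 12 * 14) > 0.4), c(10, 12, 14))
  rm[1, 1, 1] <- 0L
  dr <- boundary_distance_map(mask_volume(rm, c(20, 20, 20)))
  expect_true(all(abs(apply(dr, c(2, 3), diff)) <= 20 + 1e-9))
  expect_true(all(abs(apply(dr, c(1, 3), diff)) <= 20 + 1e-9))
  expect_true(all(abs(apply(dr, c(1, 2), diff)) <= 20 + 1e-9))
  # degenerate masks
  expect_error(boundary_distance_map(
    mask_volume(array(0L, c(3, 3, 3)))), "empty")
  expect_error(boundary_distance_map(
    mask_volume(array(1L, c(3, 3, 3)))), "background")
})

test_that("peripheral_bias_test statistic and extremes behave", {
  withr::local_seed(7)
  ref <- runif(200, 0, 4000)
  # maximal separation: all branches on the boundary
  pt <- peripheral_bias_test(rep(0, 40), ref, n_perm = 1000, seed = 3)
  expect_lte(pt$p_value, 0.001)
  # antisymmetry of the statistic under swapping
  a <- runif(50, 0, 1000); b <- runif(60, 500, 2000)
  s1 <- peripheral_bias_test(a, b, n_perm = 1000, seed = 1)$statistic
  s2 <- peripheral_bias_test(b, a, n_perm = 1000, seed = 1)$statistic
  expect_equal(s1, -s2)
  # deterministic given seed
  p1 <- peripheral_bias_test(a, b, n_perm = 1000, seed = 9)$p_value
  p2 <- peripheral_bias_test(a, b, n_perm = 1000, seed = 9)$p_value
  expect_identical(p1, p2)
  expect_error(peripheral_bias_test(a, b, n_perm = 500), "1000")
  expect_error(peripheral_bias_test(numeric(0), b), "nonempty")
})
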