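test_that("volume constructors validate their invariants", {
  expect_error(labeled_volume(array(-1L, c(2, 2, 2))), "negative")
  expect_error(labeled_volume(matrix(0L, 2, 2)), "3D")
  expect_error(labeled_volume(array(0L, c(2, 2, 2)), voxel_size = c(0, 1, 1)),
               "voxel_size")
  expect_error(mask_volume(array(2L, c(2, 2, 2))), "0/1")
  expect_error(probability_volume(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  v <- labeled_volume(array(c(0L, 3L), c(2, 2, 2)))
  expect_identical(label_set(v), 3L)
  expect_identical(label_set(labeled_volume(array(0L, c(3, 4, 4)))),
                   integer(0))
})

test_that("TIFF stacks round-trip data and metadata at all bit depths", {
  withr::local_seed(1)
  for (maxlab in c(7L, 300L, 70000L)) {     # 8-, 16-, 32-bit payloads
    d <- array(sample(0:maxlab, 4 * 5 * 6, replace = TRUE), c(4, 5, 6))
    v <- labeled_volume(d, voxel_size = c(10, 10, 10))
    f <- withr::local_tempfile(fileext = ".tif")
    write_volume(v, f)
    r <- read_volume(f)
    expect_s3_class(r, "labeled_volume")
    expect_identical(r$data, v$data)
    expect_equal(r$voxel_size, c(10, 10, 10))
  }
  m <- mask_volume(array(sample(0:1, 60, TRUE), c(3, 4, 5)),
                   voxel_size = c(20, 20, 20), structure_name = "srt")
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(m, f)
  r <- read_volume(f)
  expect_s3_class(r, "mask_volume")
  expect_identical(r$data, m$data)
  expect_identical(r$structure_name, "srt")
})

test_that("8-bit probability TIFFs quantize to nearest 1/255 and rescale", {
  p <- probability_volume(array(c(0, 0.3, 0.5, 1), c(2, 2, 2)))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(p, f)
  r <- read_volume(f)
  expect_s3_class(r, "probability_volume")
  expect_equal(r$data, array(round(p$data * 255) / 255, dim(p$data)))
  expect_equal(max(r$data), 1.0)            # 255 maps exactly to 1.0
})

test_that("read_volume errors are specific", {
  expect_error(read_volume("/nonexistent/vol.tif"), "not found")
  # a 1-page TIFF is 2D-only input
  v <- labeled_volume(array(1L, c(1, 4, 4)))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  expect_error(read_volume(f), "2D-only")
  # junk file
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(1:32), f2)
  expect_error(read_volume(f2), "TIFF")
})

test_that("HDF5 volumes round-trip with voxel metadata", {
  d <- array(0L, c(10, 8, 8)); d[1:5, 2, 2] <- 1L; d[6:10, 5, 5] <- 2L
  v <- labeled_volume(d, voxel_size = c(10, 10, 10))
  f <- withr::local_tempfile(fileext = ".h5")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(sort(label_set(r)), c(1L, 2L))
  expect_identical(r$data, v$data)
  expect_equal(r$voxel_size, c(10, 10, 10))
  # masks land in a dataset named after the structure
  m <- mask_volume(array(1L, c(3, 3, 3)), structure_name = "cell")
  f2 <- withr::local_tempfile(fileext = ".h5")
  write_volume(m, f2)
  expect_true("cell" %in% rhdf5::h5ls(f2)$name)
  r2 <- read_volume(f2)
  expect_s3_class(r2, "mask_volume")
  expect_identical(r2$structure_name, "cell")
})

test_that("reorient_longitudinal permutes without resampling", {
  withr::local_seed(2)
  d <- array(sample(0:9, 4 * 5 * 6, TRUE), c(4, 5, 6))
  v <- labeled_volume(d, voxel_size = c(1, 2, 3))
  expect_identical(reorient_longitudinal(v, 1)$data, v$data)
  w <- reorient_longitudinal(v, 3)
  expect_identical(dim(w$data), c(6L, 4L, 5L))
  expect_equal(w$voxel_size, c(3, 1, 2))
  # value multiset preserved exactly
  expect_identical(sort(as.vector(w$data)), sort(as.vector(v$data)))
  # axis permutation for long_axis = 3 is a 3-cycle: three applications
  # compose to the identity
  w3 <- reorient_longitudinal(reorient_longitudinal(w, 3), 3)
  expect_identical(w3$data, v$data)
  expect_equal(w3$voxel_size, v$voxel_size)
  # long_axis = 2 with a flip on the untouched axis is self-inverse
  u <- reorient_longitudinal(v, 2, flip = c(FALSE, FALSE, TRUE))
  u2 <- reorient_longitudinal(u, 2, flip = c(FALSE, FALSE, TRUE))
  expect_identical(u2$data, v$data)
  expect_error(reorient_longitudinal(v, 4), "long_axis")
})

test_that("bin_volume reduces labels by mode, masks by max, probs by mean", {
  v <- labeled_volume(array(0L, c(4, 4, 4)), voxel_size = c(10, 10, 10))
  expect_identical(bin_volume(v, 1L)$data, v$data)
  # half labeled 1 / half 2, split along axis 1
  d <- array(2L, c(4, 4, 4)); d[1:2, , ] <- 1L
  v <- labeled_volume(d, voxel_size = c(10, 10, 10))
  b <- bin_volume(v, 2L)
  expect_identical(dim(b$data), c(2L, 2L, 2L))
  expect_true(all(b$data[1, , ] == 1L) && all(b$data[2, , ] == 2L))
  expect_equal(b$voxel_size, c(20, 20, 20))  # 10 nm binned by 2 -> 20 nm
  # background excluded from the mode unless block all background
  d2 <- array(0L, c(2, 2, 2)); d2[1, 1, 1] <- 5L
  expect_identical(as.vector(bin_volume(labeled_volume(d2), 2L)$data), 5L)
  # mode ties break to the smallest label
  d3 <- array(c(3L, 7L), c(2, 2, 2))
  expect_identical(as.vector(bin_volume(labeled_volume(d3), 2L)$data), 3L)
  # mask max-reduction: every output fg block had >= 1 input fg voxel and
  # every input fg voxel lies in an output fg block
  withr::local_seed(3)
  md <- array(as.integer(runif(6 * 6 * 6) > 0.8), c(6, 6, 6))
  mb <- bin_volume(mask_volume(md), 2L)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    blk <- md[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    expect_identical(mb$data[i, j, k], as.integer(any(blk == 1L)))
  }
  # probabilities: block mean
  pd <- array(runif(8), c(2, 2, 2))
  pb <- bin_volume(probability_volume(pd), 2L)
  expect_equal(as.vector(pb$data), mean(pd))
  expect_error(bin_volume(v, 0L), "factor")
})
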