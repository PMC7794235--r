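test_that("containers validate their invariants", {
  expect_error(oto_volume(array(c(1, NA), c(2, 1, 1))), "non-finite")
  expect_error(oto_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  expect_error(oto_volume(matrix(0, 2, 2)), "3D")
  expect_error(oto_labelmap(array(2L, c(2, 2, 2))), "0 or 1")
  expect_error(grid_spec(c(0, 4, 4), 1), "shape")
  expect_error(grid_spec(4, -0.25), "spacing")
})

test_that("NIfTI round trip preserves values and metadata", {
  v <- oto_volume(array(rnorm(8^3, mean = 300, sd = 700), c(8, 8, 8)),
                  spacing = c(0.125, 0.125, 0.25), origin = c(-3, 2, 7.5))
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_volume(v, path)
    v2 <- read_volume(path)
    expect_lt(max(abs(v2$values - v$values)), 1e-6)
    expect_equal(v2$spacing, v$spacing)
    expect_equal(v2$origin, v$origin, tolerance = 1e-5)
    unlink(path)
  }
})

test_that("label maps are written as integer data and re-read exactly", {
  set.seed(5)
  m <- oto_labelmap(array(as.integer(runif(6^3) < 0.3), c(6, 6, 6)),
                    spacing = c(0.5, 0.5, 0.5))
  path <- tempfile(fileext = ".nii")
  write_volume(m, path)
  con <- file(path, "rb")
  seek(con, 70)
  dtype <- readBin(con, "integer", 1, size = 2, endian = "little")
  close(con)
  expect_identical(dtype, 2L)  # uint8 on disk
  m2 <- read_labelmap(path)
  expect_identical(m2$mask, m$mask)
  unlink(path)
})

test_that("reading rejects missing, 4D and non-finite files", {
  expect_error(read_volume(tempfile()), "not found")
  v <- oto_volume(array(0, c(4, 4, 4)))
  path <- tempfile(fileext = ".nii")
  write_volume(v, path)
  # patch the header in place to claim a 4D image with 2 time points
  con <- file(path, "r+b")
  seek(con, 40, rw = "write")
  writeBin(c(4L, 4L, 4L, 4L, 2L), con, size = 2L, endian = "little")
  close(con)
  expect_error(read_volume(path), "3D")
  unlink(path)
  vals <- array(0, c(3, 3, 3)); vals[2, 2, 2] <- NaN
  path2 <- tempfile(fileext = ".nii")
  write_nifti_with_affine(path2, vals, diag(4))
  expect_error(read_volume(path2), "non-finite")
  unlink(path2)
})

test_that("reading reorients flipped acquisitions without moving voxels in space", {
  # one hot voxel at 0-based index (2, 3, 4) on a grid stored L/P/I-wards:
  # the affine has negative diagonal entries and a nonzero translation
  arr <- array(0, c(6, 7, 8))
  arr[3, 4, 5] <- 1500
  affine <- rbind(c(-0.5, 0, 0, 10), c(0, 0.5, 0, -4), c(0, 0, -0.5, 20),
                  c(0, 0, 0, 1))
  world_expected <- (affine %*% c(2, 3, 4, 1))[1:3]  # by-hand affine application
  path <- tempfile(fileext = ".nii")
  write_nifti_with_affine(path, arr, affine)
  v <- read_volume(path)
  hot <- which(v$values == 1500, arr.ind = TRUE)
  expect_identical(nrow(hot), 1L)
  world_got <- v$origin + (as.numeric(hot) - 1) * v$spacing
  expect_equal(world_got, as.numeric(world_expected), tolerance = 1e-5)
  expect_equal(v$spacing, c(0.5, 0.5, 0.5))
  unlink(path)
})

test_that("resample preserves constants and the identity grid", {
  v <- oto_volume(array(100, c(8, 8, 8)), spacing = c(1, 1, 1))
  r <- resample(v, grid_spec(c(5, 3, 7), c(1.1, 2, 0.7)))
  expect_true(all(r$values == 100))
  r2 <- resample(v, grid_spec(c(8, 8, 8), c(1, 1, 1)))
  expect_identical(r2$values, v$values)
})

test_that("continuous resampling interpolates a ramp exactly at output centers", {
  d <- c(16L, 4L, 4L)
  ramp <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)  # value = x index
  v <- oto_volume(ramp, spacing = c(1, 1, 1))
  out <- resample(v, grid_spec(c(7L, 4L, 4L), c(2, 1, 1)))
  # linear interpolation of a linear ramp must reproduce the analytic value
  # at each output voxel center: world x = 2 * index, ramp value = world x
  expected <- rep(2 * (0:6), times = 16)
  expect_equal(as.vector(out$values), expected)
})

test_that("nearest resampling keeps masks binary and out-of-view fills are air/0", {
  set.seed(7)
  for (i in 1:5) {
    m <- random_mask(c(8, 8, 8), spacing = c(0.5, 0.5, 0.5))
    r <- resample(m, grid_spec(c(11, 5, 13), c(0.3, 0.8, 0.45)))
    expect_true(all(r$mask %in% c(0L, 1L)))
  }
  v <- oto_volume(array(500, c(4, 4, 4)), spacing = c(1, 1, 1))
  big <- resample(v, grid_spec(c(10, 10, 10), c(1, 1, 1)))
  expect_true(all(big$values[8:10, , ] == -1000))  # beyond the input FOV
  expect_error(resample(v, grid_spec(4, 0)), "spacing")
})

test_that("flip_lr is an involution that reverses the left-right axis", {
  set.seed(3)
  v <- oto_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  expect_identical(flip_lr(flip_lr(v))$values, v$values)
  m <- array(0L, c(7, 3, 3)); m[2, 1, 3] <- 1L
  lm <- oto_labelmap(m)
  flipped <- flip_lr(lm)
  expect_identical(unname(which(flipped$mask == 1L, arr.ind = TRUE)[1, ]),
                   c(6L, 1L, 3L))  # N - 1 - i, 0-based
  lm2 <- lm; lm2$orientation <- c("A", "R", "S")
  expect_error(flip_lr(lm2), "orientation")
})

test_that("flipping a volume with its label preserves Dice against HU thresholds", {
  ph <- generate_phantom(phantom_config(seed = 21, noise_sd = 0))
  thresh_mask <- function(vol) {
    oto_labelmap((vol$values >= -400 & vol$values <= 550) * 1L,
                 spacing = vol$spacing, origin = vol$origin)
  }
  d0 <- dice(ph$labels$inner_ear, thresh_mask(ph$volume))
  d1 <- dice(flip_lr(ph$labels$inner_ear), thresh_mask(flip_lr(ph$volume)))
  expect_equal(d1, d0)
})
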