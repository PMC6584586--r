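test_that("NIfTI round-trip preserves data exactly and voxel size to 1e-6", {
  set.seed(7)
  v <- scalar_volume(array(rnorm(10 * 12 * 14), c(10, 12, 14)),
                     voxel_grid(c(10, 12, 14), c(0.1, 0.1, 0.1)), "FA")
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, p)
  r <- read_nifti(p)
  expect_identical(r$data, v$data)
  expect_lt(max(abs(r$grid$voxel_size - v$grid$voxel_size)), 1e-6)
})

test_that("label volumes round-trip with their lookup sidecar", {
  lab <- array(0L, c(8, 8, 8)); lab[3:5, 3:5, 3:5] <- 2L; lab[6, 6, 6] <- 5L
  lt <- data.frame(id = c(2L, 5L), name = c("a", "b"),
                   hemisphere = c("left", "right"))
  lv <- label_volume(lab, voxel_grid(c(8, 8, 8)), lt)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(lv, p)
  r <- read_nifti(p, as_labels = TRUE)
  expect_identical(r$data, lv$data)
  expect_setequal(r$label_table$id, lt$id)
  expect_identical(r$label_table$hemisphere[r$label_table$id == 5L], "right")
})

test_that("reading a 4-D file as a plain volume errors as non-3-D", {
  f <- displacement_field(array(0.5, c(6, 6, 6, 3)))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(f, p)
  expect_error(read_nifti(p), "non-3-D")
  expect_error(read_nifti(file.path(tempdir(), "nope.nii")), "missing file")
  # but the field reader accepts it and round-trips
  expect_equal(read_field(p)$vectors, f$vectors)
})

test_that("non-integral labels beyond tolerance are rejected", {
  a <- array(0, c(6, 6, 6)); a[2, 2, 2] <- 1.01
  p <- withr::local_tempfile(fileext = ".nii")
  write_nifti(scalar_volume(a), p)
  expect_error(read_nifti(p, as_labels = TRUE), "non-integral")
})

test_that("resample with a zero field is the identity", {
  v <- ball_image(c(20, 20, 20))
  out <- resample(v, zero_field(v$grid), "linear")
  expect_equal(out$data, v$data, tolerance = 0)
})

test_that("pull-back convention: constant +1 shift reads content one voxel up", {
  a <- array(0, c(12, 12, 12)); a[5, 5, 5] <- 1
  v <- scalar_volume(a)
  d <- array(0, c(12, 12, 12, 3)); d[, , , 1] <- 1
  out <- resample(v, displacement_field(d), "linear")
  expect_equal(out$data[4, 5, 5], 1)
  expect_equal(sum(out$data), 1)
})

test_that("trilinear weights form a partition of unity on the interior", {
  shape <- c(24, 24, 24)
  f <- random_smooth_field(shape, amplitude = 2, seed = 3)
  v <- scalar_volume(array(1, shape))
  out <- resample(v, f, "linear")
  interior <- out$data[4:21, 4:21, 4:21]
  expect_lt(max(abs(interior - 1)), 1e-12)
})

test_that("labels require nearest-neighbour resampling", {
  lab <- label_volume(array(1L, c(6, 6, 6)))
  expect_error(resample(lab, zero_field(lab$grid), "linear"), "nearest")
  out <- resample(lab, zero_field(lab$grid), "nearest")
  expect_identical(out$data, lab$data)
})

test_that("grid and volume constructors enforce their invariants", {
  expect_error(voxel_grid(c(0, 4, 4)), "positive")
  expect_error(voxel_grid(c(4, 4, 4), c(0.1, -1, 0.1)), "positive")
  expect_error(scalar_volume(array(1, c(4, 4))), "non-3-D")
  expect_error(scalar_volume(array(c(1, NA), c(2, 2, 2))), "finite")
  expect_error(label_volume(array(2L, c(2, 2, 2)),
                            label_table = data.frame(id = 1L, name = "a",
                                                     hemisphere = "left")),
               "missing from label_table")
})
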