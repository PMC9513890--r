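test_that("NIfTI write/read round-trips data, spacing and origin", {
  set.seed(1)
  v <- volume_image(array(rnorm(10 * 12 * 14), c(10, 12, 14)),
                    spacing = c(0.5, 0.5, 0.8), origin = c(1, 2, 3))
  f <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$data, v$data)
  expect_true(all(abs(v2$spacing - c(0.5, 0.5, 0.8)) <= 1e-6))
  expect_true(all(abs(v2$origin - c(1, 2, 3)) <= 1e-6))

  m <- binary_mask(array(as.integer(runif(6^3) < 0.3), c(6, 6, 6)),
                   spacing = c(1, 1, 2))
  fm <- file.path(tempdir(), "rt_mask.nii.gz")
  write_volume(m, fm)
  m2 <- read_volume(fm, mask = TRUE)
  expect_identical(m2$data, m$data)
  expect_s3_class(m2, "binary_mask")
})

test_that("read_volume rejects missing files and non-3D images", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
  f4 <- file.path(tempdir(), "fourd.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(read_volume(f4), "3D")
})

test_that("write_volume refuses a nonexistent directory", {
  v <- volume_image(array(0:7 / 7, c(2, 2, 2)))
  expect_error(write_volume(v, file.path(tempdir(), "no_such_dir", "x.nii")),
               "directory")
})

test_that("type constructors validate their invariants", {
  expect_error(volume_image(matrix(1, 2, 2)), "3D")
  expect_error(volume_image(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(binary_mask(array(0.5, c(2, 2, 2))), "0 or 1")
  v <- volume_image(array(rnorm(8), c(2, 2, 2)))
  m_bad <- binary_mask(array(0L, c(3, 3, 3)))
  expect_error(volume_bundle(v, v, m_bad), "share")
  expect_true(same_geometry(v, v))
})
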