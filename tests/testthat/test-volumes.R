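test_that("volume and label NIfTI round-trips are lossless", {
  td <- withr::local_tempdir()
  a <- array(0, dim = c(4, 4, 4))
  v <- volume_image(a, spacing = c(1, 1, 2))
  p <- file.path(td, "v.nii.gz")
  write_volume(v, p)
  r <- read_volume(p)
  expect_identical(r$data, v$data)
  expect_equal(r$spacing, c(1, 1, 2))

  set.seed(1)
  vi <- volume_image(array(rnorm(64), dim = c(4, 4, 4)), origin = c(5, 6, 7))
  write_volume(vi, p)
  r2 <- read_volume(p)
  expect_lt(max(abs(r2$data - vi$data)), 1e-6)
  expect_equal(r2$origin, c(5, 6, 7))

  lab <- label_volume(array(sample(0:3, 4^3, replace = TRUE), dim = c(4, 4, 4)))
  pl <- file.path(td, "l.nii.gz")
  write_volume(lab, pl)
  rl <- read_volume(pl, as_labels = TRUE)
  expect_identical(rl$data, lab$data)
  expect_setequal(unique(as.vector(rl$data)), unique(as.vector(lab$data)))
})

test_that("reading non-integer voxels as labels is rejected, naming the voxel", {
  td <- withr::local_tempdir()
  a <- array(0, dim = c(3, 3, 3))
  a[2, 1, 3] <- 2.5
  p <- file.path(td, "bad.nii.gz")
  write_volume(volume_image(a), p)
  expect_error(read_volume(p, as_labels = TRUE),
               class = "atlasfuse_validation_error")
  expect_error(read_volume(p, as_labels = TRUE), "\\(1,0,2\\).*2\\.5")
})

test_that("I/O failure modes raise classed errors", {
  td <- withr::local_tempdir()
  expect_error(read_volume(file.path(td, "nope.nii.gz")),
               class = "atlasfuse_io_error")
  v <- volume_image(array(0, dim = c(3, 3, 3)))
  expect_error(write_volume(v, td), class = "atlasfuse_io_error")
  expect_error(write_volume(v, file.path(td, "missing", "x.nii.gz")),
               class = "atlasfuse_io_error")
})

test_that("displacement field round-trip is exact and component count is checked", {
  td <- withr::local_tempdir()
  z <- displacement_field(array(0, dim = c(4, 4, 4, 3)))
  p <- file.path(td, "f.nii.gz")
  write_field(z, p)
  expect_equal(read_field(p)$data, z$data)

  set.seed(2)
  f <- displacement_field(array(rnorm(4^3 * 3), dim = c(4, 4, 4, 3)),
                          spacing = c(1, 1, 1.5))
  write_field(f, p)
  rf <- read_field(p)
  expect_lt(max(abs(rf$data - f$data)), 1e-6)
  expect_equal(rf$spacing, c(1, 1, 1.5))

  # a 2-component file must be rejected
  bad <- RNifti::asNifti(array(0, dim = c(4, 4, 4, 1, 2)))
  pb <- file.path(td, "bad.nii.gz")
  RNifti::writeNifti(bad, pb)
  expect_error(read_field(pb), class = "atlasfuse_validation_error")
  expect_error(read_field(pb), "2 components")
})

test_that("warping with the zero field is the identity for both interpolators", {
  set.seed(3)
  v <- volume_image(array(rnorm(6^3), dim = c(6, 6, 6)))
  l <- label_volume(array(sample(0:3, 6^3, TRUE), dim = c(6, 6, 6)))
  z <- displacement_field(array(0, dim = c(6, 6, 6, 3)))
  expect_equal(warp(v, z, "linear")$data, v$data, tolerance = 1e-12)
  expect_identical(warp(l, z, "nearest")$data, l$data)
})

test_that("warp follows the pull-back convention out(x) = vol(x + u(x))", {
  a <- array(0, dim = c(10, 10, 10))
  a[6, 6, 6] <- 1                       # bright voxel at 0-based (5,5,5)
  u <- array(0, dim = c(10, 10, 10, 3))
  u[, , , 1] <- 1                       # u = (1,0,0)
  w <- warp(volume_image(a), displacement_field(u), "linear")
  expect_equal(w$data[5, 6, 6], 1)      # appears at 0-based (4,5,5)
  expect_equal(sum(w$data), 1)
})

test_that("label warps use nearest neighbour only and invent no labels", {
  l <- label_volume(array(sample(c(0L, 2L, 5L), 8^3, TRUE), dim = c(8, 8, 8)))
  f <- displacement_field(array(0, dim = c(8, 8, 8, 3)))
  expect_error(warp(l, f, "linear"), class = "atlasfuse_validation_error")
  for (seed in 1:5) {
    rf <- random_smooth_field(c(8, 8, 8), max_disp = 2, seed = seed)
    w <- warp(l, rf, "nearest")
    expect_true(all(unique(as.vector(w$data)) %in% c(0L, unique(as.vector(l$data)))))
  }
})

test_that("field composition matches sequential warping and inversion undoes a field", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, bias_amplitude = 0))
  a <- random_smooth_field(c(32, 32, 32), max_disp = 1.5, seed = 10)
  b <- random_smooth_field(c(32, 32, 32), max_disp = 1.5, seed = 11)
  two_step <- warp(warp(ph$image, b, "linear"), a, "linear")
  one_step <- warp(ph$image, compose_fields(a, b), "linear")
  expect_lt(mean(abs(two_step$data - one_step$data)), 5e-3)

  inv <- invert_field(a)
  comp <- compose_fields(a, inv)        # should be near-zero displacement
  mag <- sqrt(comp$data[, , , 1]^2 + comp$data[, , , 2]^2 + comp$data[, , , 3]^2)
  expect_lt(mean(mag), 0.05)
})
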