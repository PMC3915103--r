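cube_mask <- function(d, from, to) {
  m <- array(FALSE, dim = d)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

test_that("Dice hits its definitional anchors", {
  m <- cube_mask(c(10, 10, 10), c(3, 3, 3), c(6, 6, 6))
  expect_equal(dice(m, m), 100)                          # identity -> 100%
  disj <- cube_mask(c(10, 10, 10), c(8, 8, 8), c(10, 10, 10))
  expect_equal(dice(m, disj), 0)                         # disjoint -> 0%
  # |auto| = |ref| = 100, overlap 80
  a <- array(FALSE, dim = c(10, 10, 10)); a[1:100] <- TRUE
  r <- array(FALSE, dim = c(10, 10, 10)); r[21:120] <- TRUE
  expect_equal(dice(a, r), 80)
  expect_equal(dice(a, r), dice(r, a))
  empty <- array(FALSE, dim = c(10, 10, 10))
  expect_equal(dice(empty, empty), 100)
  expect_equal(dice(a, empty), 0)
  expect_error(dice(a, array(FALSE, dim = c(9, 10, 10))),
               class = "atlasfuse_validation_error")
})

test_that("surface voxels are the 6-connectivity boundary", {
  d <- c(7, 7, 7)
  solid <- cube_mask(d, c(3, 3, 3), c(5, 5, 5))           # 3x3x3 cube
  sv <- surface_voxels(solid)
  expect_equal(nrow(sv), 26)                              # all but the centre
  expect_false(any(sv[, 1] == 3 & sv[, 2] == 3 & sv[, 3] == 3))  # centre (0-based 3,3,3)
  canon <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  expect_equal(canon(sv), canon(bf_surface_coords(solid)), ignore_attr = TRUE)

  single <- array(FALSE, dim = d); single[4, 4, 4] <- TRUE
  expect_equal(surface_voxels(single), cbind(3L, 3L, 3L), ignore_attr = TRUE)

  sheet <- cube_mask(d, c(1, 1, 4), c(7, 7, 4))           # 1-voxel-thick sheet
  expect_equal(nrow(surface_voxels(sheet)), 49)
  expect_error(surface_voxels(array(FALSE, dim = d)),
               class = "atlasfuse_validation_error")
})

test_that("MAD and Hausdorff have hand-computable geometric values", {
  d <- c(12, 12, 12)
  m <- cube_mask(d, c(4, 4, 4), c(7, 7, 7))
  expect_equal(mad_surface(m, m, c(1, 1, 1)), 0)
  expect_equal(hausdorff(m, m, c(1, 1, 1)), 0)

  # two parallel unit-thickness sheets 3 voxels apart: every surface point is
  # 3 voxels from the other sheet
  s1 <- cube_mask(d, c(4, 2, 2), c(4, 10, 10))
  s2 <- cube_mask(d, c(7, 2, 2), c(7, 10, 10))
  expect_equal(mad_surface(s1, s2, c(1, 1, 1)), 3.0)

  # unit cube translated by 2 voxels
  c1 <- cube_mask(d, c(4, 4, 4), c(4, 4, 4))
  c2 <- cube_mask(d, c(6, 4, 4), c(6, 4, 4))
  expect_equal(hausdorff(c1, c2, c(1, 1, 1)), 2.0)
})

test_that("MAD and Hausdorff match the all-pairs brute-force oracle", {
  for (seed in 1:10) {
    d <- c(16, 16, 16)
    a <- random_blob(d, seed)
    r <- random_blob(d, seed + 1000)
    sp <- c(1, 1, 1)
    bf <- bf_surface_metrics(a, r, sp)
    expect_equal(mad_surface(a, r, sp), bf$mad, tolerance = 1e-6)
    expect_equal(hausdorff(a, r, sp), bf$hausdorff, tolerance = 1e-6)
    expect_gte(hausdorff(a, r, sp), mad_surface(a, r, sp))
    # symmetry
    expect_equal(mad_surface(r, a, sp), mad_surface(a, r, sp), tolerance = 1e-12)
  }
})

test_that("surface distances honour anisotropic spacing and scale linearly", {
  d <- c(12, 12, 12)
  a <- random_blob(d, 5)
  r <- random_blob(d, 6)
  expect_equal(mad_surface(a, r, c(2, 2, 2)), 2 * mad_surface(a, r, c(1, 1, 1)),
               tolerance = 1e-9)
  expect_equal(hausdorff(a, r, c(3, 3, 3)), 3 * hausdorff(a, r, c(1, 1, 1)),
               tolerance = 1e-9)
  bf <- bf_surface_metrics(a, r, c(1, 2, 0.5))
  expect_equal(mad_surface(a, r, c(1, 2, 0.5)), bf$mad, tolerance = 1e-6)
})

test_that("empty masks yield NA distance metrics with a warning", {
  d <- c(8, 8, 8)
  m <- cube_mask(d, c(3, 3, 3), c(5, 5, 5))
  empty <- array(FALSE, dim = d)
  expect_warning(res <- mad_surface(m, empty, c(1, 1, 1)))
  expect_true(is.na(res))
  expect_warning(res2 <- hausdorff(empty, m, c(1, 1, 1)))
  expect_true(is.na(res2))
})

test_that("evaluate_all reports one row per label plus an unweighted mean", {
  arr <- array(0L, dim = c(10, 10, 10))
  arr[2:4, 2:4, 2:4] <- 1L
  arr[6:8, 6:8, 6:8] <- 2L
  lab <- label_volume(arr)
  res <- evaluate_all(lab, lab)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$dsc_percent == 100))
  expect_true(all(res$mad_mm == 0) && all(res$hausdorff_mm == 0))

  # a label missing from auto: DSC 0 for that row
  auto <- label_volume(ifelse(arr == 2L, 0L, arr))
  res2 <- evaluate_all(auto, lab, labels = c(1L, 2L))
  expect_equal(res2$dsc_percent[which(res2$label == 2)], 0)

  # a label absent from the reference is flagged and excluded from means
  res3 <- evaluate_all(lab, lab, labels = c(1L, 2L, 7L))
  expect_equal(nrow(res3), 4L)
  expect_match(res3$note[which(res3$label == 7)], "absent")
  expect_equal(res3$dsc_percent[res3$note == "mean"], 100)
})
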