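test_that("phantoms have the requested labels and are seed-deterministic", {
  ph <- make_phantom(phantom_spec(seed = 5))
  expect_setequal(unique(as.vector(ph$labels$data)), 0:4)
  ph2 <- make_phantom(phantom_spec(seed = 5))
  expect_identical(ph$image$data, ph2$image$data)
  expect_identical(ph$labels$data, ph2$labels$data)
  ph3 <- make_phantom(phantom_spec(seed = 6))
  expect_false(identical(ph$image$data, ph3$image$data))
})

test_that("noise- and bias-free phantoms are piecewise constant away from edges", {
  spec <- phantom_spec(noise_sd = 0, bias_amplitude = 0, pv_sigma = 1)
  ph <- make_phantom(spec)
  s1 <- spec$structures[[1]]
  ctr <- round(s1$center) + 1
  expect_equal(ph$image$data[ctr[1], ctr[2], ctr[3]], s1$intensity,
               tolerance = 1e-3)
  expect_equal(ph$labels$data[ctr[1], ctr[2], ctr[3]], s1$label)
  # far corner is outside the head: zero intensity
  expect_equal(ph$image$data[1, 1, 1], 0, tolerance = 1e-6)
})

test_that("overlapping structures are rejected", {
  bad <- list(list(label = 1L, center = c(15, 15, 15), radii = c(4, 4, 4),
                   intensity = 0.5),
              list(label = 2L, center = c(16, 15, 15), radii = c(4, 4, 4),
                   intensity = 0.9))
  expect_error(make_phantom(phantom_spec(structures = bad)),
               class = "atlasfuse_validation_error")
})

test_that("random smooth fields respect the max-displacement contract", {
  z <- random_smooth_field(c(16, 16, 16), max_disp = 0, seed = 1)
  expect_true(all(z$data == 0))
  f <- random_smooth_field(c(16, 16, 16), max_disp = 2.5, seed = 1)
  mag <- sqrt(f$data[, , , 1]^2 + f$data[, , , 2]^2 + f$data[, , , 3]^2)
  expect_equal(max(mag), 2.5, tolerance = 1e-6)
  f2 <- random_smooth_field(c(16, 16, 16), max_disp = 2.5, seed = 1)
  expect_identical(f$data, f2$data)
  # distinct seeds decorrelate (smooth fields have few effective degrees of
  # freedom, so individual |cos| values sit well above 0; the mean over many
  # independent pairs must still be small)
  cos_sim <- vapply(1:20, function(s) {
    a <- as.vector(random_smooth_field(c(16, 16, 16), max_disp = 1, seed = s)$data)
    b <- as.vector(random_smooth_field(c(16, 16, 16), max_disp = 1, seed = s + 100)$data)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_lt(abs(mean(cos_sim)), 0.15)
})

test_that("populations have the declared size and composition", {
  pop <- make_population(population_spec(k_modes = 3L, per_mode = 3L, seed = 2))
  expect_length(pop$members, 9L)
  expect_equal(tabulate(pop$mode_assignment), c(3L, 3L, 3L))
  expect_length(pop$true_fields, 9L)
  expect_true(all(vapply(pop$members, function(m)
    identical(dim(m$image$data), c(32L, 32L, 32L)), logical(1))))
  # determinism
  pop2 <- make_population(population_spec(k_modes = 3L, per_mode = 3L, seed = 2))
  expect_identical(pop$members[[5]]$image$data, pop2$members[[5]]$image$data)
})

test_that("within-mode pairs are closer than between-mode pairs", {
  img_msd <- function(a, b) mean((a$image$data - b$image$data)^2)
  lab_dsc <- function(a, b) dice(a$labels$data != 0, b$labels$data != 0)
  n_better_msd <- 0L; n_tot <- 0L
  dsc_within <- c(); dsc_between <- c()
  for (seed in 1:5) {
    pop <- make_population(population_spec(seed = seed))
    ids <- names(pop$members)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      same <- pop$mode_assignment[i] == pop$mode_assignment[j]
      m <- img_msd(pop$members[[i]], pop$members[[j]])
      d <- lab_dsc(pop$members[[i]], pop$members[[j]])
      if (same) dsc_within <- c(dsc_within, d) else dsc_between <- c(dsc_between, d)
      if (!same) next
      # compare this within-mode pair against every between-mode pair
      for (k in seq_along(ids)) {
        if (pop$mode_assignment[k] == pop$mode_assignment[i]) next
        n_tot <- n_tot + 1L
        if (m < img_msd(pop$members[[i]], pop$members[[k]]))
          n_better_msd <- n_better_msd + 1L
      }
    }
  }
  expect_gte(n_better_msd / n_tot, 0.95)
  expect_gt(mean(dsc_within), mean(dsc_between))
})

test_that("shrinking within-mode displacement collapses a mode onto itself", {
  pspec <- population_spec(k_modes = 1L, per_mode = 3L,
                           between_mode_disp = 4, within_mode_disp = 0.05,
                           seed = 9)
  pop <- make_population(pspec)
  base_noise <- 2 * pspec$base$noise_sd^2
  msd <- mean((pop$members[[1]]$image$data - pop$members[[3]]$image$data)^2)
  # members differ by little more than their independent noise draws
  expect_lt(msd, 4 * base_noise)
})

test_that("oracle pair fields align population members", {
  # appearance offsets are zeroed so the residual isolates geometry: after
  # oracle warping it cannot drop below the two members' independent noise
  # (2 * noise_sd^2), so compare against that floor.
  pop <- make_population(population_spec(k_modes = 2L, per_mode = 2L, seed = 13,
                                         mode_appearance_sd = 0,
                                         member_appearance_sd = 0))
  ids <- names(pop$members)
  # cross-mode pair: large true deformation difference
  U <- oracle_pair_field(pop$true_fields[[ids[1]]], pop$true_fields[[ids[3]]])
  warped <- warp(pop$members[[ids[1]]]$image, U, "linear")
  before <- mean((pop$members[[ids[1]]]$image$data - pop$members[[ids[3]]]$image$data)^2)
  after <- mean((warped$data - pop$members[[ids[3]]]$image$data)^2)
  expect_lt(after, 0.25 * before)
  expect_lt(after, 10 * 2 * population_spec()$base$noise_sd^2)
  # self-pair: exactly zero
  Uself <- oracle_pair_field(pop$true_fields[[ids[1]]], pop$true_fields[[ids[1]]])
  expect_true(all(abs(Uself$data) < 1e-12))
})
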