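#' Synthetic labelled phantoms and atlas populations
#'
#' Desk-scale stand-ins for a labelled brain MRI atlas population: a base
#' anatomy of compact structures (one large thalamus-like ellipsoid, one
#' thin ventricle-like structure to stress the surface metrics, plus
#' smaller compact bodies), rendered with partial-volume edge smoothing, a
#' smooth multiplicative bias field and additive Gaussian noise.
#'
#' A population is organised in modes that emulate anatomical subtypes:
#' each mode draws a smooth random deformation axis (maximum displacement
#' `between_mode_disp`), and its members sit at evenly spaced severities
#' along that axis, offset by a small independent jitter field, so that
#' member-specific displacement stays within `within_mode_disp`.  Members
#' of a mode are therefore mutually similar, modes are mutually dissimilar,
#' and within each mode some members are genuinely closer to the base
#' anatomy than others -- the cluster structure the graph-based atlas
#' selection is designed to detect.  Ground-truth deformations are
#' returned so the oracle registration backend can bypass real
#' registration.
#'
#' @name phantom
NULL

default_structures <- function(grid_shape) {
  s <- grid_shape / 32          # scale geometry with the grid
  list(
    list(label = 1L, center = c(11, 20, 16) * s, radii = c(5.0, 4.5, 4.5) * s,
         intensity = 0.9),     # large, thalamus-like
    list(label = 2L, center = c(20, 12, 16) * s, radii = c(1.8, 5.5, 2.8) * s,
         intensity = 0.5),     # thin, ventricle-like
    list(label = 3L, center = c(22, 22, 18) * s, radii = c(3.2, 3.2, 3.2) * s,
         intensity = 0.7),
    list(label = 4L, center = c(10, 9, 11) * s, radii = c(2.6, 2.6, 2.6) * s,
         intensity = 0.8)
  )
}

#' Phantom specification
#'
#' @param grid_shape integer 3-vector of grid dimensions.
#' @param structures list of ellipsoids, each a list with `label`, `center`
#'   (voxels), `radii` (voxels) and `intensity`.  The default places four
#'   non-overlapping structures scaled to the grid.
#' @param background_intensity intensity of unlabelled "tissue" inside the
#'   head.
#' @param head_radii radii (voxels) of the outer head ellipsoid, centred in
#'   the grid; intensity outside the head is 0, as in a skull-stripped
#'   scan, matching the zero out-of-grid sampling convention.
#' @param pv_sigma Gaussian edge-smoothing sigma in voxels (partial volume).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; structures span roughly 0.25-0.9).
#' @param bias_amplitude peak relative amplitude of the smooth
#'   multiplicative bias field (a random quadratic polynomial).  The
#'   default emulates the small residual inhomogeneity left after the
#'   upstream bias correction the pipeline assumes; raise it to test
#'   robustness against uncorrected scans.
#' @param spacing,origin geometry of the produced volumes.
#' @param seed RNG seed; every phantom is deterministic given its spec.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         structures = default_structures(grid_shape),
                         head_radii = 0.42 * grid_shape,
                         background_intensity = 0.25,
                         pv_sigma = 1.2,
                         noise_sd = 0.02,
                         bias_amplitude = 0.02,
                         spacing = c(1, 1, 1),
                         origin = c(0, 0, 0),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    validation_error("grid_shape must be a 3-vector of dimensions >= 8")
  if (length(structures) < 1L) validation_error("need at least one structure")
  labs <- vapply(structures, function(s) as.integer(s$label), integer(1))
  if (anyDuplicated(labs) || any(labs < 1L))
    validation_error("structure labels must be distinct positive integers")
  if (noise_sd < 0 || bias_amplitude < 0)
    validation_error("noise_sd and bias_amplitude must be >= 0")
  for (s in structures) {
    if (any(s$center - s$radii < 0) || any(s$center + s$radii > grid_shape - 1))
      validation_error("structure with label %d does not fit inside the grid", s$label)
  }
  structure(list(grid_shape = grid_shape, structures = structures,
                 head_radii = check_vec3(head_radii, "head_radii"),
                 background_intensity = background_intensity,
                 pv_sigma = pv_sigma, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 spacing = spacing, origin = origin, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Random quadratic polynomial over the grid, scaled to max |P| = 1.
random_quadratic <- function(d) {
  g <- coord_grids(d)
  xs <- (g$x - (d[1] - 1) / 2) / d[1]
  ys <- (g$y - (d[2] - 1) / 2) / d[2]
  zs <- (g$z - (d[3] - 1) / 2) / d[3]
  basis <- cbind(xs, ys, zs, xs * ys, xs * zs, ys * zs, xs^2, ys^2, zs^2)
  p <- as.vector(basis %*% stats::runif(ncol(basis), -1, 1))
  array(p / max(abs(p)), dim = d)
}

#' Generate a labelled phantom
#'
#' @param spec a [phantom_spec].
#' @return list with `image` (a [volume_image]) and `labels`
#'   (a [label_volume]); bit-identical across calls with the same spec.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) validation_error("make_phantom expects a phantom_spec")
  d <- spec$grid_shape
  g <- coord_grids(d)
  lab <- array(0L, dim = d)
  ctr <- (d - 1) / 2
  head <- ((g$x - ctr[1]) / spec$head_radii[1])^2 +
          ((g$y - ctr[2]) / spec$head_radii[2])^2 +
          ((g$z - ctr[3]) / spec$head_radii[3])^2 <= 1
  img <- array(ifelse(head, spec$background_intensity, 0), dim = d)
  for (s in spec$structures) {
    inside <- ((g$x - s$center[1]) / s$radii[1])^2 +
              ((g$y - s$center[2]) / s$radii[2])^2 +
              ((g$z - s$center[3]) / s$radii[3])^2 <= 1
    inside <- array(inside, dim = d)
    if (any(lab[inside] != 0L))
      validation_error("structures with labels %d and %d overlap",
                       max(lab[inside]), s$label)
    lab[inside] <- as.integer(s$label)
    img[inside] <- s$intensity
  }
  if (spec$pv_sigma > 0) img <- gaussian_smooth(img, spec$pv_sigma)
  with_seed(spec$seed, {
    if (spec$bias_amplitude > 0)
      img <- img * (1 + spec$bias_amplitude * random_quadratic(d))
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
  })
  list(image = volume_image(img, spec$spacing, spec$origin),
       labels = label_volume(lab, spec$spacing, spec$origin))
}

#' Smooth random displacement field
#'
#' Independent Gaussian vectors on a coarse control grid, trilinearly
#' upsampled, Gaussian-smoothed, and rescaled so the maximum displacement
#' magnitude equals `max_disp` exactly.
#'
#' @param shape grid dimensions (3-vector).
#' @param max_disp maximum displacement magnitude in voxels (`0` gives the
#'   zero field).
#' @param smoothness_sigma Gaussian smoothing sigma in voxels.
#' @param seed RNG seed.
#' @param control_spacing knot spacing of the coarse grid, in voxels.
#' @param spacing,origin geometry slots of the returned field.
#' @return a [displacement_field].
#' @export
random_smooth_field <- function(shape, max_disp, smoothness_sigma = 3,
                                seed = 1L, control_spacing = 8,
                                spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (max_disp < 0) validation_error("max_disp must be >= 0")
  u <- array(0, dim = c(shape, 3L))
  if (max_disp > 0) {
    cd <- pmax(2L, as.integer(ceiling(shape / control_spacing)) + 1L)
    scale <- shape / cd
    with_seed(seed, {
      for (c in 1:3) {
        coarse <- array(stats::rnorm(prod(cd)), dim = cd)
        fine <- upsample_to(coarse, shape, scale)
        u[, , , c] <- gaussian_smooth(fine, smoothness_sigma)
      }
    })
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    peak <- max(mag)
    if (peak > 0) u <- u * (max_disp / peak)
  }
  displacement_field(u, spacing, origin)
}

#' Population specification
#'
#' @param base a [phantom_spec] describing the base anatomy.
#' @param k_modes number of anatomical modes (subtypes).
#' @param per_mode members per mode.
#' @param between_mode_disp maximum displacement (voxels) of a mode's
#'   deformation axis; must exceed `within_mode_disp`.
#' @param within_mode_disp maximum member-specific displacement (voxels).
#' @param jitter_frac fraction of `within_mode_disp` spent on each member's
#'   independent jitter field (the rest sets the severity spread along the
#'   mode axis).  Kept small by default so the severity axis dominates
#'   member idiosyncrasy -- the controlled part of the cluster structure.
#' @param mode_appearance_sd standard deviation of the per-mode structure
#'   intensity offsets (intensity units; the shared background tissue is
#'   offset with half this sd).  Modes emulate anatomical subtypes that
#'   differ in appearance as well as shape -- without an appearance
#'   component the intensity similarity term carries no information about
#'   mode membership once images are well registered.
#' @param member_appearance_sd standard deviation of the additional
#'   per-member intensity micro-offsets (background again at half sd).
#' @param seed RNG seed for the population.
#' @return a `population_spec`.
#' @export
population_spec <- function(base = phantom_spec(),
                            k_modes = 3L, per_mode = 3L,
                            between_mode_disp = 4, within_mode_disp = 1,
                            jitter_frac = 0.1,
                            mode_appearance_sd = 0.08,
                            member_appearance_sd = 0.01, seed = 1L) {
  if (!inherits(base, "phantom_spec")) validation_error("base must be a phantom_spec")
  if (k_modes < 1L || per_mode < 1L)
    validation_error("k_modes and per_mode must be >= 1")
  if (!(between_mode_disp > within_mode_disp && within_mode_disp > 0))
    validation_error("need between_mode_disp > within_mode_disp > 0")
  if (jitter_frac < 0 || jitter_frac >= 1)
    validation_error("jitter_frac must be in [0, 1)")
  if (mode_appearance_sd < 0 || member_appearance_sd < 0)
    validation_error("appearance sds must be >= 0")
  structure(list(base = base, k_modes = as.integer(k_modes),
                 per_mode = as.integer(per_mode),
                 between_mode_disp = between_mode_disp,
                 within_mode_disp = within_mode_disp,
                 jitter_frac = jitter_frac,
                 mode_appearance_sd = mode_appearance_sd,
                 member_appearance_sd = member_appearance_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate an atlas population with known cluster structure
#'
#' For each mode a deformation axis `D_m` is drawn
#' (`max_disp = between_mode_disp`).  Member i of mode m receives the
#' member field `V_i = (s_i - 1) D_m + J_i`, with severities `s_i` evenly
#' spaced so that the axis component of `V_i` stays within
#' `(1 - jitter_frac) * within_mode_disp` and `J_i` an independent jitter
#' field of maximum displacement `jitter_frac * within_mode_disp`.  The
#' member's ground-truth deformation is the composition `T_i` of the mode
#' warp after the member warp (`warp(base, T_i)` applies `V_i` on top of
#' `D_m`); image and labels are warped once with `T_i` (linear /
#' nearest), then each member gets its own bias and noise draw.
#'
#' The subject is an independent noisy rendering of the undeformed base
#' (ground-truth field zero), so each member's distance to the subject
#' grows with its severity.
#'
#' @param pspec a `population_spec`.
#' @return list with `members` (each `id`, `image`, `labels`, `mode`,
#'   `severity`), `mode_assignment` (integer vector), `true_fields` (named
#'   list of base-to-member [displacement_field]s), `subject` (`image`,
#'   `labels`, zero `true_field`) and `base` (noise-free base phantom).
#' @export
make_population <- function(pspec) {
  if (!inherits(pspec, "population_spec"))
    validation_error("make_population expects a population_spec")
  base_spec <- pspec$base
  clean_spec <- base_spec
  clean_spec$noise_sd <- 0
  clean_spec$bias_amplitude <- 0
  base <- make_phantom(clean_spec)
  d <- base_spec$grid_shape
  n_struct <- length(base_spec$structures)

  n <- pspec$k_modes * pspec$per_mode
  rand <- with_seed(pspec$seed, list(
    seeds = sample.int(.Machine$integer.max, pspec$k_modes + 2L * n + 1L),
    # column 1 = background tissue (half sd), then one column per structure
    mode_offsets = cbind(stats::rnorm(pspec$k_modes,
                                      sd = pspec$mode_appearance_sd / 2),
                         matrix(stats::rnorm(pspec$k_modes * n_struct,
                                             sd = pspec$mode_appearance_sd),
                                nrow = pspec$k_modes)),
    member_offsets = cbind(stats::rnorm(n, sd = pspec$member_appearance_sd / 2),
                           matrix(stats::rnorm(n * n_struct,
                                               sd = pspec$member_appearance_sd),
                                  nrow = n))))
  axis_spread <- (1 - pspec$jitter_frac) * pspec$within_mode_disp
  jitter_disp <- pspec$jitter_frac * pspec$within_mode_disp

  members <- list()
  true_fields <- list()
  mode_assignment <- integer(0)
  idx <- 0L
  for (m in seq_len(pspec$k_modes)) {
    D_m <- random_smooth_field(d, pspec$between_mode_disp,
                               seed = rand$seeds[m],
                               spacing = base_spec$spacing, origin = base_spec$origin)
    sev_axis <- if (pspec$per_mode == 1L) 0
                else seq(-axis_spread, axis_spread, length.out = pspec$per_mode) /
                     pspec$between_mode_disp
    for (k in seq_len(pspec$per_mode)) {
      idx <- idx + 1L
      id <- sprintf("atlas%02d", idx)
      # anatomy of this member: base structures with the mode's appearance
      # offsets plus a per-member micro-offset, rendered noise/bias-free
      anat_spec <- clean_spec
      anat_spec$background_intensity <- base_spec$background_intensity +
        rand$mode_offsets[m, 1L] + rand$member_offsets[idx, 1L]
      for (s in seq_len(n_struct))
        anat_spec$structures[[s]]$intensity <-
          base_spec$structures[[s]]$intensity +
          rand$mode_offsets[m, s + 1L] + rand$member_offsets[idx, s + 1L]
      anat <- make_phantom(anat_spec)
      J <- random_smooth_field(d, jitter_disp,
                               seed = rand$seeds[pspec$k_modes + idx],
                               spacing = base_spec$spacing, origin = base_spec$origin)
      V <- displacement_field(sev_axis[k] * D_m$data + J$data,
                              base_spec$spacing, base_spec$origin)
      T_i <- compose_fields(V, D_m)
      img <- warp(anat$image, T_i, "linear")
      lab <- warp(anat$labels, T_i, "nearest")
      member_spec <- base_spec
      member_spec$seed <- rand$seeds[pspec$k_modes + n + idx]
      img <- render_appearance(img, member_spec)
      members[[id]] <- list(id = id, image = img, labels = lab,
                            mode = m, severity = 1 + sev_axis[k])
      true_fields[[id]] <- T_i
      mode_assignment <- c(mode_assignment, m)
    }
  }
  subject_spec <- base_spec
  subject_spec$seed <- rand$seeds[length(rand$seeds)]
  subject_img <- render_appearance(base$image, subject_spec)
  list(members = members,
       mode_assignment = mode_assignment,
       true_fields = true_fields,
       subject = list(image = subject_img, labels = base$labels,
                      true_field = zero_field(base$image)),
       base = base)
}

# Apply a spec's bias field and noise to an already-formed intensity image.
render_appearance <- function(img, spec) {
  arr <- img$data
  d <- dim(arr)
  with_seed(spec$seed, {
    if (spec$bias_amplitude > 0)
      arr <- arr * (1 + spec$bias_amplitude * random_quadratic(d))
    if (spec$noise_sd > 0)
      arr <- arr + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
  })
  volume_image(arr, img$spacing, img$origin)
}

#' Compute oracle pairwise registrations for a population
#'
#' Builds the `"<moving>__to__<fixed>"` registration list the graph and
#' fusion steps consume, from the population's ground-truth fields, for all
#' ordered atlas pairs and all atlas-to-subject pairs.
#'
#' @param pop a population from [make_population].
#' @param subject_id node id used for the subject.
#' @return named list of [displacement_field]s.
#' @export
oracle_registrations <- function(pop, subject_id = "subject") {
  ids <- names(pop$members)
  regs <- list()
  for (i in ids) {
    for (j in ids) {
      if (i == j) next
      regs[[reg_key(i, j)]] <-
        oracle_pair_field(pop$true_fields[[i]], pop$true_fields[[j]])
    }
    regs[[reg_key(i, subject_id)]] <-
      oracle_pair_field(pop$true_fields[[i]], pop$subject$true_field)
  }
  regs
}
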