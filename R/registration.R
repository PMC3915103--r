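#' Pairwise deformable registration
#'
#' The atlas graph needs a dense displacement field for every ordered pair
#' of images.  Registration quality is deliberately pluggable: the novelty
#' of this package is atlas selection and fusion, not registration, so three
#' backends satisfy one contract:
#'
#' * `builtin` -- a deterministic multi-resolution demons-style registrator
#'   (Gaussian-regularised gradient descent on the mean squared intensity
#'   difference).  Adequate for the smooth, moderate deformations of the
#'   phantom suite; not a substitute for a production diffeomorphic tool on
#'   clinical data.
#' * `oracle` -- returns a caller-supplied known field unchanged; used with
#'   the phantom generator, whose ground-truth deformations are known.
#' * `external` -- reads a precomputed field from disk (any registration
#'   tool can be slotted in by writing fields as 3-component NIfTI named
#'   `<moving>__to__<fixed>.nii.gz`).
#'
#' All backends return a pull-back field on the fixed grid: warping the
#' moving image with it approximates the fixed image.
#'
#' @name registration
NULL

registration_result <- function(field, moving_id, fixed_id,
                                initial_msd = NA_real_, residual_msd = NA_real_) {
  structure(list(field = field, moving_id = moving_id, fixed_id = fixed_id,
                 initial_msd = initial_msd, residual_msd = residual_msd),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration %s -> %s, MSD %.4g -> %.4g>\n",
              x$moving_id, x$fixed_id, x$initial_msd, x$residual_msd))
  invisible(x)
}

builtin_defaults <- function() {
  list(levels = 3L,              # pyramid depth (coarsest = 2^(levels-1) downsampling)
       iterations = c(30L, 20L, 10L),  # per level, coarse to fine
       sigma_field = 1.0,        # Gaussian field regularisation per iteration (voxels)
       step = 1.0)               # scaling of the demons force
}

#' Register a moving image to a fixed image
#'
#' @param moving,fixed [volume_image]s of identical shape (the pipeline
#'   assumes all inputs live in a common space).
#' @param backend one of `"builtin"`, `"oracle"`, `"external"`.
#' @param params backend parameters.  `builtin`: `levels`, `iterations`
#'   (vector, coarse to fine), `sigma_field`, `step`.  `oracle`: `field`, a
#'   known [displacement_field].  `external`: `path` to a field file.
#' @param moving_id,fixed_id identifiers recorded in the result.
#' @return a `registration_result` with elements `field`, `moving_id`,
#'   `fixed_id`, `initial_msd`, `residual_msd`.
#' @export
register <- function(moving, fixed,
                     backend = c("builtin", "oracle", "external"),
                     params = list(),
                     moving_id = "moving", fixed_id = "fixed") {
  backend <- match.arg(backend)
  if (!inherits(moving, "volume_image") || !inherits(fixed, "volume_image"))
    validation_error("register expects volume_image inputs")
  if (!same_grid(moving, fixed))
    validation_error("register: image shapes differ (%s vs %s)",
                     paste(grid_dim(moving), collapse = "x"),
                     paste(grid_dim(fixed), collapse = "x"))
  field <- switch(backend,
    oracle = {
      if (is.null(params$field))
        validation_error("oracle backend requires params$field")
      if (!identical(grid_dim(params$field), grid_dim(fixed)))
        validation_error("oracle field shape differs from fixed image shape")
      params$field
    },
    external = {
      if (is.null(params$path))
        validation_error("external backend requires params$path")
      f <- read_field(params$path)
      if (!identical(grid_dim(f), grid_dim(fixed)))
        validation_error("external field '%s' shape differs from fixed image shape",
                         params$path)
      f
    },
    builtin = demons_field(moving, fixed, params)
  )
  init <- intensity_msd(fixed, moving)
  resid <- intensity_msd(fixed, warp(moving, field, "linear"))
  registration_result(field, moving_id, fixed_id, init, resid)
}

#' Register a pair of images in both directions
#'
#' Convenience wrapper populating both directed edges i->j and j->i of the
#' atlas graph.  Directions are computed independently; no inverse
#' consistency is enforced (the graph is directed, so mild asymmetry is
#' tolerated).
#'
#' @inheritParams register
#' @param params_rev parameters for the reverse direction (defaults to
#'   `params`; the oracle backend needs a `field` per direction).
#' @return list with elements `fwd` (moving -> fixed) and `rev`.
#' @export
invertible_pair <- function(moving, fixed,
                            backend = c("builtin", "oracle", "external"),
                            params = list(), params_rev = params,
                            moving_id = "moving", fixed_id = "fixed") {
  backend <- match.arg(backend)
  list(fwd = register(moving, fixed, backend, params, moving_id, fixed_id),
       rev = register(fixed, moving, backend, params_rev, fixed_id, moving_id))
}

# ---------------------------------------------------------------------------
# Built-in demons-style registrator.
#
# Classic additive demons force: with residual r = warped - fixed and g the
# spatial gradient of the warped image, the per-voxel update is
# -r g / (|g|^2 + r^2) (bounded by half a voxel), followed by Gaussian
# smoothing of the accumulated field.  Intensities are rescaled to [0,1]
# jointly so the force balance is invariant to the input intensity scale.
demons_field <- function(moving, fixed, params = list()) {
  p <- utils::modifyList(builtin_defaults(), params)
  levels <- as.integer(p$levels)
  iters <- rep_len(as.integer(p$iterations), levels)
  d_full <- grid_dim(fixed)
  if (any(d_full < 2L)) validation_error("builtin registration needs dims >= 2")

  lo <- min(min(moving$data), min(fixed$data))
  hi <- max(max(moving$data), max(fixed$data))
  rng <- if (hi > lo) hi - lo else 1
  mv <- (moving$data - lo) / rng
  fx <- (fixed$data - lo) / rng

  # image pyramid, element 1 = full resolution
  pyr_m <- list(mv); pyr_f <- list(fx)
  for (l in seq_len(levels - 1L)) {
    if (any(dim(pyr_m[[l]]) < 8L)) { levels <- l; iters <- iters[seq_len(l)]; break }
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
  }

  u <- NULL
  for (lev in rev(seq_len(levels))) {
    m <- pyr_m[[lev]]; f <- pyr_f[[lev]]
    d <- dim(f)
    if (is.null(u)) {
      u <- array(0, dim = c(d, 3L))
    } else {
      scale <- d / dim(pyr_f[[lev + 1L]])
      u_new <- array(0, dim = c(d, 3L))
      for (c in 1:3)
        u_new[, , , c] <- upsample_to(u[, , , c], d, scale) * scale[c]
      u <- u_new
    }
    g <- coord_grids(d)
    best_u <- u
    best_msd <- Inf
    for (it in seq_len(iters[levels - lev + 1L])) {
      px <- g$x + as.vector(u[, , , 1])
      py <- g$y + as.vector(u[, , , 2])
      pz <- g$z + as.vector(u[, , , 3])
      warped <- array(sample_trilinear(m, px, py, pz), dim = d)
      r <- warped - f
      msd <- mean(r^2)
      if (msd < best_msd) { best_msd <- msd; best_u <- u }
      gx <- diff_axis(warped, 1L)
      gy <- diff_axis(warped, 2L)
      gz <- diff_axis(warped, 3L)
      denom <- gx^2 + gy^2 + gz^2 + r^2
      denom[denom < 1e-9] <- 1e-9
      fac <- p$step * r / denom
      u[, , , 1] <- gaussian_smooth(u[, , , 1] - fac * gx, p$sigma_field)
      u[, , , 2] <- gaussian_smooth(u[, , , 2] - fac * gy, p$sigma_field)
      u[, , , 3] <- gaussian_smooth(u[, , , 3] - fac * gz, p$sigma_field)
    }
    # keep the best iterate seen at this level
    px <- g$x + as.vector(u[, , , 1])
    py <- g$y + as.vector(u[, , , 2])
    pz <- g$z + as.vector(u[, , , 3])
    warped <- array(sample_trilinear(m, px, py, pz), dim = d)
    if (mean((warped - f)^2) > best_msd) u <- best_u
  }
  displacement_field(u, fixed$spacing, fixed$origin)
}

# ---------------------------------------------------------------------------
# Oracle field construction from known ground-truth deformations.

#' Exact pairwise field from known ground-truth deformations
#'
#' If two images were generated from a common base as
#' `img_i = warp(base, T_i)` and `img_j = warp(base, T_j)`, the field `U`
#' registering `img_i` (moving) to `img_j` (fixed) satisfies
#' `U(x) = T_j(x) - T_i(x + U(x))`, solved here by fixed-point iteration.
#' With `T_j = 0` this reduces to the inverse of `T_i`.  Used to drive the
#' oracle registration backend on phantom populations.
#'
#' @param moving_true,fixed_true ground-truth base-to-image
#'   [displacement_field]s for the moving and fixed image.
#' @param iterations fixed-point sweeps.
#' @return a [displacement_field] on the fixed grid.
#' @export
oracle_pair_field <- function(moving_true, fixed_true, iterations = 3L) {
  if (!same_grid(moving_true, fixed_true))
    validation_error("oracle_pair_field: grids differ")
  U <- displacement_field(fixed_true$data - moving_true$data,
                          fixed_true$spacing, fixed_true$origin)
  for (i in seq_len(iterations)) {
    s <- sample_field_at(moving_true, U)
    U <- displacement_field(fixed_true$data - s$data,
                            fixed_true$spacing, fixed_true$origin)
  }
  U
}
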