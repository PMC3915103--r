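#' Pairwise similarity terms and edge costs
#'
#' The directed cost graph over atlases and subject uses, for the edge from
#' image i to image j, the weighted sum
#' \deqn{e_{ij} = w_1 \hat M_{ij} + w_2 \hat H_{ij}}
#' where \eqn{M_{ij}} is the mean squared voxel-wise intensity difference
#' between the target and the warped source, \eqn{H_{ij}} is the harmonic
#' energy (mean Frobenius norm of the Jacobian) of the displacement field
#' that registered source to target, and the hats denote min-max
#' normalisation of each term over all edges of the graph, so both terms and
#' the resulting cost live in \eqn{[0,1]}.  Default weights are
#' `w1 = 0.2`, `w2 = 0.8`.
#'
#' @name similarity
NULL

#' Cost weights for combining intensity and shape terms
#'
#' @param w1 weight of the intensity term, in `[0,1]`.
#' @param w2 weight of the shape (harmonic-energy) term; `w1 + w2` must be 1.
#' @return a `cost_weights` object.
#' @export
cost_weights <- function(w1 = 0.2, w2 = 0.8) {
  if (!is_scalar_number(w1) || !is_scalar_number(w2) ||
      w1 < 0 || w1 > 1 || w2 < 0 || w2 > 1)
    validation_error("w1 and w2 must be single numbers in [0,1]")
  if (abs(w1 + w2 - 1) > 1e-10)
    validation_error("w1 + w2 must equal 1 (got %g + %g)", w1, w2)
  structure(list(w1 = w1, w2 = w2), class = "cost_weights")
}

#' Mean squared voxel-wise intensity difference
#'
#' `M = (1/N) * sum_m (i_m - j_m)^2` over the `N` included voxels, where `i`
#' is the target and `j` the source already warped onto the target grid.
#'
#' @param target a [volume_image].
#' @param warped_source a [volume_image] on the same grid.
#' @param mask optional [label_volume]; only voxels with non-zero mask value
#'   contribute to `N`.
#' @return a non-negative scalar (intensity-squared units).
#' @export
intensity_msd <- function(target, warped_source, mask = NULL) {
  if (!same_grid(target, warped_source))
    validation_error("intensity_msd: image shapes differ (%s vs %s)",
                     paste(grid_dim(target), collapse = "x"),
                     paste(grid_dim(warped_source), collapse = "x"))
  sq <- (target$data - warped_source$data)^2
  if (is.null(mask)) return(mean(sq))
  if (!same_grid(target, mask))
    validation_error("intensity_msd: mask shape differs from image shape")
  keep <- mask$data != 0L
  if (!any(keep)) validation_error("intensity_msd: mask is empty")
  mean(sq[keep])
}

#' Per-voxel Frobenius norm of the displacement Jacobian
#'
#' Differentiates the displacement (not the full transform), so the identity
#' transform scores 0 everywhere.  Central differences in the interior,
#' one-sided at the boundary faces; derivatives in voxel units.
#'
#' @param field a [displacement_field] with every dimension >= 2.
#' @return a [volume_image] of Frobenius norms.
#' @export
jacobian_frobenius <- function(field) {
  if (!inherits(field, "displacement_field"))
    validation_error("jacobian_frobenius expects a displacement_field")
  d <- dim(field$data)[1:3]
  if (any(d < 2L))
    validation_error("jacobian_frobenius: field is degenerate (dims %s); need >= 2 per axis",
                     paste(d, collapse = "x"))
  acc <- array(0, dim = d)
  for (comp in 1:3) {
    u <- field$data[, , , comp]
    for (axis in 1:3) acc <- acc + diff_axis(u, axis)^2
  }
  volume_image(sqrt(acc), field$spacing, field$origin)
}

#' Harmonic energy of a displacement field
#'
#' The mean over (optionally masked) voxels of the Frobenius norm of the
#' displacement Jacobian; a dimensionless summary of deformation magnitude
#' and irregularity used as the shape similarity term of the atlas graph.
#'
#' @param field a [displacement_field].
#' @param mask optional [label_volume] restricting the mean.
#' @return a non-negative scalar.
#' @export
harmonic_energy <- function(field, mask = NULL) {
  fro <- jacobian_frobenius(field)$data
  if (is.null(mask)) return(mean(fro))
  if (!identical(dim(fro), grid_dim(mask)))
    validation_error("harmonic_energy: mask shape differs from field shape")
  keep <- mask$data != 0L
  if (!any(keep)) validation_error("harmonic_energy: mask is empty")
  mean(fro[keep])
}

#' Jointly min-max normalise similarity term matrices
#'
#' The intensity term (intensity-squared units) and the harmonic energy
#' (dimensionless) are incommensurate, so each is rescaled to `[0,1]` over
#' all finite entries of its matrix before the weighted combination.  If all
#' finite entries of a term coincide, that term is mapped to 0.
#'
#' @param all_M,all_H numeric matrices of raw term values over graph edges;
#'   `NA`/`Inf` entries mark absent edges and are left untouched.
#' @return a list with normalised matrices `M` and `H`.
#' @export
normalize_terms <- function(all_M, all_H) {
  norm_one <- function(x, what) {
    fin <- is.finite(x)
    if (any(x[fin] < 0))
      validation_error("normalize_terms: negative %s entry", what)
    if (!any(fin)) return(x)
    lo <- min(x[fin]); hi <- max(x[fin])
    if (hi == lo) { x[fin] <- 0; return(x) }
    x[fin] <- (x[fin] - lo) / (hi - lo)
    x
  }
  list(M = norm_one(all_M, "intensity"), H = norm_one(all_H, "harmonic-energy"))
}

#' Weighted edge cost from normalised terms
#'
#' @param Mhat,Hhat normalised terms in `[0,1]` (scalars or equal-shape arrays).
#' @param w a [cost_weights].
#' @return `w1 * Mhat + w2 * Hhat`, in `[0,1]`.
#' @export
edge_cost <- function(Mhat, Hhat, w = cost_weights()) {
  if (!inherits(w, "cost_weights")) validation_error("w must be a cost_weights object")
  chk <- c(Mhat, Hhat)
  chk <- chk[is.finite(chk)]
  if (any(chk < 0 | chk > 1))
    validation_error("edge_cost inputs must be normalised to [0,1]")
  w$w1 * Mhat + w$w2 * Hhat
}
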