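#' Segmentation evaluation metrics
#'
#' Per-structure agreement between an automated and a reference label map:
#' * Dice similarity coefficient, `DSC = 2 |A n B| / (|A| + |B|) x 100%`
#'   (100 = complete volumetric overlap, 0 = disjoint);
#' * symmetric mean absolute surface distance (MAD, mm): the average, over
#'   both directions, of the mean distance from one segmentation's surface
#'   to the other's;
#' * symmetric Hausdorff distance (mm): the worst surface-to-surface
#'   distance over both directions.
#'
#' Surfaces are mask voxels with at least one face-adjacent (6-connected)
#' background neighbour; voxels on the grid boundary count the outside as
#' background.  Distances run voxel-centre to voxel-centre through an exact
#' Euclidean distance transform that honours anisotropic spacing.
#'
#' @name metrics
NULL

as_mask <- function(x, what = "mask") {
  if (inherits(x, c("label_volume", "volume_image"))) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    validation_error("%s must be a 3-D array or label_volume", what)
  x != 0
}

#' Dice similarity coefficient (percent)
#'
#' When `label` is given, both volumes are binarised to that label first.
#' Two empty masks agree perfectly (100); one empty mask scores 0.
#'
#' @param auto,ref [label_volume]s (or 3-D arrays) of identical shape.
#' @param label optional label id to binarise on; default compares non-zero
#'   masks.
#' @return DSC in `[0, 100]`.
#' @export
dice <- function(auto, ref, label = NULL) {
  a <- if (inherits(auto, c("label_volume", "volume_image"))) auto$data else auto
  r <- if (inherits(ref, c("label_volume", "volume_image"))) ref$data else ref
  if (!identical(dim(a), dim(r)))
    validation_error("dice: shapes differ (%s vs %s)",
                     paste(dim(a), collapse = "x"), paste(dim(r), collapse = "x"))
  am <- if (is.null(label)) a != 0 else a == label
  rm_ <- if (is.null(label)) r != 0 else r == label
  na <- sum(am); nr <- sum(rm_)
  if (na + nr == 0L) return(100)
  200 * sum(am & rm_) / (na + nr)
}

# ---------------------------------------------------------------------------
# Exact Euclidean distance transform (squared), separable lower-envelope
# algorithm, one pass per axis with physical sample spacing.

edt_sq_1d <- function(f, s) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- s * (seq_len(n) - 1)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2L:n) {
    repeat {
      p <- v[k]
      sep <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (k > 1L && sep <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- sep
    z[k + 1L] <- Inf
  }
  k <- 1L
  out <- numeric(n)
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  out
}

BIG_DIST_SQ <- 1e12

# Distance (mm) from every voxel centre to the nearest TRUE voxel centre.
distance_map <- function(set, spacing) {
  if (!any(set)) validation_error("distance_map: empty point set")
  d <- dim(set)
  f <- array(ifelse(set, 0, BIG_DIST_SQ), dim = d)
  for (axis in 1:3) {
    if (d[axis] == 1L) next
    perm <- c(axis, setdiff(1:3, axis))
    tmp <- aperm(f, perm)
    m <- matrix(tmp, d[axis], prod(d[-axis]))
    m <- apply(m, 2L, edt_sq_1d, s = spacing[axis])
    f <- aperm(array(m, dim = d[perm]), order(perm))
  }
  sqrt(f)
}

surface_mask <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- function(di, dj, dk)
    pad[2:(d[1] + 1) + di, 2:(d[2] + 1) + dj, 2:(d[3] + 1) + dk, drop = FALSE]
  bg_neighbour <- !core(1, 0, 0) | !core(-1, 0, 0) |
                  !core(0, 1, 0) | !core(0, -1, 0) |
                  !core(0, 0, 1) | !core(0, 0, -1)
  mask & array(bg_neighbour, dim = d)
}

#' Surface voxels of a binary mask
#'
#' @param mask a binary [label_volume] or logical/numeric 3-D array.
#' @return integer matrix of 0-based voxel coordinates (one row per surface
#'   voxel).
#' @export
surface_voxels <- function(mask) {
  m <- as_mask(mask)
  if (!any(m)) validation_error("surface_voxels: empty mask")
  which(surface_mask(m), arr.ind = TRUE) - 1L
}

surface_distances <- function(auto_mask, ref_mask, spacing) {
  sa <- surface_mask(auto_mask)
  sr <- surface_mask(ref_mask)
  da <- distance_map(sr, spacing)[sa]   # auto surface -> ref surface
  dr <- distance_map(sa, spacing)[sr]   # ref surface -> auto surface
  list(a2r = da, r2a = dr)
}

check_mask_pair <- function(auto, ref, what) {
  a <- as_mask(auto, "auto"); r <- as_mask(ref, "ref")
  if (!identical(dim(a), dim(r)))
    validation_error("%s: shapes differ", what)
  if (!any(a) || !any(r)) {
    warning(sprintf("%s: empty mask; metric undefined (NA)", what))
    return(NULL)
  }
  list(a = a, r = r)
}

#' Symmetric mean absolute surface distance (mm)
#'
#' @param auto_mask,ref_mask binary [label_volume]s or 3-D arrays.
#' @param spacing voxel size in mm (3-vector; defaults to the volume's
#'   spacing when a label_volume is passed).
#' @return MAD in mm, or `NA` (with a warning) if either mask is empty.
#' @export
mad_surface <- function(auto_mask, ref_mask, spacing = NULL) {
  spacing <- resolve_spacing(spacing, auto_mask)
  mp <- check_mask_pair(auto_mask, ref_mask, "mad_surface")
  if (is.null(mp)) return(NA_real_)
  sd_ <- surface_distances(mp$a, mp$r, spacing)
  (mean(sd_$a2r) + mean(sd_$r2a)) / 2
}

#' Symmetric Hausdorff distance (mm)
#'
#' The exact maximum (no percentile variant) of surface-to-surface
#' distances over both directions.
#'
#' @inheritParams mad_surface
#' @return Hausdorff distance in mm, or `NA` if either mask is empty.
#' @export
hausdorff <- function(auto_mask, ref_mask, spacing = NULL) {
  spacing <- resolve_spacing(spacing, auto_mask)
  mp <- check_mask_pair(auto_mask, ref_mask, "hausdorff")
  if (is.null(mp)) return(NA_real_)
  sd_ <- surface_distances(mp$a, mp$r, spacing)
  max(max(sd_$a2r), max(sd_$r2a))
}

resolve_spacing <- function(spacing, vol) {
  if (!is.null(spacing)) return(check_vec3(spacing, "spacing"))
  if (inherits(vol, c("label_volume", "volume_image"))) return(vol$spacing)
  c(1, 1, 1)
}

#' Evaluate a segmentation against a reference, per structure
#'
#' One row per requested label with DSC (percent), MAD (mm) and Hausdorff
#' (mm), plus an unweighted `mean` row.  Labels absent from the reference
#' are flagged in the `note` column and excluded from the means.
#'
#' @param auto,ref [label_volume]s of identical shape.
#' @param labels integer label ids to evaluate (default: all non-zero
#'   labels of the reference).
#' @param spacing voxel size in mm; defaults to the reference's spacing.
#' @return a `data.frame` with columns `label`, `dsc_percent`, `mad_mm`,
#'   `hausdorff_mm`, `note`.
#' @export
evaluate_all <- function(auto, ref, labels = NULL, spacing = NULL) {
  if (!identical(grid_dim(auto), grid_dim(ref)))
    validation_error("evaluate_all: shapes differ")
  spacing <- resolve_spacing(spacing, ref)
  if (is.null(labels))
    labels <- setdiff(sort(unique(as.vector(ref$data))), 0L)
  rows <- lapply(labels, function(L) {
    am <- auto$data == L
    rm_ <- ref$data == L
    if (!any(rm_))
      return(data.frame(label = L, dsc_percent = NA_real_, mad_mm = NA_real_,
                        hausdorff_mm = NA_real_, note = "absent from reference"))
    dsc <- dice(auto, ref, label = L)
    if (!any(am))
      return(data.frame(label = L, dsc_percent = dsc, mad_mm = NA_real_,
                        hausdorff_mm = NA_real_, note = "absent from auto"))
    sd_ <- surface_distances(am, rm_, spacing)
    data.frame(label = L, dsc_percent = dsc,
               mad_mm = (mean(sd_$a2r) + mean(sd_$r2a)) / 2,
               hausdorff_mm = max(max(sd_$a2r), max(sd_$r2a)),
               note = "")
  })
  out <- do.call(rbind, rows)
  # labels absent from the reference contribute nothing; a label absent from
  # auto still counts its DSC of 0, while its undefined distances drop out
  means <- data.frame(label = NA_integer_,
                      dsc_percent = mean(out$dsc_percent, na.rm = TRUE),
                      mad_mm = mean(out$mad_mm, na.rm = TRUE),
                      hausdorff_mm = mean(out$hausdorff_mm, na.rm = TRUE),
                      note = "mean")
  rbind(out, means)
}
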