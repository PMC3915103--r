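#' Core volume types
#'
#' `atlasfuse` works with three simple in-memory containers:
#' * `volume_image`: a 3-D scalar intensity grid with voxel spacing (mm) and
#'   a world origin (mm);
#' * `label_volume`: a 3-D grid of non-negative integer label IDs
#'   (0 = background) with the same geometry slots;
#' * `displacement_field`: a per-voxel 3-vector field defined over a fixed
#'   image grid, stored as a 4-D array `(nx, ny, nz, 3)`.
#'
#' Displacement fields follow the pull-back convention used throughout the
#' package: a field `u` defined on the fixed grid warps a moving image via
#' `out(x) = moving(x + u(x))`, with both `x` and `u` expressed in 0-based
#' voxel units of the fixed grid.  This is the convention under which labels
#' warped by an atlas-to-subject field land on the subject grid.
#'
#' @param data numeric 3-D array (4-D with last dimension 3 for fields).
#' @param spacing voxel size in mm per axis, all components positive.
#' @param origin world position of voxel (0,0,0) in mm.
#' @return an object of the corresponding class.
#' @name volume-types
NULL

#' @rdname volume-types
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    validation_error("volume_image data must be a 3-D array")
  if (any(dim(data) < 1L))
    validation_error("volume_image dimensions must all be >= 1")
  if (any(!is.finite(data)))
    validation_error("volume_image intensities must be finite")
  spacing <- check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) validation_error("spacing components must be > 0")
  origin <- check_vec3(origin, "origin")
  data <- array(as.double(data), dim = dim(data))
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @rdname volume-types
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    validation_error("label_volume data must be a 3-D array")
  if (any(!is.finite(data)))
    validation_error("label_volume values must be finite")
  off <- which(data != round(data) | data < 0)
  if (length(off) > 0L) {
    ijk <- arrayInd(off[1L], dim(data)) - 1L
    validation_error(
      "label values must be non-negative integers; first offending voxel (%d,%d,%d) has value %g",
      ijk[1], ijk[2], ijk[3], data[off[1L]])
  }
  spacing <- check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) validation_error("spacing components must be > 0")
  origin <- check_vec3(origin, "origin")
  data <- array(as.integer(round(data)), dim = dim(data))
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @rdname volume-types
#' @export
displacement_field <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 3L)
    validation_error("displacement_field data must be a 4-D array with 3 components, got %s",
                     paste(dim(data), collapse = "x"))
  if (any(!is.finite(data)))
    validation_error("displacement components must be finite")
  spacing <- check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) validation_error("spacing components must be > 0")
  origin <- check_vec3(origin, "origin")
  data <- array(as.double(data), dim = dim(data))
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "displacement_field")
}

#' @export
dim.volume_image <- function(x) dim(x$data)
#' @export
dim.label_volume <- function(x) dim(x$data)
#' @export
dim.displacement_field <- function(x) dim(x$data)[1:3]

grid_dim <- function(x) {
  if (inherits(x, "displacement_field")) dim(x$data)[1:3] else dim(x$data)
}

same_grid <- function(a, b) identical(grid_dim(a), grid_dim(b))

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$data)))
  cat(sprintf("<label_volume %s, labels {%s}>\n",
              paste(dim(x$data), collapse = "x"),
              paste(labs, collapse = ",")))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat(sprintf("<displacement_field %s, max |u| = %.4g vox>\n",
              paste(dim(x$data)[1:3], collapse = "x"), max(mag)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# NIfTI I/O

nifti_with_geometry <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd == 3L) spacing else c(spacing, rep(1, nd - 3L))
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::qform(img) <- structure(m, code = 2L)
  img
}

geometry_from_nifti <- function(img) {
  pd <- RNifti::pixdim(img)[1:3]
  hd <- RNifti::niftiHeader(img)
  list(spacing = as.numeric(pd),
       origin = as.numeric(c(hd$qoffset_x, hd$qoffset_y, hd$qoffset_z)))
}

#' Read a scalar or label volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3-D volume.
#' @param as_labels if `TRUE`, voxel values are checked to be non-negative
#'   integers and a [label_volume] is returned; otherwise a [volume_image].
#' @return a [volume_image] or [label_volume].
#' @export
read_volume <- function(path, as_labels = FALSE) {
  if (!file.exists(path) || dir.exists(path))
    io_error("cannot read volume: no such file '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) io_error("failed to read NIfTI '%s': %s",
                                               path, conditionMessage(e)))
  arr <- drop(as.array(img))
  if (length(dim(arr)) != 3L)
    validation_error("'%s' is not a 3-D volume (dims %s)", path,
                     paste(dim(as.array(img)), collapse = "x"))
  geo <- geometry_from_nifti(img)
  if (as_labels) label_volume(arr, geo$spacing, geo$origin)
  else volume_image(arr, geo$spacing, geo$origin)
}

#' Write a volume or label map to a NIfTI file
#'
#' Label volumes are stored as 32-bit integers (lossless round-trip);
#' intensity volumes as 64-bit floats.
#'
#' @param vol a [volume_image] or [label_volume].
#' @param path output path; the parent directory must exist.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, c("volume_image", "label_volume")))
    validation_error("write_volume expects a volume_image or label_volume")
  if (dir.exists(path))
    io_error("cannot write volume: '%s' is a directory", path)
  if (!dir.exists(dirname(path)))
    io_error("cannot write volume: parent directory '%s' does not exist", dirname(path))
  img <- nifti_with_geometry(vol$data, vol$spacing, vol$origin)
  dtype <- if (inherits(vol, "label_volume")) "int32" else "double"
  tryCatch(RNifti::writeNifti(img, path, datatype = dtype),
           error = function(e) io_error("failed to write '%s': %s", path,
                                        conditionMessage(e)))
  invisible(NULL)
}

#' Read / write displacement fields
#'
#' Fields are stored as multi-component NIfTI with dimensions
#' `(nx, ny, nz, 1, 3)` and intent code 1007 (vector), components in voxel
#' units of the fixed grid.  A 4-D `(nx, ny, nz, 3)` layout is also accepted
#' on read.
#'
#' @param path path to the field file.
#' @return a [displacement_field].
#' @export
read_field <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    io_error("cannot read field: no such file '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) io_error("failed to read NIfTI '%s': %s",
                                               path, conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(arr, dim = d[c(1, 2, 3, 5)])
    d <- dim(arr)
  }
  if (length(d) != 4L || d[4] != 3L)
    validation_error("'%s' is not a 3-component displacement field (found %d components)",
                     path, if (length(d) >= 4L) d[length(d)] else 1L)
  geo <- geometry_from_nifti(img)
  displacement_field(arr, geo$spacing, geo$origin)
}

#' @rdname read_field
#' @param field a [displacement_field] to write.
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "displacement_field"))
    validation_error("write_field expects a displacement_field")
  if (!dir.exists(dirname(path)))
    io_error("cannot write field: parent directory '%s' does not exist", dirname(path))
  d <- dim(field$data)
  arr5 <- array(field$data, dim = c(d[1:3], 1L, 3L))
  img <- nifti_with_geometry(arr5, field$spacing, field$origin)
  img$intent_code <- 1007L
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e) io_error("failed to write '%s': %s", path,
                                        conditionMessage(e)))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Interpolation / warping

# Trilinear sampling of a 3-D array at continuous 0-based coordinates.
# Points outside [-1, dim-1+1) sample a zero background; points straddling
# the boundary blend with zero, so intensities fade rather than clamp.
sample_trilinear <- function(arr, px, py, pz) {
  d <- dim(arr)
  out <- numeric(length(px))
  ok <- px > -1 & px < d[1] & py > -1 & py < d[2] & pz > -1 & pz < d[3]
  if (!any(ok)) return(out)
  px <- px[ok]; py <- py[ok]; pz <- pz[ok]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  pd <- d + 2L
  pad <- array(0, dim = pd)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  # 0-based voxel v sits at padded 1-based index v + 2; gather via linear
  # indices into the padded vector for speed
  sx <- pd[1]; sxy <- pd[1] * pd[2]
  base <- (i0 + 2) + (j0 + 1) * sx + (k0 + 1) * sxy
  val <-
    (1 - fx) * (1 - fy) * (1 - fz) * pad[base] +
    fx       * (1 - fy) * (1 - fz) * pad[base + 1] +
    (1 - fx) * fy       * (1 - fz) * pad[base + sx] +
    fx       * fy       * (1 - fz) * pad[base + sx + 1] +
    (1 - fx) * (1 - fy) * fz       * pad[base + sxy] +
    fx       * (1 - fy) * fz       * pad[base + sxy + 1] +
    (1 - fx) * fy       * fz       * pad[base + sxy + sx] +
    fx       * fy       * fz       * pad[base + sxy + sx + 1]
  out[ok] <- val
  out
}

# Nearest-neighbour sampling; out-of-grid points return 0 (background).
sample_nearest <- function(arr, px, py, pz) {
  d <- dim(arr)
  out <- numeric(length(px))
  i <- round(px); j <- round(py); k <- round(pz)
  ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
  out[ok] <- arr[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
  out
}

# 0-based coordinate grids for a given shape, as long vectors in array order.
coord_grids <- function(d) {
  list(x = rep(0:(d[1] - 1), times = d[2] * d[3]),
       y = rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
       z = rep(0:(d[3] - 1), each = d[1] * d[2]))
}

#' Warp a volume with a displacement field
#'
#' Applies the pull-back transform `out(x) = vol(x + u(x))`, `x` and `u` in
#' 0-based voxel units of the fixed grid (the field's grid, which is also
#' the output grid).  Samples falling outside the moving volume map to 0
#' (background).  Label volumes must use nearest-neighbour interpolation so
#' no new label values are invented.
#'
#' @param vol a [volume_image] or [label_volume] (the moving image).
#' @param field a [displacement_field] on the fixed (output) grid.
#' @param interpolation `"linear"` (intensities only) or `"nearest"`.
#' @return a warped volume of the same class as `vol`, on the field's grid.
#' @export
warp <- function(vol, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(field, "displacement_field"))
    validation_error("warp expects a displacement_field")
  is_labels <- inherits(vol, "label_volume")
  if (!is_labels && !inherits(vol, "volume_image"))
    validation_error("warp expects a volume_image or label_volume")
  if (is_labels && interpolation == "linear")
    validation_error("label volumes must be warped with nearest-neighbour interpolation")
  d <- dim(field$data)[1:3]
  g <- coord_grids(d)
  px <- g$x + as.vector(field$data[, , , 1])
  py <- g$y + as.vector(field$data[, , , 2])
  pz <- g$z + as.vector(field$data[, , , 3])
  v <- if (interpolation == "linear") sample_trilinear(vol$data, px, py, pz)
       else sample_nearest(vol$data, px, py, pz)
  arr <- array(v, dim = d)
  if (is_labels) label_volume(arr, field$spacing, field$origin)
  else volume_image(arr, field$spacing, field$origin)
}

# Trilinear sampling of all 3 components of a field array at once; the
# interpolation weights are computed a single time and reused per component.
sample_trilinear3 <- function(arr4, px, py, pz) {
  d <- dim(arr4)[1:3]
  n <- length(px)
  out <- matrix(0, n, 3L)
  ok <- px > -1 & px < d[1] & py > -1 & py < d[2] & pz > -1 & pz < d[3]
  if (!any(ok)) return(out)
  px <- px[ok]; py <- py[ok]; pz <- pz[ok]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  pd <- d + 2L
  pad <- array(0, dim = c(pd, 3L))
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- arr4
  sx <- pd[1]; sxy <- pd[1] * pd[2]; comp_off <- prod(pd)
  b <- (i0 + 2) + (j0 + 1) * sx + (k0 + 1) * sxy
  w000 <- (1 - fx) * (1 - fy) * (1 - fz); w100 <- fx * (1 - fy) * (1 - fz)
  w010 <- (1 - fx) * fy * (1 - fz);       w110 <- fx * fy * (1 - fz)
  w001 <- (1 - fx) * (1 - fy) * fz;       w101 <- fx * (1 - fy) * fz
  w011 <- (1 - fx) * fy * fz;             w111 <- fx * fy * fz
  for (c in 1:3) {
    base <- b + (c - 1L) * comp_off
    out[ok, c] <-
      w000 * pad[base] + w100 * pad[base + 1] +
      w010 * pad[base + sx] + w110 * pad[base + sx + 1] +
      w001 * pad[base + sxy] + w101 * pad[base + sxy + 1] +
      w011 * pad[base + sxy + sx] + w111 * pad[base + sxy + sx + 1]
  }
  out
}

# Warp each component of a displacement field `f` by sampling it at x + u(x)
# for a carrier field `u` (trilinear, zero outside).  Internal building block
# for field composition and inversion.
sample_field_at <- function(f, u) {
  d <- dim(u$data)[1:3]
  g <- coord_grids(d)
  px <- g$x + as.vector(u$data[, , , 1])
  py <- g$y + as.vector(u$data[, , , 2])
  pz <- g$z + as.vector(u$data[, , , 3])
  displacement_field(array(sample_trilinear3(f$data, px, py, pz), dim = c(d, 3L)),
                     u$spacing, u$origin)
}

# Zero field on the grid of a reference volume.
zero_field <- function(ref) {
  d <- grid_dim(ref)
  displacement_field(array(0, dim = c(d, 3L)), ref$spacing, ref$origin)
}

#' Compose two displacement fields
#'
#' Returns the field of the composite warp "apply `b`, then apply `a`":
#' `warp(warp(img, b), a)` equals `warp(img, compose_fields(a, b))` up to
#' interpolation error, with `u(x) = a(x) + b(x + a(x))`.
#'
#' @param a,b [displacement_field]s on the same grid.
#' @return a [displacement_field].
#' @export
compose_fields <- function(a, b) {
  if (!same_grid(a, b))
    validation_error("compose_fields: grids differ")
  bs <- sample_field_at(b, a)
  displacement_field(a$data + bs$data, a$spacing, a$origin)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the field `v` with `v(x) = -u(x + v(x))`, the
#' pull-back inverse of `u`.  Accurate for smooth, moderate fields; used by
#' the oracle registration backend on synthetic data.
#'
#' @param u a [displacement_field].
#' @param iterations number of fixed-point sweeps.
#' @return a [displacement_field] approximating the inverse of `u`.
#' @export
invert_field <- function(u, iterations = 8L) {
  v <- displacement_field(-u$data, u$spacing, u$origin)
  for (i in seq_len(iterations)) {
    s <- sample_field_at(u, v)
    v <- displacement_field(-s$data, u$spacing, u$origin)
  }
  v
}
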