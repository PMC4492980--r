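#' 3-D image volume
#'
#' Lightweight container for a 3-D scalar lattice with a 4x4 voxel-to-world
#' affine (mm, RAS+, 0-based voxel indices) and a unit tag.  All images in the
#' pipeline (CT in Hounsfield units, PET in SUV-like units, probability maps,
#' integer label maps) are carried in this structure.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; last row must be (0,0,0,1) and the
#'   upper-left 3x3 block must be invertible.
#' @param unit one of `"HU"`, `"SUV"`, `"probability"`, `"label"`,
#'   `"arbitrary"`.
#' @param meta optional named list of free-form metadata (e.g. the shift
#'   applied by [offset_to_nonnegative()]).
#' @return An object of class `ct_volume`.
#' @export
new_volume <- function(data, affine = diag(4), unit = "arbitrary", meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 10)
    stop("volume affine is not invertible")
  unit <- match.arg(unit, c("HU", "SUV", "probability", "label", "arbitrary"))
  if (unit == "probability") {
    rng <- range(data, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("probability volume must lie in [0, 1]")
  }
  if (unit == "label") {
    if (any(data < 0) || any(data != round(data)))
      stop("label volume must contain non-negative integers")
    storage.mode(data) <- "integer"
  }
  structure(list(data = data, affine = affine, unit = unit, meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_size(x)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, unit=%s\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3], x$unit))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname new_volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "ct_volume")

#' Voxel dimensions in mm
#' @param vol a `ct_volume`.
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Grid descriptor of a volume
#'
#' A grid is the geometry of a volume without its data: integer dimensions
#' plus the voxel-to-world affine.  Templates, deformation fields and
#' resampling targets are all specified as grids.
#'
#' @param dim integer length-3 dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A list with elements `dim` and `affine`, class `ct_grid`.
#' @export
make_grid <- function(dim, affine) {
  structure(list(dim = as.integer(dim), affine = as.matrix(affine)),
            class = "ct_grid")
}

#' @rdname make_grid
#' @param vol a `ct_volume`.
#' @export
vol_grid <- function(vol) make_grid(dim(vol$data), vol$affine)

#' Centered isotropic grid
#'
#' Convenience constructor for a world-centered isotropic RAS+ grid, the
#' default space for phantoms and templates.
#'
#' @param n voxels per axis (scalar or length 3).
#' @param spacing voxel size in mm (default 2, the conventional template
#'   resolution; phantoms use coarser grids).
#' @return A `ct_grid` whose world origin sits at the grid center.
#' @export
iso_grid <- function(n, spacing = 2) {
  n <- rep_len(as.integer(n), 3L)
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -spacing * (n - 1) / 2
  make_grid(n, aff)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) && max(abs(a$affine - b$affine)) < tol
}

#' Voxel/world coordinate mapping
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
vox_to_world <- function(affine, ijk) {
  ijk <- rbind_pts(ijk)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

#' @rdname vox_to_world
#' @param xyz n x 3 matrix of world coordinates.
#' @export
world_to_vox <- function(affine, xyz) {
  xyz <- rbind_pts(xyz)
  inv <- solve(affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], `+`)
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# World coordinates of every voxel of a grid, as an n x 3 matrix in
# column-major voxel order (the order of as.vector(vol$data)).
grid_world_coords <- function(grid) {
  d <- grid$dim
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  vox_to_world(grid$affine, cbind(i, j, k))
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti.  The unit tag is not part of NIfTI-1; it is
#' supplied by the caller on read and recorded by the cohort manifest on
#' write.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param unit unit tag to attach on read.
#' @return `read_volume` returns a `ct_volume`; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path, unit = "arbitrary") {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  dat <- array(as.numeric(img), dim = dim(img))
  if (unit == "label") storage.mode(dat) <- "integer"
  new_volume(dat, aff, unit)
}

#' @rdname read_volume
#' @param vol a `ct_volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Separable Gaussian smoothing
#'
#' Smooths a volume with an isotropic (in mm) Gaussian kernel applied
#' separably along each axis, with truncated-kernel renormalization at the
#' edges.  Used for the PET point-spread function of the phantom and for the
#' multi-resolution pyramid of the registration engine.
#'
#' @param vol a `ct_volume`.
#' @param fwhm_mm full width at half maximum in mm; 0 returns the input.
#' @return Smoothed `ct_volume` on the same grid.
#' @export
smooth_gaussian <- function(vol, fwhm_mm) {
  if (fwhm_mm <= 0) return(vol)
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sp <- voxel_size(vol)
  out <- vol$data
  for (ax in 1:3) {
    sig <- sig_mm / sp[ax]
    if (sig < 1e-3) next
    out <- conv_axis(out, gauss_kernel(sig), ax)
  }
  new_volume(out, vol$affine, if (vol$unit == "label") "arbitrary" else vol$unit,
             vol$meta)
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Convolve along one axis with edge renormalization via a banded matrix.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[off + r + 1L]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- K %*% matrix(a, nrow = n)
  a <- array(m, dim = da)
  aperm(a, order(perm))
}

#' Trilinear / nearest-neighbour sampling
#'
#' Samples an array at continuous 0-based voxel coordinates.  Points outside
#' the lattice return `fill`.
#'
#' @param arr 3-D array.
#' @param vox n x 3 matrix of continuous 0-based voxel coordinates.
#' @param fill value for out-of-lattice points.
#' @return Numeric vector of n sampled values.
#' @export
sample_trilinear <- function(arr, vox, fill = 0) {
  d <- dim(arr)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(as.numeric(fill), length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  base <- x0 + d[1] * (y0 + d[2] * z0) + 1
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- arr[base];                 v100 <- arr[base + sx]
  v010 <- arr[base + sy];            v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];            v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz];       v111 <- arr[base + sx + sy + sz]
  val <- v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) +
    v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz +
    v111 * fx * fy * fz
  out[inside] <- val
  out
}

#' @rdname sample_trilinear
#' @export
sample_nearest <- function(arr, vox, fill = 0) {
  d <- dim(arr)
  x <- round(vox[, 1]); y <- round(vox[, 2]); z <- round(vox[, 3])
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(as.numeric(fill), length(x))
  if (!any(inside)) return(out)
  idx <- x[inside] + d[1] * (y[inside] + d[2] * z[inside]) + 1
  out[inside] <- arr[idx]
  out
}

# Smooth + decimate one pyramid level: keep every `step`-th voxel, updating
# the affine so world geometry is preserved.
decimate_volume <- function(vol, step) {
  if (step <= 1L) return(vol)
  d <- dim(vol$data)
  ix <- seq(1L, d[1], by = step); iy <- seq(1L, d[2], by = step)
  iz <- seq(1L, d[3], by = step)
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * step
  new_volume(vol$data[ix, iy, iz, drop = FALSE], aff, vol$unit, vol$meta)
}
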