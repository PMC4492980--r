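#' Spatial transforms
#'
#' Transforms are world-to-world (mm) maps used for pull-back resampling:
#' a transform returned by registering `moving` to `fixed` maps points of the
#' fixed space into the moving space, so that resampling `moving` onto the
#' fixed grid is a direct application.  Three concrete kinds exist:
#'
#' * `ct_affine`: a 4x4 matrix (rigid 6-DOF, similarity 9-DOF or full
#'   12-DOF);
#' * `ct_dfield`: a dense displacement synthesized from low-frequency 3-D
#'   discrete-cosine basis coefficients anchored to a grid, `x -> x + d(x)`;
#' * `ct_seq`: a composition, applied right-to-left like matrix products.
#'
#' @name transforms
NULL

#' Affine transform
#' @param matrix 4x4 world-to-world matrix.
#' @param dof degrees of freedom used to build it (6, 9 or 12).
#' @return A `ct_affine` transform.
#' @export
affine_transform <- function(matrix, dof = 12L) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < 1e-12) stop("singular affine transform")
  structure(list(matrix = matrix, dof = as.integer(dof)),
            class = c("ct_affine", "ct_transform"))
}

#' Cosine-basis deformation field
#'
#' The warp is parameterized by coefficients of separable DCT-II basis
#' functions over the anchor grid, the low-frequency family conventional for
#' template normalization.  Displacements are in mm and are defined (by
#' cosine extension) everywhere in space.
#'
#' @param coeffs 4-D array `k1 x k2 x k3 x 3` of basis coefficients (mm).
#' @param grid anchor `ct_grid` on which the basis is defined.
#' @param regularization_weight the bending-energy weight used when the
#'   field was estimated (recorded for provenance).
#' @return A `ct_dfield` transform.
#' @export
dct_field <- function(coeffs, grid, regularization_weight = 0) {
  stopifnot(length(dim(coeffs)) == 4L, dim(coeffs)[4] == 3L)
  structure(list(coeffs = coeffs, grid = grid,
                 regularization_weight = regularization_weight),
            class = c("ct_dfield", "ct_transform"))
}

#' @rdname transforms
#' @param ... transforms, applied right-to-left.
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  flat <- list()
  for (t in ts) {
    if (inherits(t, "ct_seq")) flat <- c(flat, t$parts) else flat <- c(flat, list(t))
  }
  # collapse adjacent affines
  out <- list()
  for (t in flat) {
    n <- length(out)
    if (n > 0 && inherits(t, "ct_affine") && inherits(out[[n]], "ct_affine")) {
      out[[n]] <- affine_transform(out[[n]]$matrix %*% t$matrix,
                                   max(out[[n]]$dof, t$dof))
    } else out <- c(out, list(t))
  }
  if (length(out) == 1L) return(out[[1L]])
  structure(list(parts = out), class = c("ct_seq", "ct_transform"))
}

#' Apply a transform to world points
#' @param t a `ct_transform`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped world coordinates.
#' @export
transform_points <- function(t, pts) UseMethod("transform_points")

#' @export
transform_points.ct_affine <- function(t, pts) {
  pts <- rbind_pts(pts)
  sweep(pts %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], `+`)
}

#' @export
transform_points.ct_dfield <- function(t, pts) {
  pts <- rbind_pts(pts)
  pts + dct_displacement_at(t, pts)
}

#' @export
transform_points.ct_seq <- function(t, pts) {
  for (part in rev(t$parts)) pts <- transform_points(part, pts)
  pts
}

#' @export
transform_points.ct_dfield_inv <- function(t, pts) {
  # fixed-point inversion of x -> x + d(x): solve y + d(y) = x
  pts <- rbind_pts(pts)
  y <- pts
  for (i in seq_len(t$max_iter)) {
    dy <- dct_displacement_at(t$field, y)
    y_new <- pts - dy
    step <- sqrt(rowSums((y_new - y)^2))
    y <- y_new
    if (mean(step) < t$tol) break
  }
  attr(y, "converged") <- mean(step) < t$tol
  y
}

# DCT-II basis matrix for continuous 0-based voxel coordinate u on an axis of
# n voxels: b_k(u) = cos(pi * k * (u + 0.5) / n), k = 0..K-1.
dct_basis_at <- function(u, n, K) {
  outer((u + 0.5) / n * pi, seq_len(K) - 1)  |> cos()
}

dct_displacement_at <- function(field, pts) {
  k <- dim(field$coeffs)[1:3]
  vox <- world_to_vox(field$grid$affine, pts)
  Bx <- dct_basis_at(vox[, 1], field$grid$dim[1], k[1])
  By <- dct_basis_at(vox[, 2], field$grid$dim[2], k[2])
  Bz <- dct_basis_at(vox[, 3], field$grid$dim[3], k[3])
  n <- nrow(vox)
  out <- matrix(0, n, 3)
  cf <- matrix(field$coeffs, nrow = prod(k), ncol = 3)
  # B (n x prod(k)) assembled column-block by z,y for memory locality
  B <- matrix(0, n, prod(k))
  col <- 1L
  for (kz in seq_len(k[3])) for (ky in seq_len(k[2])) for (kx in seq_len(k[1])) {
    B[, col] <- Bx[, kx] * By[, ky] * Bz[, kz]
    col <- col + 1L
  }
  out[] <- B %*% cf
  out
}

# Basis matrix for a full set of sample points (voxel coords), reused by the
# nonlinear optimizer.
dct_basis_matrix <- function(vox, grid_dim, k) {
  Bx <- dct_basis_at(vox[, 1], grid_dim[1], k[1])
  By <- dct_basis_at(vox[, 2], grid_dim[2], k[2])
  Bz <- dct_basis_at(vox[, 3], grid_dim[3], k[3])
  B <- matrix(0, nrow(vox), prod(k))
  col <- 1L
  for (kz in seq_len(k[3])) for (ky in seq_len(k[2])) for (kx in seq_len(k[1])) {
    B[, col] <- Bx[, kx] * By[, ky] * Bz[, kz]
    col <- col + 1L
  }
  B
}

#' Invert a transform
#'
#' Affines invert exactly; deformation fields invert by per-point fixed-point
#' iteration (mean residual < `tol` mm or `max_iter` sweeps); compositions
#' invert part-wise in reverse order.
#'
#' @param t a `ct_transform`.
#' @param tol mean residual displacement (mm) at which field inversion stops.
#' @param max_iter iteration cap for field inversion.
#' @return The inverse `ct_transform`.
#' @export
invert_transform <- function(t, tol = 0.1, max_iter = 50L) {
  if (inherits(t, "ct_affine"))
    return(affine_transform(solve(t$matrix), t$dof))
  if (inherits(t, "ct_dfield"))
    return(structure(list(field = t, tol = tol, max_iter = as.integer(max_iter)),
                     class = c("ct_dfield_inv", "ct_transform")))
  if (inherits(t, "ct_dfield_inv"))
    return(t$field)
  if (inherits(t, "ct_warp"))
    return(structure(list(warp = t, tol = tol, max_iter = as.integer(max_iter)),
                     class = c("ct_warp_inv", "ct_transform")))
  if (inherits(t, "ct_warp_inv"))
    return(t$warp)
  if (inherits(t, "ct_seq")) {
    inv <- lapply(rev(t$parts), invert_transform, tol = tol, max_iter = max_iter)
    return(do.call(compose_transforms, inv))
  }
  stop("unknown transform class")
}

#' Resample a volume through a transform
#'
#' Pull-back resampling: for every voxel of `target_grid`, the source volume
#' is sampled at the transformed world point.  Label and probability-mask
#' volumes should use nearest-neighbour interpolation.
#'
#' @param vol source `ct_volume`.
#' @param t `ct_transform` mapping target-space world points into the
#'   source space (use [identity_transform()] for plain regridding).
#' @param target_grid `ct_grid` of the output.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value outside the source field of view (default: source
#'   minimum, so air stays darkest).
#' @return `ct_volume` on `target_grid`.
#' @export
apply_transform <- function(vol, t, target_grid,
                            interpolation = c("trilinear", "nearest"),
                            fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(fill)) fill <- min(vol$data)
  pts <- grid_world_coords(target_grid)
  src_world <- transform_points(t, pts)
  src_vox <- world_to_vox(vol$affine, src_world)
  vals <- if (interpolation == "nearest")
    sample_nearest(vol$data, src_vox, fill = fill)
  else sample_trilinear(vol$data, src_vox, fill = fill)
  dat <- array(vals, dim = target_grid$dim)
  if (vol$unit == "label") storage.mode(dat) <- "integer"
  new_volume(dat, target_grid$affine, vol$unit, vol$meta)
}

#' @rdname transforms
#' @export
identity_transform <- function() affine_transform(diag(4), dof = 6L)

#' Serialize / restore transforms as JSON (+ NIfTI for dense fields)
#'
#' Affine matrices and DCT coefficients are written into one JSON document;
#' this round-trips every transform kind produced by the engine.
#'
#' @param t a `ct_transform`.
#' @param path output `.json` path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the transform.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(transform_to_list(t), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

transform_to_list <- function(t) {
  if (inherits(t, "ct_affine"))
    return(list(kind = "affine", dof = t$dof, matrix = as.vector(t$matrix)))
  if (inherits(t, "ct_dfield"))
    return(list(kind = "dct_field",
                coeffs = as.vector(t$coeffs), kdim = dim(t$coeffs),
                grid_dim = t$grid$dim, grid_affine = as.vector(t$grid$affine),
                regularization_weight = t$regularization_weight))
  if (inherits(t, "ct_dfield_inv"))
    return(list(kind = "inverse", of = transform_to_list(t$field)))
  if (inherits(t, "ct_warp"))
    return(list(kind = "warp", affine = transform_to_list(t$affine),
                field = transform_to_list(t$field)))
  if (inherits(t, "ct_warp_inv"))
    return(list(kind = "inverse", of = transform_to_list(t$warp)))
  if (inherits(t, "ct_seq"))
    return(list(kind = "sequence", parts = lapply(t$parts, transform_to_list)))
  stop("unknown transform class")
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

transform_from_list <- function(l) {
  num <- function(x) as.numeric(unlist(x))
  switch(l$kind,
    affine = affine_transform(matrix(num(l$matrix), 4, 4), l$dof),
    dct_field = dct_field(array(num(l$coeffs), dim = num(l$kdim)),
                          make_grid(num(l$grid_dim),
                                    matrix(num(l$grid_affine), 4, 4)),
                          num(l$regularization_weight)),
    inverse = invert_transform(transform_from_list(l$of)),
    warp = structure(list(affine = transform_from_list(l$affine),
                          field = transform_from_list(l$field)),
                     class = c("ct_warp", "ct_transform")),
    sequence = do.call(compose_transforms,
                       lapply(l$parts, transform_from_list)),
    stop("unknown transform kind in file"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
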