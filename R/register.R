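#' Registration configuration
#'
#' Conventional template-normalization settings: multi-resolution pyramids
#' described as `(smoothing FWHM mm, decimation step)` pairs, a 32-bin joint
#' histogram for normalized mutual information, a low-frequency cosine basis
#' (default 8 components per axis, the conventional 25 mm cutoff on a 192 mm
#' head field of view) with bending-energy regularization for the nonlinear
#' stage, and Levenberg-damped Gauss-Newton / Nelder-Mead optimizers with a
#' relative-cost convergence tolerance.  The nonlinear stage runs entirely
#' at 8 mm smoothness, the working smoothness conventional for template
#' normalization; finer schedules with a smaller basis (e.g. `basis_k = 6`,
#' `nl_levels = list(c(8,3), c(4,2), c(2,2))`) trade speed for precision in
#' same-modality warp recovery.  Registration is deterministic given its
#' inputs.
#'
#' @param rigid_levels,affine_levels,nl_levels lists of `c(fwhm_mm, step)`.
#' @param nmi_bins joint-histogram bins for the NMI metric.
#' @param basis_k cosine basis size per axis of the nonlinear warp.
#' @param lambda bending-energy weight of the nonlinear warp.
#' @param max_iter iteration cap per level.
#' @param tol relative cost-change convergence tolerance.
#' @return Named configuration list.
#' @export
register_config <- function(rigid_levels = list(c(8, 3), c(4, 2), c(2, 1)),
                            affine_levels = list(c(8, 2), c(4, 1)),
                            nl_levels = list(c(8, 3)),
                            nmi_bins = 32L, basis_k = 8L, lambda = 5,
                            max_iter = 64L, tol = 1e-4) {
  list(rigid_levels = rigid_levels, affine_levels = affine_levels,
       nl_levels = nl_levels, nmi_bins = as.integer(nmi_bins),
       basis_k = as.integer(basis_k), lambda = lambda,
       max_iter = as.integer(max_iter), tol = tol)
}

#' Build an affine matrix from pose parameters
#'
#' Parameter order: translations (mm), rotations (radians, applied as
#' `Rx Ry Rz`), log-scales, shears.  The matrix is `T R S H`.
#'
#' @param p numeric vector of up to 12 parameters (missing tail = identity).
#' @return 4x4 matrix.
#' @export
affine_from_params <- function(p) {
  p <- c(p, rep(0, 12 - length(p)))
  tr <- p[1:3]; r <- p[4:6]; s <- exp(p[7:9]); h <- p[10:12]
  Rx <- diag(4); Rx[2:3, 2:3] <- matrix(c(cos(r[1]), sin(r[1]),
                                          -sin(r[1]), cos(r[1])), 2)
  Ry <- diag(4); Ry[c(1, 3), c(1, 3)] <- matrix(c(cos(r[2]), -sin(r[2]),
                                                  sin(r[2]), cos(r[2])), 2)
  Rz <- diag(4); Rz[1:2, 1:2] <- matrix(c(cos(r[3]), sin(r[3]),
                                          -sin(r[3]), cos(r[3])), 2)
  S <- diag(c(s, 1))
  H <- diag(4); H[1, 2] <- h[1]; H[1, 3] <- h[2]; H[2, 3] <- h[3]
  Tm <- diag(4); Tm[1:3, 4] <- tr
  Tm %*% Rx %*% Ry %*% Rz %*% S %*% H
}

registration_result <- function(transform, final_cost, initial_cost,
                                iterations, converged) {
  structure(list(transform = transform, final_cost = final_cost,
                 initial_cost = initial_cost, iterations = iterations,
                 converged = converged), class = "ct_registration")
}

#' @export
print.ct_registration <- function(x, ...) {
  cat(sprintf("<ct_registration> cost %.6g -> %.6g in %d iterations (%s)\n",
              x$initial_cost, x$final_cost, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

check_not_constant <- function(vol, what) {
  if (diff(range(vol$data)) <= 0)
    stop(sprintf("%s image is constant; registration undefined", what))
}

prep_level <- function(vol, fwhm, step, standardize = TRUE) {
  v <- smooth_gaussian(vol, fwhm)
  if (step > 1L) v <- decimate_volume(v, step)
  if (standardize) {
    s <- stats::sd(as.vector(v$data))
    v$data <- (v$data - mean(v$data)) / (s + 1e-12)
  }
  v
}

center_of_mass <- function(vol) {
  w <- as.vector(vol$data) - min(vol$data)
  if (sum(w) <= 0) return(c(0, 0, 0))
  pts <- grid_world_coords(vol_grid(vol))
  colSums(pts * w) / sum(w)
}

# Sample a (smoothed, standardized) moving volume at world points, returning
# values and an inside-FOV mask.
sample_moving <- function(mov, world_pts, fill) {
  vox <- world_to_vox(mov$affine, world_pts)
  d <- dim(mov$data)
  inside <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  list(values = sample_trilinear(mov$data, vox, fill = fill),
       vox = vox, inside = inside)
}

#' Rigid (6-DOF) registration
#'
#' Multi-resolution Nelder-Mead over translations and rotations, with
#' center-of-mass initialization.  The default metric is negative normalized
#' mutual information (for cross-modality pairs such as PET to CT); `ssd`
#' operates on intensity-standardized smoothed volumes.
#'
#' @param moving,fixed `ct_volume`s overlapping in world space.
#' @param metric `"nmi"` or `"ssd"`.
#' @param config a [register_config()].
#' @return A `ct_registration` whose `transform` maps fixed-space world
#'   points into the moving space (ready for [apply_transform()]).
#' @export
rigid_register <- function(moving, fixed, metric = c("nmi", "ssd"),
                           config = register_config()) {
  metric <- match.arg(metric)
  check_not_constant(moving, "moving"); check_not_constant(fixed, "fixed")
  p0 <- c(center_of_mass(moving) - center_of_mass(fixed), 0, 0, 0)
  p <- p0
  total_iter <- 0L
  init_cost <- final_cost <- NA_real_
  for (lv in config$rigid_levels) {
    f <- prep_level(fixed, lv[1], lv[2], standardize = metric == "ssd")
    m <- prep_level(moving, lv[1], 1L, standardize = metric == "ssd")
    pts <- grid_world_coords(vol_grid(f))
    fv <- as.vector(f$data)
    fill <- min(m$data)
    costf <- function(par) {
      phi <- transform_points(affine_transform(affine_from_params(par), 6L), pts)
      sm <- sample_moving(m, phi, fill)
      if (metric == "ssd") mean((sm$values - fv)^2)
      else -nmi_metric(fv, sm$values, config$nmi_bins)
    }
    init_cost <- costf(p0)  # cost of the initialization at this level
    opt <- stats::optim(p, costf, method = "Nelder-Mead",
                        control = list(maxit = 400,
                                       parscale = c(1, 1, 1, .02, .02, .02),
                                       reltol = config$tol))
    if (opt$value <= costf(p)) p <- opt$par
    total_iter <- total_iter + opt$counts[1]
    if (costf(p) > init_cost) p <- p0  # optimizer failed at this level
    final_cost <- costf(p)
  }
  registration_result(
    affine_transform(affine_from_params(p), dof = 6L),
    final_cost, init_cost, as.integer(total_iter),
    converged = final_cost <= init_cost)
}

nmi_metric <- function(a, b, bins) {
  cut_bins <- function(x) {
    r <- range(x)
    if (diff(r) <= 0) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / diff(r) * bins) + 1L, 1L), bins)
  }
  ia <- cut_bins(a); ib <- cut_bins(b)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  pj <- joint / sum(joint)
  pa <- tapply_sum(pj, rep(seq_len(bins), each = bins))
  pb <- tapply_sum(pj, rep(seq_len(bins), times = bins))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(pa) + ent(pb)) / max(ent(pj), 1e-12)
}

tapply_sum <- function(x, g) as.vector(rowsum(matrix(x, ncol = 1), g))

# Sampled voxel-space image gradient of a volume, returned in world mm units.
world_gradient_at <- function(mov, vox, inside) {
  d <- dim(mov$data)
  g <- matrix(0, nrow(vox), 3)
  central <- function(arr, ax) {
    dp <- shift_num(arr, ax, -1L); dm <- shift_num(arr, ax, 1L)
    (dp - dm) / 2
  }
  A3inv <- solve(mov$affine[1:3, 1:3])
  for (ax in 1:3) {
    gax <- central(mov$data, ax)
    g[, ax] <- sample_trilinear(gax, vox, fill = 0)
  }
  g %*% A3inv  # d/dworld = d/dvox %*% dvox/dworld
}

shift_num <- function(a, axis, off) {
  d <- dim(a)
  out <- array(0, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  o <- off
  if (o >= 0) { dst[[axis]] <- (1 + o):d[axis]; src[[axis]] <- 1:(d[axis] - o) }
  else { dst[[axis]] <- 1:(d[axis] + o); src[[axis]] <- (1 - o):d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  # replicate edge values so gradients stay finite at boundaries
  out
}

#' Affine (12-DOF) registration
#'
#' Sum-of-squared-differences on intensity-standardized, smoothed volumes,
#' minimized by Levenberg-damped Gauss-Newton over translations, rotations,
#' log-scales and shears, with multi-resolution continuation and
#' center-of-mass initialization.
#'
#' @inheritParams rigid_register
#' @param dof 6, 9 or 12 free parameters.
#' @return A `ct_registration` (fixed-world to moving-world transform).
#' @export
affine_register <- function(moving, fixed, dof = 12L,
                            config = register_config()) {
  check_not_constant(moving, "moving"); check_not_constant(fixed, "fixed")
  n_par <- c(`6` = 6L, `9` = 9L, `12` = 12L)[as.character(dof)]
  if (is.na(n_par)) stop("dof must be 6, 9 or 12")
  p0 <- c(center_of_mass(moving) - center_of_mass(fixed), rep(0, n_par - 3))
  p <- p0
  init_cost <- NA_real_; final_cost <- NA_real_; total_iter <- 0L
  for (lv in config$affine_levels) {
    f <- prep_level(fixed, lv[1], lv[2])
    m <- prep_level(moving, lv[1], 1L)
    pts <- grid_world_coords(vol_grid(f))
    fv <- as.vector(f$data)
    fill <- min(m$data)
    cost_at <- function(par) {
      sm <- sample_moving(m, transform_points(
        affine_transform(affine_from_params(par)), pts), fill)
      mean((sm$values - fv)^2)
    }
    init_cost <- cost_at(p0)
    cur <- cost_at(p)
    if (cur > init_cost) { p <- p0; cur <- init_cost }
    mu <- 1e-3
    for (it in seq_len(config$max_iter)) {
      M <- affine_from_params(p)
      phi <- transform_points(affine_transform(M), pts)
      sm <- sample_moving(m, phi, fill)
      r <- sm$values - fv
      w <- as.numeric(sm$inside)
      g <- world_gradient_at(m, sm$vox, sm$inside)
      J <- matrix(0, length(r), n_par)
      h <- 1e-5
      for (j in seq_len(n_par)) {
        pj <- p; pj[j] <- pj[j] + h
        dM <- (affine_from_params(pj) - M) / h
        dphi <- sweep(pts %*% t(dM[1:3, 1:3]), 2, dM[1:3, 4], `+`)
        J[, j] <- rowSums(g * dphi)
      }
      Jw <- J * w
      rhs <- -crossprod(Jw, r * w)
      JtJ <- crossprod(Jw)
      improved <- FALSE
      for (try in 1:6) {
        delta <- tryCatch(solve(JtJ + mu * diag(diag(JtJ) + 1e-8), rhs),
                          error = function(e) NULL)
        if (is.null(delta)) { mu <- mu * 10; next }
        new_cost <- cost_at(p + as.vector(delta))
        if (new_cost < cur) {
          p <- p + as.vector(delta); mu <- mu / 3
          improved <- TRUE
          conv <- (cur - new_cost) / max(cur, 1e-12) < config$tol
          cur <- new_cost
          break
        }
        mu <- mu * 10
      }
      total_iter <- total_iter + 1L
      if (!improved || conv) break
    }
    final_cost <- cur
  }
  registration_result(affine_transform(affine_from_params(p), dof = n_par),
                      final_cost, init_cost, total_iter,
                      converged = final_cost <= init_cost)
}

#' Nonlinear (cosine-basis) registration
#'
#' Estimates low-frequency DCT warp coefficients minimizing mean SSD between
#' the standardized template and the warped moving image plus a
#' bending-energy penalty `lambda * sum_c w_c |c|^2` (with `w_c` the 4th power
#' spatial frequency of basis component `c`), by Levenberg-damped
#' Gauss-Newton.  The returned transform is the composition `x -> A x +
#' d(x)` of the affine initialization and the warp, mapping template-space
#' world points into the moving space.
#'
#' @param moving `ct_volume` to normalize.
#' @param template fixed `ct_volume` defining the target space.
#' @param affine_init a `ct_affine` (e.g. from [affine_register()]); if
#'   `NULL` one is estimated first.
#' @param config a [register_config()].
#' @return A `ct_registration`; `transform` is a `ct_warp` combining the
#'   affine and the deformation field.
#' @export
nonlinear_register <- function(moving, template, affine_init = NULL,
                               config = register_config()) {
  check_not_constant(moving, "moving"); check_not_constant(template, "template")
  if (is.null(affine_init))
    affine_init <- affine_register(moving, template, config = config)$transform
  A <- affine_init$matrix
  tgrid <- vol_grid(template)
  k <- rep_len(config$basis_k, 3L)
  L <- tgrid$dim * voxel_size(template)  # field of view, mm
  cf <- array(0, dim = c(k, 3))
  # bending-energy weight per coefficient: 4th power of spatial frequency
  # (1/mm^4), penalizing curvature of the displacement field
  wk <- array(0, dim = k)
  for (kz in seq_len(k[3])) for (ky in seq_len(k[2])) for (kx in seq_len(k[1]))
    wk[kx, ky, kz] <- ((pi * (kx - 1) / L[1])^2 + (pi * (ky - 1) / L[2])^2 +
                         (pi * (kz - 1) / L[3])^2)^2
  W <- rep(as.vector(wk)[-1], 3)
  init_cost <- NA_real_; final_cost <- NA_real_; total_iter <- 0L
  nb <- prod(k)
  cvec <- numeric(3 * (nb - 1))  # constant term excluded: affine owns it
  for (lv in config$nl_levels) {
    f <- prep_level(template, lv[1], lv[2])
    m <- prep_level(moving, lv[1], 1L)
    pts <- grid_world_coords(vol_grid(f))
    # basis evaluated at template voxel coordinates of the sample points;
    # the constant (DC) component is dropped -- translations belong to the
    # affine stage and would be unpenalized by bending energy
    tvox <- world_to_vox(tgrid$affine, pts)
    B <- dct_basis_matrix(tvox, tgrid$dim, k)[, -1, drop = FALSE]
    fv <- as.vector(f$data)
    fill <- min(m$data)
    Apts <- sweep(pts %*% t(A[1:3, 1:3]), 2, A[1:3, 4], `+`)
    overlap_check <- sample_moving(m, Apts, fill)
    if (mean(overlap_check$inside) < 0.05)
      stop("volumes do not overlap after affine initialization")
    cost_at <- function(cv) {
      disp <- matrix(B %*% matrix(cv, ncol = 3), ncol = 3)
      sm <- sample_moving(m, Apts + disp, fill)
      mean((sm$values - fv)^2) + config$lambda * sum(W * cv^2)
    }
    init_cost <- cost_at(numeric(length(cvec)))
    cur <- cost_at(cvec)
    if (cur > init_cost) { cvec <- numeric(length(cvec)); cur <- init_cost }
    mu <- 1e-3
    for (it in seq_len(config$max_iter)) {
      disp <- matrix(B %*% matrix(cvec, ncol = 3), ncol = 3)
      sm <- sample_moving(m, Apts + disp, fill)
      r <- sm$values - fv
      w <- as.numeric(sm$inside)
      g <- world_gradient_at(m, sm$vox, sm$inside)
      J <- cbind(B * (g[, 1] * w), B * (g[, 2] * w), B * (g[, 3] * w))
      n <- length(r)
      rhs <- -(crossprod(J, r * w) / n + config$lambda * W * cvec)
      JtJ <- crossprod(J) / n
      reg <- config$lambda * diag(W, length(W))
      improved <- FALSE; conv <- FALSE
      for (try in 1:6) {
        delta <- tryCatch(
          solve(JtJ + reg + mu * diag(diag(JtJ) + 1e-10), rhs),
          error = function(e) NULL)
        if (is.null(delta)) { mu <- mu * 10; next }
        new_cost <- cost_at(cvec + as.vector(delta))
        if (new_cost < cur) {
          cvec <- cvec + as.vector(delta); mu <- mu / 3
          improved <- TRUE
          conv <- (cur - new_cost) / max(cur, 1e-12) < config$tol
          cur <- new_cost
          break
        }
        mu <- mu * 10
      }
      total_iter <- total_iter + 1L
      if (!improved || conv) break
    }
    final_cost <- cur
  }
  cf_flat <- matrix(0, nb, 3)
  cf_flat[-1, ] <- matrix(cvec, ncol = 3)
  cf <- array(cf_flat, dim = c(k, 3))
  field <- dct_field(cf, tgrid, regularization_weight = config$lambda)
  warp <- structure(list(affine = affine_transform(A), field = field),
                    class = c("ct_warp", "ct_transform"))
  registration_result(warp, final_cost, init_cost, total_iter,
                      converged = final_cost <= init_cost)
}

#' @export
transform_points.ct_warp <- function(t, pts) {
  pts <- rbind_pts(pts)
  transform_points(t$affine, pts) + dct_displacement_at(t$field, pts)
}

#' @export
transform_points.ct_warp_inv <- function(t, pts) {
  # solve A y + d(y) = x by fixed point on y' = A^{-1}(x - d(y))
  pts <- rbind_pts(pts)
  Ainv <- invert_transform(t$warp$affine)
  y <- transform_points(Ainv, pts)
  for (i in seq_len(t$max_iter)) {
    dy <- dct_displacement_at(t$warp$field, y)
    y_new <- transform_points(Ainv, pts - dy)
    step <- sqrt(rowSums((y_new - y)^2))
    y <- y_new
    if (mean(step) < t$tol) break
  }
  attr(y, "converged") <- mean(step) < t$tol
  y
}
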