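#' Shift a CT volume to non-negative intensities
#'
#' If the minimum voxel value is negative, every voxel is shifted by its
#' absolute value so the new minimum is exactly zero; already non-negative
#' volumes pass through unchanged (so Hounsfield semantics are kept when no
#' air is present).  The applied shift is recorded in the output metadata.
#'
#' @param ct a `ct_volume` in Hounsfield units.
#' @return Shifted `ct_volume` with `meta$offset_shift` set.
#' @export
offset_to_nonnegative <- function(ct) {
  if (any(!is.finite(ct$data))) stop("CT volume contains non-finite voxels")
  mn <- min(ct$data)
  shift <- if (mn < 0) -mn else 0
  out <- ct
  if (shift > 0) out$data <- ct$data + shift
  out$meta$offset_shift <- shift
  out
}

#' Parameters of the piecewise CT intensity transformation
#'
#' The itCT map compresses the skull-brain contrast of a Hounsfield-unit CT:
#' values at or below `low_break` are offset by `low_offset`, values above
#' `high_break` by `high_offset`, and the soft-tissue window in between is
#' linearly rescaled onto `mid_range`.  The defaults make the map continuous
#' and globally non-decreasing.
#'
#' @param low_break,high_break window breakpoints in HU.
#' @param low_offset,high_offset additive offsets of the outer segments.
#' @param mid_range increasing length-2 target range of the middle segment.
#' @return Validated parameter list of class `itct_params`.
#' @export
itct_params <- function(low_break = -100, high_break = 100,
                        low_offset = 1000, high_offset = 3000,
                        mid_range = c(900, 3100)) {
  stopifnot(low_break < high_break, mid_range[1] < mid_range[2])
  p <- list(low_break = low_break, high_break = high_break,
            low_offset = low_offset, high_offset = high_offset,
            mid_range = mid_range)
  # continuity at both breakpoints and global monotonicity
  if (abs((low_break + low_offset) - mid_range[1]) > 1e-9)
    stop("itCT map discontinuous at the lower breakpoint")
  if (abs((high_break + high_offset) - mid_range[2]) > 1e-9)
    stop("itCT map discontinuous at the upper breakpoint")
  class(p) <- "itct_params"
  p
}

#' Piecewise CT intensity transformation (itCT)
#'
#' Elementwise map: `v <= -100 -> v + 1000`; `-100 < v <= 100 ->
#' 900 + (v + 100) * (3100 - 900) / 200`; `v > 100 -> v + 3000` (at the
#' default parameters).  Shape, grid and intensity rank order are preserved.
#'
#' @param ct a `ct_volume` in HU (also accepts a bare numeric vector/array
#'   for scalar evaluation).
#' @param params an [itct_params()] list.
#' @return Transformed `ct_volume` (or numeric, matching the input).
#' @export
intensity_transform <- function(ct, params = itct_params()) {
  f <- function(v) {
    lo <- v <= params$low_break
    hi <- v > params$high_break
    mid <- !lo & !hi
    out <- v
    out[lo] <- v[lo] + params$low_offset
    out[hi] <- v[hi] + params$high_offset
    out[mid] <- params$mid_range[1] +
      (v[mid] - params$low_break) *
      diff(params$mid_range) / (params$high_break - params$low_break)
    out
  }
  if (is_volume(ct)) {
    out <- ct
    out$data <- f(ct$data)
    out$unit <- "arbitrary"
    out
  } else f(ct)
}

#' Scalp-stripping
#'
#' Masks a head CT to the scalp-stripping mask (skull, brain, CSF and soft
#' tissue below the skull convexity); voxels outside the mask are set to the
#' fill value.
#'
#' @param ct a `ct_volume`.
#' @param scalp_mask probability or label `ct_volume` on the same grid;
#'   voxels with mask > 0.5 are kept.
#' @param fill value outside the mask (default: volume minimum, keeping air
#'   darkest).
#' @return Masked `ct_volume`.
#' @export
strip_scalp <- function(ct, scalp_mask, fill = NULL) {
  if (!same_grid(vol_grid(ct), vol_grid(scalp_mask)))
    stop("scalp mask must be on the CT grid; resample it first")
  keep <- scalp_mask$data > 0.5
  if (!any(keep)) stop("empty scalp-stripping mask")
  if (is.null(fill)) fill <- min(ct$data)
  out <- ct
  out$data[!keep] <- fill
  out$meta$scalp_stripped <- TRUE
  out
}

#' Build the template scalp-stripping mask from tissue priors
#'
#' Union of the skull/brain/CSF probabilistic maps thresholded at
#' `threshold`, then morphologically closed with a ball of radius
#' `close_radius` voxels to bridge the CSF gaps.
#'
#' @param priors a `tissue_maps` list (see [tissue_maps()]).
#' @param threshold prior threshold for inclusion.
#' @param close_radius closing radius in voxels.
#' @return Binary label `ct_volume`.
#' @export
build_scalp_mask <- function(priors, threshold = 0.05, close_radius = 2L) {
  u <- (priors$skull$data >= threshold) | (priors$brain$data >= threshold) |
    (priors$csf$data >= threshold)
  m <- morph_ball(morph_ball(u, close_radius, dilate = TRUE),
                  close_radius, dilate = FALSE)
  new_volume(array(as.integer(m), dim(u)), priors$skull$affine, "label")
}

# Binary dilation/erosion with a discrete ball, via axis shifts.
morph_ball <- function(mask, radius, dilate = TRUE) {
  if (radius < 1L) return(mask)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                      dz = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  d <- dim(mask)
  acc <- if (dilate) array(FALSE, d) else array(TRUE, d)
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(mask, c(offs$dx[r], offs$dy[r], offs$dz[r]),
                      fill = !dilate)
    acc <- if (dilate) acc | sh else acc & sh
  }
  acc
}

shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Probabilistic tissue maps
#' @param skull,brain,csf probability `ct_volume`s on one grid.
#' @return A `tissue_maps` list.
#' @export
tissue_maps <- function(skull, brain, csf) {
  stopifnot(same_grid(vol_grid(skull), vol_grid(brain)),
            same_grid(vol_grid(skull), vol_grid(csf)))
  for (v in list(skull, brain, csf))
    if (min(v$data) < -1e-9 || max(v$data) > 1 + 1e-9)
      stop("tissue priors must lie in [0, 1]")
  structure(list(skull = skull, brain = brain, csf = csf),
            class = "tissue_maps")
}

#' Probabilistic-atlas tissue segmentation
#'
#' Per-voxel maximum a posteriori assignment into background / skull / brain
#' / CSF: class posteriors are `prior * Gaussian(intensity; mu, sigma)` with
#' per-class `(mu, sigma)` re-estimated by a short EM loop initialized from
#' prior-weighted moments.  Voxels whose priors are all below `eps` become
#' background; posterior ties break by the fixed priority skull > brain >
#' CSF.
#'
#' @param ct_normalized `ct_volume` already in the priors' space.
#' @param priors a [tissue_maps()] object.
#' @param n_iter EM iterations.
#' @param eps prior floor under which a voxel is background.
#' @return Label `ct_volume` with codes 0 = background, 1 = skull,
#'   2 = brain, 3 = CSF (matching [phantom_codes()]).
#' @export
segment_tissues <- function(ct_normalized, priors, n_iter = 3L, eps = 1e-3) {
  if (!same_grid(vol_grid(ct_normalized), vol_grid(priors$skull)))
    stop("CT must be resampled into the priors' space first")
  v <- as.vector(ct_normalized$data)
  pri <- cbind(skull = as.vector(priors$skull$data),
               brain = as.vector(priors$brain$data),
               csf = as.vector(priors$csf$data))
  for (cl in colnames(pri))
    if (sum(pri[, cl]) <= 0) stop(sprintf("tissue prior '%s' has zero mass", cl))
  active <- rowSums(pri >= eps) > 0
  mu <- sig <- numeric(3)
  for (c in 1:3) {
    w <- pri[active, c]
    mu[c] <- sum(w * v[active]) / sum(w)
    sig[c] <- sqrt(sum(w * (v[active] - mu[c])^2) / sum(w))
  }
  sig <- pmax(sig, 1e-3)
  post <- NULL
  for (it in seq_len(n_iter)) {
    lik <- vapply(1:3, function(c)
      stats::dnorm(v[active], mu[c], sig[c]), numeric(sum(active)))
    post <- pri[active, ] * lik
    tot <- rowSums(post)
    tot[tot <= 0] <- 1
    post <- post / tot
    for (c in 1:3) {
      w <- post[, c]
      if (sum(w) <= 0) next
      mu[c] <- sum(w * v[active]) / sum(w)
      sig[c] <- max(sqrt(sum(w * (v[active] - mu[c])^2) / sum(w)), 1e-3)
    }
  }
  lab <- integer(length(v))  # background = 0
  # argmax with tie priority skull > brain > csf == first max in column order
  cls <- max.col(post, ties.method = "first")
  codes <- c(phantom_codes()[["skull"]], phantom_codes()[["brain"]],
             phantom_codes()[["csf"]])
  lab[active] <- codes[cls]
  new_volume(array(lab, dim(ct_normalized$data)), ct_normalized$affine, "label")
}

#' Skull-stripping
#'
#' Masks a CT to its whole-brain segment, producing the ssCT image.
#'
#' @param ct a `ct_volume`.
#' @param brain_label binary or label `ct_volume` on the CT grid; voxels
#'   with value equal to `brain_code` (or any positive value when
#'   `brain_code = NULL`) are kept.
#' @param brain_code label code of the brain segment (default: the phantom
#'   brain code from a [segment_tissues()] output).
#' @param fill fill value outside the brain (default: volume minimum).
#' @return The ssCT `ct_volume`.
#' @export
skull_strip <- function(ct, brain_label, brain_code = phantom_codes()[["brain"]],
                        fill = NULL) {
  if (!same_grid(vol_grid(ct), vol_grid(brain_label)))
    stop("brain label must be on the CT grid")
  keep <- if (is.null(brain_code)) brain_label$data > 0
    else brain_label$data == brain_code
  if (!any(keep)) stop("empty brain segment")
  if (is.null(fill)) fill <- min(ct$data)
  out <- ct
  out$data[!keep] <- fill
  out$meta$skull_stripped <- TRUE
  out
}

#' Full ssCT preparation for one subject
#'
#' The skull-stripping route: offset the CT to non-negative values, affinely
#' normalize it to the whole-CT template, bring the scalp mask and the tissue
#' priors back to native space through the inverse transform, scalp-strip,
#' segment (MAP + EM) and mask the original CT to the brain segment.
#'
#' @param ct native `ct_volume` in HU.
#' @param templates a `template_set` (see [build_template_set()]) providing
#'   `whole_ct`, `priors` and `scalp_mask`.
#' @param config registration configuration (see [register_config()]).
#' @return List with `ssct` (native-space skull-stripped CT), `segmentation`
#'   and `to_template` (the affine used).
#' @export
make_ssct <- function(ct, templates, config = register_config()) {
  ct0 <- offset_to_nonnegative(ct)
  reg <- affine_register(ct0, templates$whole_ct, config = config)
  inv <- invert_transform(reg$transform)  # native-world -> template-world
  grid <- vol_grid(ct)
  mask_n <- apply_transform(templates$scalp_mask, inv, grid,
                            interpolation = "nearest", fill = 0)
  stripped <- strip_scalp(ct0, mask_n)
  pri_n <- tissue_maps(
    apply_transform(templates$priors$skull, inv, grid, fill = 0),
    apply_transform(templates$priors$brain, inv, grid, fill = 0),
    apply_transform(templates$priors$csf, inv, grid, fill = 0))
  pri_n <- tissue_maps(clamp01(pri_n$skull), clamp01(pri_n$brain),
                       clamp01(pri_n$csf))
  seg <- segment_tissues(stripped, pri_n)
  list(ssct = skull_strip(ct, seg), segmentation = seg,
       to_template = reg$transform)
}

clamp01 <- function(vol) {
  vol$data <- pmin(pmax(vol$data, 0), 1)
  vol$unit <- "probability"
  vol
}
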