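#' Average normalized volumes into an intensity template
#'
#' @param normalized_volumes list of at least two `ct_volume`s on one grid.
#' @return Voxelwise-mean `ct_volume`.
#' @export
build_intensity_template <- function(normalized_volumes) {
  stopifnot(length(normalized_volumes) >= 2L)
  g <- vol_grid(normalized_volumes[[1]])
  acc <- array(0, g$dim)
  for (v in normalized_volumes) {
    if (!same_grid(vol_grid(v), g)) stop("grid mismatch between volumes")
    acc <- acc + v$data
  }
  new_volume(acc / length(normalized_volumes), g$affine,
             normalized_volumes[[1]]$unit)
}

#' Average binary masks into a probabilistic map
#'
#' @param binary_masks list of binary (0/1) `ct_volume`s on one grid.
#' @return Probability `ct_volume` (voxelwise mean, in `[0, 1]`).
#' @export
build_probabilistic_map <- function(binary_masks) {
  stopifnot(length(binary_masks) >= 1L)
  g <- vol_grid(binary_masks[[1]])
  acc <- array(0, g$dim)
  for (v in binary_masks) {
    if (!same_grid(vol_grid(v), g)) stop("grid mismatch between masks")
    if (!all(v$data %in% c(0, 1))) stop("masks must be binary")
    acc <- acc + v$data
  }
  new_volume(acc / length(binary_masks), g$affine, "probability")
}

#' VOI template from regional probabilistic maps
#'
#' A voxel belongs to a region iff its probability is at or above
#' `threshold` (inclusive boundary); where several regions pass, the highest
#' probability wins, ties breaking by the order of `region_prob_maps`.
#'
#' @param region_prob_maps named list of probability `ct_volume`s on one
#'   grid (e.g. `caudate_l`, `caudate_r`, `putamen_l`, `putamen_r`,
#'   `cerebellum`).
#' @param threshold inclusion threshold (default 0.8).
#' @param target_grid optional `ct_grid` to resample the labels onto
#'   (nearest-neighbour); default keeps the maps' grid.
#' @return A `voi_template`: list with `labels` (label `ct_volume`),
#'   `regions` (named integer codes) and `threshold`.
#' @export
build_voi_template <- function(region_prob_maps, threshold = 0.8,
                               target_grid = NULL) {
  stopifnot(length(region_prob_maps) >= 1L, !is.null(names(region_prob_maps)))
  g <- vol_grid(region_prob_maps[[1]])
  nr <- length(region_prob_maps)
  probs <- vapply(region_prob_maps, function(v) {
    if (!same_grid(vol_grid(v), g)) stop("grid mismatch between region maps")
    as.vector(v$data)
  }, numeric(prod(g$dim)))
  pass <- probs >= threshold
  lab <- integer(nrow(probs))
  any_pass <- rowSums(pass) > 0
  if (any(any_pass)) {
    masked <- probs
    masked[!pass] <- -Inf
    lab[any_pass] <- max.col(masked[any_pass, , drop = FALSE],
                             ties.method = "first")
  }
  for (i in seq_len(nr)) {
    if (!any(lab == i))
      stop(sprintf("region '%s' has no voxel at or above threshold %g",
                   names(region_prob_maps)[i], threshold))
  }
  labels <- new_volume(array(lab, g$dim), g$affine, "label")
  if (!is.null(target_grid) && !same_grid(g, target_grid))
    labels <- apply_transform(labels, identity_transform(), target_grid,
                              interpolation = "nearest", fill = 0)
  structure(list(labels = labels,
                 regions = stats::setNames(seq_len(nr), names(region_prob_maps)),
                 threshold = threshold),
            class = "voi_template")
}

#' Wrap an existing label volume as a VOI template
#' @param labels label `ct_volume`.
#' @param regions named integer vector mapping region names to codes.
#' @return A `voi_template`.
#' @export
voi_from_labels <- function(labels, regions) {
  structure(list(labels = labels, regions = regions, threshold = NA_real_),
            class = "voi_template")
}

region_mask <- function(voi, region) {
  code <- voi$regions[[region]]
  if (is.null(code)) stop(sprintf("unknown region '%s'", region))
  voi$labels$data == code
}

#' Subregional parcellation of the striatal VOI
#'
#' Simplified geometric scheme: the ventral striatum is carved from the
#' caudate plus putamen below the axial plane one voxel under their combined
#' centroid; the remainder of each nucleus is split at the coronal plane
#' through that nucleus' centroid into anterior and posterior halves.  The
#' subregions partition the parent labels exactly.
#'
#' @param voi a `voi_template` containing `caudate_l/r` and `putamen_l/r`.
#' @return A new `voi_template` with per-side subregion labels
#'   (`caudate_ant_*`, `caudate_post_*`, `putamen_ant_*`, `putamen_post_*`,
#'   `ventral_striatum_*`) plus any other regions carried over.
#' @export
parcellate_striatum <- function(voi) {
  g <- vol_grid(voi$labels)
  pts <- grid_world_coords(g)
  lab <- as.vector(voi$labels$data)
  out <- integer(length(lab))
  new_regions <- integer(0)
  next_code <- 1L
  add_region <- function(name, mask) {
    out[mask] <<- next_code
    new_regions[[name]] <<- next_code
    next_code <<- next_code + 1L
  }
  for (side in c("l", "r")) {
    cd <- lab == voi$regions[[paste0("caudate_", side)]]
    pt <- lab == voi$regions[[paste0("putamen_", side)]]
    if (!any(cd) || !any(pt))
      stop("caudate and putamen labels must be nonempty on both sides")
    for (m in list(cd, pt))
      if (length(unique(pts[m, 3])) < 2L)
        stop("degenerate single-slice nucleus; cannot parcellate")
    zc <- mean(pts[cd | pt, 3])
    vz <- voxel_size(voi$labels)[3]
    ventral <- (cd | pt) & pts[, 3] < zc - vz
    for (nucleus in c("caudate", "putamen")) {
      m <- if (nucleus == "caudate") cd else pt
      yc <- mean(pts[m, 2])
      add_region(paste0(nucleus, "_ant_", side), m & !ventral & pts[, 2] >= yc)
      add_region(paste0(nucleus, "_post_", side), m & !ventral & pts[, 2] < yc)
    }
    add_region(paste0("ventral_striatum_", side), ventral)
  }
  for (rn in names(voi$regions)) {
    m <- lab == voi$regions[[rn]] & out == 0L
    if (any(m)) add_region(rn, m)
  }
  structure(list(labels = new_volume(array(out, g$dim), g$affine, "label"),
                 regions = new_regions, threshold = voi$threshold),
            class = "voi_template")
}

#' Build the full template set from a control cohort
#'
#' Constructs every template the four normalization routes need -- whole-CT,
#' itCT, ssCT, MR and ligand-specific PET intensity templates, probabilistic
#' skull/brain/CSF maps, the scalp-stripping mask, and the thresholded
#' striatal/cerebellar VOI template -- by normalizing the control subjects
#' with their gold-standard normalization parameters and averaging, the same
#' construction order used when templates are bootstrapped from a reference
#' normalization.
#'
#' @param hc_subjects list of healthy-control `subject_record`s (phantom
#'   truth present).
#' @param grid target `ct_grid` of the template space (default: the grid of
#'   the first subject, i.e. the canonical phantom grid).
#' @param voi_threshold probability threshold of the VOI template.
#' @return A `template_set` list: `whole_ct`, `itct`, `ssct`, `mr`, `pet`,
#'   `priors` ([tissue_maps()]), `scalp_mask`, `voi`, `voi_sub`.
#' @export
build_template_set <- function(hc_subjects, grid = NULL, voi_threshold = 0.8) {
  stopifnot(length(hc_subjects) >= 2L)
  if (is.null(grid)) grid <- vol_grid(hc_subjects[[1]]$ct)
  codes <- phantom_codes()
  norm_vol <- function(s, vol, nn = FALSE)
    apply_transform(vol, s$truth$to_subject, grid,
                    interpolation = if (nn) "nearest" else "trilinear",
                    fill = if (nn) 0 else min(vol$data))
  bin_mask <- function(labvol, code_set) {
    new_volume(array(as.integer(labvol$data %in% code_set), grid$dim),
               grid$affine, "label")
  }
  n_ct <- lapply(hc_subjects, function(s)
    norm_vol(s, offset_to_nonnegative(s$ct)))
  n_lab <- lapply(hc_subjects, function(s) norm_vol(s, s$truth$labels, nn = TRUE))
  n_pet <- lapply(hc_subjects, function(s) norm_vol(s, s$pet))
  n_mr <- lapply(hc_subjects, function(s) norm_vol(s, s$mr))
  n_itct <- lapply(hc_subjects, function(s)
    norm_vol(s, intensity_transform(s$ct)))

  brain_codes <- c(codes[["brain"]], codes[["caudate_l"]], codes[["caudate_r"]],
                   codes[["putamen_l"]], codes[["putamen_r"]],
                   codes[["cerebellum"]])
  priors <- tissue_maps(
    build_probabilistic_map(lapply(n_lab, bin_mask, codes[["skull"]])),
    build_probabilistic_map(lapply(n_lab, bin_mask, brain_codes)),
    build_probabilistic_map(lapply(n_lab, bin_mask, codes[["csf"]])))
  scalp_mask <- build_scalp_mask(priors)

  n_ssct <- lapply(seq_along(hc_subjects), function(i) {
    brain <- bin_mask(n_lab[[i]], brain_codes)
    skull_strip(n_ct[[i]], brain, brain_code = NULL)
  })

  region_maps <- lapply(
    stats::setNames(nm = c("caudate_l", "caudate_r", "putamen_l", "putamen_r",
                           "cerebellum")),
    function(rn) build_probabilistic_map(lapply(n_lab, bin_mask, codes[[rn]])))
  voi <- build_voi_template(region_maps, threshold = voi_threshold)

  structure(list(
    whole_ct = build_intensity_template(n_ct),
    itct = build_intensity_template(n_itct),
    ssct = build_intensity_template(n_ssct),
    mr = build_intensity_template(n_mr),
    pet = build_intensity_template(n_pet),
    priors = priors, scalp_mask = scalp_mask,
    voi = voi, voi_sub = parcellate_striatum(voi),
    grid = grid), class = "template_set")
}
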