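#' Phantom configuration
#'
#' Defaults define the study conditions the cohort emulates: a
#' dopamine-transporter PET cohort of healthy controls (HC) and Parkinson's
#' disease (PD) patients scanned on a PET/CT system.  Striatal uptake moments
#' are subject-level means/SDs of the generative (pre-smoothing) uptake;
#' PD putamina additionally carry an anterior-to-posterior uptake gradient
#' (posterior-putaminal deficit) and a multiplicative left-right asymmetry
#' tied to the clinically worse side.
#'
#' @param grid_n voxels per axis of the (isotropic, world-centered) lattice.
#' @param spacing voxel size in mm.  The default 64^3 at 3 mm is a desk-scale
#'   stand-in for scanner-resolution matrices; finer grids are configuration
#'   only.
#' @param hc_caudate,hc_putamen,pd_caudate,pd_putamen `c(mean, sd)` of the
#'   subject-level regional uptake draw for each group.
#' @param putamen_gradient amplitude g of the PD anterior-posterior gradient:
#'   uptake runs from `level + g` (anterior pole) to `level - g` (posterior
#'   pole).  Over the posterior half of a solid ellipsoid the mean of a
#'   linear profile is `level - 3g/8`, so the default 3.2 calibrates the
#'   population posterior-putamen mean to 3.4 for a whole-putamen level of
#'   4.6 (a step profile uses `level - g/2`, g = 2.4 equivalently).
#' @param gradient_shape `"linear"` or `"step"` profile of the deficit.
#' @param asymmetry total worse/better multiplicative split of striatal
#'   uptake in PD (worse-side striatum x (1 - a/2), better x (1 + a/2)).
#' @param psf_fwhm PET point-spread function, Gaussian FWHM in mm.
#' @param pet_noise_sd,ct_noise_sd,mr_noise_sd additive Gaussian noise SDs
#'   (SUV-like units / HU / arbitrary MR units).
#' @param max_rotation,max_translation,max_scale ranges of the random
#'   per-subject affine (degrees, mm, fractional scale).
#' @param warp_sd,warp_k SD (mm) of the random cosine-basis coefficients of
#'   the smooth inter-subject warp and basis size per axis.
#' @param severity_intercept,severity_slope,severity_noise_sd the synthetic
#'   UPDRS-like severity model `severity = intercept - slope * putaminal
#'   uptake + N(0, sd)`, floored at zero; defaults give PD severity of about
#'   28 +/- 8.
#' @param prob_worse_left probability that the clinically worse side is the
#'   left (34/56 in the emulated cohort).
#' @param identity_transform if `TRUE` the subject anatomy equals the
#'   canonical anatomy (no affine, no warp); used for interpolation-tolerance
#'   checks.
#' @return Named list of parameters.
#' @export
phantom_params <- function(grid_n = 64L, spacing = 3,
                           hc_caudate = c(7.2, 1.4), hc_putamen = c(8.9, 1.3),
                           pd_caudate = c(5.2, 1.5), pd_putamen = c(4.6, 1.1),
                           putamen_gradient = 3.2,
                           gradient_shape = c("linear", "step"),
                           asymmetry = 0.15,
                           psf_fwhm = 6, pet_noise_sd = 0.05,
                           ct_noise_sd = 5, mr_noise_sd = 3,
                           max_rotation = 6, max_translation = 5,
                           max_scale = 0.05,
                           warp_sd = 0.8, warp_k = 3L,
                           severity_intercept = 51, severity_slope = 5,
                           severity_noise_sd = 5.9,
                           prob_worse_left = 34 / 56,
                           identity_transform = FALSE) {
  stopifnot(grid_n >= 32L, hc_putamen > 0, pd_putamen[1] > 0,
            pd_putamen[2] >= 0, hc_caudate > 0, pd_caudate[1] > 0,
            pd_caudate[2] >= 0)
  list(grid_n = as.integer(grid_n), spacing = spacing,
       hc_caudate = hc_caudate, hc_putamen = hc_putamen,
       pd_caudate = pd_caudate, pd_putamen = pd_putamen,
       putamen_gradient = putamen_gradient,
       gradient_shape = match.arg(gradient_shape),
       asymmetry = asymmetry, psf_fwhm = psf_fwhm,
       pet_noise_sd = pet_noise_sd, ct_noise_sd = ct_noise_sd,
       mr_noise_sd = mr_noise_sd, max_rotation = max_rotation,
       max_translation = max_translation, max_scale = max_scale,
       warp_sd = warp_sd, warp_k = as.integer(warp_k),
       severity_intercept = severity_intercept,
       severity_slope = severity_slope,
       severity_noise_sd = severity_noise_sd,
       prob_worse_left = prob_worse_left,
       identity_transform = identity_transform)
}

#' Phantom label codes
#'
#' Integer codes of the canonical head anatomy: nested ellipsoids for scalp,
#' skull, CSF shell and brain parenchyma; paired ellipsoids for caudate and
#' putamen; a posterior-inferior ellipsoid for the cerebellum.
#' @return Named integer vector.
#' @export
phantom_codes <- function() {
  c(air = 0L, skull = 1L, brain = 2L, csf = 3L,
    caudate_l = 4L, caudate_r = 5L, putamen_l = 6L, putamen_r = 7L,
    cerebellum = 8L, scalp = 9L)
}

# Analytic canonical anatomy: semi-axes and centers in canonical world mm.
phantom_geometry <- function() {
  list(
    head  = list(c = c(0, 0, 0),    s = c(75, 90, 70)),
    skull = list(c = c(0, 0, 0),    s = c(70, 84, 64)),
    inner = list(c = c(0, 0, 0),    s = c(63, 77, 57)),   # inside = CSF shell
    brain = list(c = c(0, 0, 0),    s = c(59, 73, 53)),
    vent_l = list(c = c(-9, 5, 15), s = c(5, 16, 8)),
    vent_r = list(c = c(9, 5, 15),  s = c(5, 16, 8)),
    caudate_l = list(c = c(-14, 18, 10), s = c(8, 14, 10)),
    caudate_r = list(c = c(14, 18, 10),  s = c(8, 14, 10)),
    putamen_l = list(c = c(-26, 0, 2),   s = c(10, 20, 9)),
    putamen_r = list(c = c(26, 0, 2),    s = c(10, 20, 9)),
    cerebellum = list(c = c(0, -40, -28), s = c(30, 20, 16))
  )
}

in_ellipsoid <- function(pts, e) {
  rowSums(sweep(sweep(pts, 2, e$c), 2, e$s, `/`)^2) <= 1
}

# Label every canonical-space point (n x 3 world mm).
phantom_label_points <- function(pts) {
  g <- phantom_geometry()
  code <- phantom_codes()
  lab <- rep(code[["air"]], nrow(pts))
  lab[in_ellipsoid(pts, g$head)]  <- code[["scalp"]]
  lab[in_ellipsoid(pts, g$skull)] <- code[["skull"]]
  lab[in_ellipsoid(pts, g$inner)] <- code[["csf"]]
  lab[in_ellipsoid(pts, g$brain)] <- code[["brain"]]
  lab[in_ellipsoid(pts, g$vent_l) | in_ellipsoid(pts, g$vent_r)] <- code[["csf"]]
  for (r in c("caudate_l", "caudate_r", "putamen_l", "putamen_r", "cerebellum"))
    lab[in_ellipsoid(pts, g[[r]])] <- code[[r]]
  lab
}

#' Canonical anatomy on a grid
#' @param params phantom configuration from [phantom_params()].
#' @return Label `ct_volume` of the canonical head on the canonical grid.
#' @export
canonical_labels <- function(params = phantom_params()) {
  grid <- iso_grid(params$grid_n, params$spacing)
  lab <- phantom_label_points(grid_world_coords(grid))
  new_volume(array(as.integer(lab), grid$dim), grid$affine, "label")
}

# CT Hounsfield strata by label code (air, CSF, brain/soft tissue, skull).
ct_stratum <- function(lab) {
  hu <- c("0" = -1000, "1" = 1000, "2" = 30, "3" = 10, "4" = 35, "5" = 35,
          "6" = 35, "7" = 35, "8" = 30, "9" = 40)
  unname(hu[as.character(lab)])
}

mr_stratum <- function(lab) {
  v <- c("0" = 0, "1" = 10, "2" = 100, "3" = 20, "4" = 110, "5" = 110,
         "6" = 110, "7" = 110, "8" = 100, "9" = 30)
  unname(v[as.character(lab)])
}

# Random subject-to-canonical map: affine (rotation/translation/scale) then a
# smooth cosine-basis warp in canonical space.
random_subject_transform <- function(params, grid) {
  deg <- pi / 180
  rot <- stats::runif(3, -params$max_rotation, params$max_rotation) * deg
  tra <- stats::runif(3, -params$max_translation, params$max_translation)
  sca <- exp(stats::runif(3, log(1 - params$max_scale), log(1 + params$max_scale)))
  A <- affine_from_params(c(tra, rot, log(sca), 0, 0, 0))
  k <- params$warp_k
  cf <- array(stats::rnorm(k^3 * 3, sd = params$warp_sd), dim = c(k, k, k, 3))
  cf[1, 1, 1, ] <- 0  # constant term would duplicate the translation
  compose_transforms(dct_field(cf, grid), affine_transform(A, dof = 12L))
}

#' Generate one synthetic subject
#'
#' Builds CT (HU strata plus noise), PET (unit nonspecific background,
#' cerebellar reference at 1.0, group-specific striatal uptake, Gaussian PSF,
#' noise) and an MR-like volume for one subject whose anatomy is the
#' canonical head carried through a random affine plus smooth warp.  The
#' ground truth (labels, transforms, generative uptake, severity) is stored
#' alongside.
#'
#' @param params configuration from [phantom_params()].
#' @param group `"HC"` or `"PD"`.
#' @param seed integer seed; identical `(params, group, seed)` give
#'   bit-identical subjects.
#' @param id subject identifier string.
#' @return A `subject_record` list: `id`, `group`, `worse_side`, `severity`,
#'   volumes `ct`/`pet`/`mr`, and `truth` (label volume, `to_template` /
#'   `to_subject` transforms, `true_uptake`, pre-PSF pet).
#' @export
generate_subject <- function(params = phantom_params(),
                             group = c("HC", "PD"), seed = 1L,
                             id = sprintf("%s%03d", group[1], seed %% 1000L)) {
  group <- match.arg(group)
  if (any(c(params$hc_putamen[2], params$pd_putamen[2],
            params$hc_caudate[2], params$pd_caudate[2]) < 0))
    stop("uptake SD must be non-negative")
  set.seed(as.integer(seed %% .Machine$integer.max))
  grid <- iso_grid(params$grid_n, params$spacing)

  # per-subject uptake draws
  if (group == "HC") {
    caud <- stats::rnorm(1, params$hc_caudate[1], params$hc_caudate[2])
    puta <- stats::rnorm(1, params$hc_putamen[1], params$hc_putamen[2])
    worse_side <- "none"
    grad <- 0
  } else {
    caud <- stats::rnorm(1, params$pd_caudate[1], params$pd_caudate[2])
    puta <- stats::rnorm(1, params$pd_putamen[1], params$pd_putamen[2])
    worse_side <- if (stats::runif(1) < params$prob_worse_left) "left" else "right"
    grad <- params$putamen_gradient
  }
  caud <- max(caud, 0.2); puta <- max(puta, 0.2)
  side_factor <- c(left = 1, right = 1)
  if (group == "PD") {
    # affected striatum is contralateral to the clinically worse side
    affected <- if (worse_side == "left") "right" else "left"
    side_factor[affected] <- 1 - params$asymmetry / 2
    side_factor[setdiff(c("left", "right"), affected)] <- 1 + params$asymmetry / 2
  }

  to_template <- if (params$identity_transform) identity_transform()
    else random_subject_transform(params, grid)
  to_subject <- invert_transform(to_template)

  pts_c <- transform_points(to_template, grid_world_coords(grid))
  lab <- phantom_label_points(pts_c)
  codes <- phantom_codes()
  for (r in c("caudate_l", "caudate_r", "putamen_l", "putamen_r", "cerebellum"))
    if (!any(lab == codes[[r]]))
      stop(sprintf("phantom label '%s' is empty; grid too coarse or transform too large", r))

  ct_dat <- ct_stratum(lab) + stats::rnorm(length(lab), 0, params$ct_noise_sd)
  mr_dat <- mr_stratum(lab) + stats::rnorm(length(lab), 0, params$mr_noise_sd)

  # PET uptake field evaluated in canonical coordinates
  pet0 <- numeric(length(lab))
  pet0[lab %in% c(codes[["brain"]], codes[["cerebellum"]])] <- 1
  pet0[lab == codes[["csf"]]] <- 0.3
  g <- phantom_geometry()
  for (side in c("l", "r")) {
    sf <- side_factor[[if (side == "l") "left" else "right"]]
    sel <- lab == codes[[paste0("caudate_", side)]]
    pet0[sel] <- caud * sf
    sel <- lab == codes[[paste0("putamen_", side)]]
    if (any(sel)) {
      e <- g[[paste0("putamen_", side)]]
      rel_y <- (pts_c[sel, 2] - e$c[2]) / e$s[2]  # -1 posterior .. +1 anterior
      prof <- if (params$gradient_shape == "linear") puta + grad * rel_y
        else puta + grad / 2 * sign(rel_y)
      pet0[sel] <- pmax(prof, 0.05) * sf
    }
  }
  pet_pre <- new_volume(array(pet0, grid$dim), grid$affine, "SUV")
  pet <- smooth_gaussian(pet_pre, params$psf_fwhm)
  pet$data <- pet$data + array(stats::rnorm(length(lab), 0, params$pet_noise_sd),
                               grid$dim)

  severity <- 0
  if (group == "PD") {
    severity <- params$severity_intercept - params$severity_slope * puta +
      stats::rnorm(1, 0, params$severity_noise_sd)
    severity <- max(severity, 0)
  }

  true_uptake <- list(
    caudate_l = caud * side_factor[["left"]],
    caudate_r = caud * side_factor[["right"]],
    putamen_l = puta * side_factor[["left"]],
    putamen_r = puta * side_factor[["right"]],
    putamen_anterior = puta +
      grad * (if (params$gradient_shape == "linear") 3 / 8 else 1 / 2),
    putamen_posterior = puta -
      grad * (if (params$gradient_shape == "linear") 3 / 8 else 1 / 2),
    cerebellum = 1)

  truth <- list(
    labels = new_volume(array(as.integer(lab), grid$dim), grid$affine, "label"),
    to_template = to_template, to_subject = to_subject,
    true_uptake = true_uptake, severity = severity, pet_pre_psf = pet_pre)

  structure(list(
    id = id, group = group, worse_side = worse_side, severity = severity,
    ct = new_volume(array(ct_dat, grid$dim), grid$affine, "HU"),
    pet = pet,
    mr = new_volume(array(mr_dat, grid$dim), grid$affine, "arbitrary"),
    truth = truth), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s), worse side %s, severity %.1f\n",
              x$id, x$group, x$worse_side, x$severity))
  invisible(x)
}

#' Generate a seeded cohort
#'
#' Per-subject seeds derive deterministically from the cohort seed.  If
#' `out_dir` is given, CT/PET/MR volumes are written as NIfTI and a manifest
#' CSV (`id,group,worse_side,severity,ct_path,pet_path,mr_path`) is emitted.
#'
#' @param n_hc,n_pd numbers of healthy controls and patients.
#' @param params configuration from [phantom_params()].
#' @param seed cohort seed.
#' @param out_dir optional directory for NIfTI volumes and `manifest.csv`.
#' @return List with `subjects` (list of `subject_record`) and `manifest`
#'   (data.frame).
#' @export
generate_cohort <- function(n_hc, n_pd, params = phantom_params(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(n_hc >= 0, n_pd >= 0)
  groups <- c(rep("HC", n_hc), rep("PD", n_pd))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sseed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483629 + 1
    subjects[[i]] <- generate_subject(params, groups[i], seed = sseed,
                                      id = sprintf("%s%03d", groups[i], i))
  }
  n <- length(subjects)
  manifest <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    group = if (n) groups else character(0),
    worse_side = vapply(subjects, `[[`, "", "worse_side"),
    severity = vapply(subjects, `[[`, 0, "severity"),
    ct_path = rep(NA_character_, n), pet_path = rep(NA_character_, n),
    mr_path = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(subjects)) {
      s <- subjects[[i]]
      for (mod in c("ct", "pet", "mr")) {
        p <- file.path(out_dir, sprintf("%s_%s.nii.gz", s$id, mod))
        write_volume(s[[mod]], p)
        manifest[[paste0(mod, "_path")]][i] <- p
      }
      write_volume(s$truth$labels,
                   file.path(out_dir, sprintf("%s_labels.nii.gz", s$id)))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(subjects = subjects, manifest = manifest)
}
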