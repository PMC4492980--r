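#' Spatially normalize a subject's PET by one of four routes
#'
#' * `ssCT` / `itCT`: prepare the CT (skull-stripping via probabilistic
#'   atlases, or piecewise intensity transformation), register it (affine
#'   plus cosine-basis nonlinear) to the matching CT template, and resample
#'   the PET through the same parameters.
#' * `MR`: register the MR-like volume to the MR template and resample the
#'   PET through it.
#' * `PET`: register the PET directly to the ligand-specific PET template.
#'
#' PET/CT scanner geometry co-aligns PET with CT, so no PET-to-structure
#' rigid coregistration is applied by default; set `coregister_pet = TRUE`
#' to insert an NMI rigid step.
#'
#' @param subject a `subject_record`.
#' @param route `"ssCT"`, `"itCT"`, `"MR"` or `"PET"`.
#' @param templates a `template_set` from [build_template_set()].
#' @param config a [register_config()].
#' @param coregister_pet rigidly coregister PET to the structural volume
#'   before composing (default `FALSE`).
#' @return Normalized PET `ct_volume` on the template grid, with
#'   `meta$route` and `meta$transform` provenance.
#' @export
normalize_pet <- function(subject, route = c("ssCT", "itCT", "MR", "PET"),
                          templates, config = register_config(),
                          coregister_pet = FALSE) {
  route <- match.arg(route)
  struct <- switch(route,
    ssCT = {
      if (is.null(subject$ct)) stop("ssCT route requires a CT volume")
      make_ssct(subject$ct, templates, config)$ssct
    },
    itCT = {
      if (is.null(subject$ct)) stop("itCT route requires a CT volume")
      intensity_transform(offset_to_nonnegative(subject$ct))
    },
    MR = {
      if (is.null(subject$mr)) stop("MR route requires an MR volume")
      subject$mr
    },
    PET = subject$pet)
  tmpl <- switch(route, ssCT = templates$ssct, itCT = templates$itct,
                 MR = templates$mr, PET = templates$pet)
  reg <- nonlinear_register(struct, tmpl, config = config)
  t_total <- reg$transform
  if (coregister_pet && route != "PET") {
    rig <- rigid_register(subject$pet, struct, metric = "nmi", config = config)
    t_total <- compose_transforms(rig$transform, t_total)
  }
  out <- apply_transform(subject$pet, t_total, templates$grid, fill = 0)
  out$meta$route <- route
  out$meta$transform <- t_total
  out
}

resolve_side <- function(side, worse_side) {
  if (!side %in% c("worse", "better")) return(side)
  if (is.null(worse_side) || identical(worse_side, "none"))
    stop("worse/better side requested but the subject has no worse side")
  # the affected striatum is contralateral to the clinically worse side
  affected <- if (worse_side == "left") "right" else "left"
  if (side == "worse") affected else setdiff(c("left", "right"), affected)
}

#' Mean regional uptake (SUV)
#'
#' Arithmetic mean of the PET voxels under a VOI label.  `side = "both"`
#' averages the two unilateral means; `"worse"`/`"better"` resolve to the
#' striatal side contralateral to the subject's clinically worse/better
#' side.
#'
#' @param pet a PET `ct_volume` on the VOI grid.
#' @param voi a `voi_template`.
#' @param region base region name (e.g. `"putamen"`, `"caudate"`,
#'   `"cerebellum"`, or a subregion like `"putamen_post"`).
#' @param side `"left"`, `"right"`, `"both"`, `"worse"` or `"better"`
#'   (ignored for unpaired regions present under their bare name).
#' @param worse_side the subject's clinically worse side, for
#'   `"worse"`/`"better"`.
#' @return Mean uptake (scalar).
#' @export
measure_suv <- function(pet, voi, region,
                        side = c("both", "left", "right", "worse", "better"),
                        worse_side = NULL) {
  side <- match.arg(side)
  if (!same_grid(vol_grid(pet), vol_grid(voi$labels)))
    stop("PET must be on the VOI template grid")
  if (region %in% names(voi$regions)) {  # unpaired region
    m <- region_mask(voi, region)
    if (!any(m)) stop(sprintf("region '%s' is empty", region))
    return(mean(pet$data[m]))
  }
  one_side <- function(sd) {
    nm <- paste0(region, "_", substr(sd, 1, 1))
    if (!nm %in% names(voi$regions)) stop(sprintf("unknown region '%s'", nm))
    m <- region_mask(voi, nm)
    if (!any(m)) stop(sprintf("region '%s' is empty", nm))
    mean(pet$data[m])
  }
  if (side == "both") return((one_side("left") + one_side("right")) / 2)
  one_side(resolve_side(side, worse_side))
}

#' Target-to-cerebellar uptake ratio
#' @param suv_target,suv_cerebellum mean regional uptakes.
#' @return `suv_target / suv_cerebellum`.
#' @export
compute_suvr <- function(suv_target, suv_cerebellum) {
  if (any(suv_cerebellum <= 0)) stop("cerebellar SUV must be positive")
  suv_target / suv_cerebellum
}

#' Percent bias of a method SUVR against the ground-truth SUVR
#' @param suvr_method,suvr_truth SUVR values.
#' @return `100 * (suvr_method - suvr_truth) / suvr_truth`.
#' @export
compute_bias <- function(suvr_method, suvr_truth) {
  if (any(suvr_truth <= 0)) stop("truth SUVR must be positive")
  100 * (suvr_method - suvr_truth) / suvr_truth
}

suvr_rows_for_pet <- function(pet, voi, voi_sub, regions, subject, method) {
  cereb <- measure_suv(pet, voi, "cerebellum")
  whole <- c("caudate", "putamen", "cerebellum")
  rows <- list()
  for (region in regions) {
    v <- if (region %in% whole) voi else voi_sub
    sides <- if (subject$group == "PD") c("both", "worse", "better")
      else "both"
    for (side in sides) {
      suv <- measure_suv(pet, v, region, side, subject$worse_side)
      rows[[length(rows) + 1L]] <- data.frame(
        id = subject$id, group = subject$group, method = method,
        region = region, side = side, suv = suv,
        suvr = compute_suvr(suv, cereb), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Quantify one subject across normalization routes
#'
#' Measures regional SUV and SUVR for every requested route plus the
#' ground-truth reference (`TRUTH`: phantom labels applied to the native
#' PET), and the percent bias of each route against it.
#'
#' @param subject a `subject_record` with phantom truth.
#' @param templates a `template_set`.
#' @param routes character vector among `ssCT`, `itCT`, `MR`, `PET`.
#' @param regions base region names to report (defaults to caudate, putamen
#'   and the striatal subregions).
#' @param config a [register_config()].
#' @return Long data.frame `id, group, method, region, side, suv, suvr,
#'   bias_percent`.
#' @export
quantify_subject <- function(subject, templates,
                             routes = c("ssCT", "itCT", "MR", "PET"),
                             regions = c("caudate", "putamen", "caudate_ant",
                                         "caudate_post", "putamen_ant",
                                         "putamen_post", "ventral_striatum"),
                             config = register_config()) {
  # ground truth: phantom labels (parcellated the same way) on the native PET
  truth_voi <- voi_from_labels(
    subject$truth$labels,
    phantom_codes()[c("caudate_l", "caudate_r", "putamen_l", "putamen_r",
                      "cerebellum")])
  truth_sub <- parcellate_striatum(truth_voi)
  tab <- suvr_rows_for_pet(subject$pet, truth_voi, truth_sub, regions,
                           subject, "TRUTH")
  for (route in routes) {
    npet <- normalize_pet(subject, route, templates, config)
    tab <- rbind(tab, suvr_rows_for_pet(npet, templates$voi,
                                        templates$voi_sub, regions, subject,
                                        route))
  }
  truth <- tab[tab$method == "TRUTH", c("region", "side", "suvr")]
  names(truth)[3] <- "suvr_truth"
  tab <- merge(tab, truth, by = c("region", "side"), sort = FALSE)
  tab$bias_percent <- ifelse(tab$method == "TRUTH", 0,
                             compute_bias(tab$suvr, tab$suvr_truth))
  tab$suvr_truth <- NULL
  tab[order(tab$method, tab$region, tab$side),
      c("id", "group", "method", "region", "side", "suv", "suvr",
        "bias_percent")]
}

#' Quantify a cohort
#'
#' @param subjects list of `subject_record`s.
#' @inheritParams quantify_subject
#' @param progress print one line per subject.
#' @return Row-bound long data.frame over all subjects.
#' @export
quantify_cohort <- function(subjects, templates,
                            routes = c("ssCT", "itCT", "MR", "PET"),
                            regions = c("caudate", "putamen", "caudate_ant",
                                        "caudate_post", "putamen_ant",
                                        "putamen_post", "ventral_striatum"),
                            config = register_config(), progress = FALSE) {
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    if (progress)
      message(sprintf("[quantify] %s (%d/%d)", subjects[[i]]$id, i,
                      length(subjects)))
    out[[i]] <- quantify_subject(subjects[[i]], templates, routes, regions,
                                 config)
  }
  do.call(rbind, out)
}
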