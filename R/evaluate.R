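#' Two-sample group comparison
#'
#' Independent two-sided t-test, pooled-variance (Student) by default with
#' Welch available via `equal_var = FALSE`.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param equal_var pooled-variance if `TRUE` (default).
#' @return A `stats_result` list: `kind = "ttest"`, `t`, `p_value`, `df`,
#'   `n = c(n_a, n_b)`.
#' @export
group_ttest <- function(values_a, values_b, equal_var = TRUE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0 &&
      mean(values_a) == mean(values_b))
    stop("zero variance in both groups with equal means: t undefined")
  ht <- stats::t.test(values_a, values_b, var.equal = equal_var)
  structure(list(kind = "ttest", t = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 n = c(length(values_a), length(values_b))),
            class = "stats_result")
}

#' ROC area under the curve
#'
#' AUC as the Mann-Whitney probability that a randomly chosen subject of the
#' positive class ranks above a randomly chosen subject of the negative
#' class, ties counting one half.  For SUVR-style scores where *lower*
#' values indicate disease, set `direction = "lower"` so the reported AUC is
#' the discrimination ability of the marker (the orientation is recorded in
#' the result rather than folded silently into a sign change).
#'
#' @param values numeric scores.
#' @param labels binary labels (logical or 0/1; 1 = disease).
#' @param direction `"higher"` if larger scores indicate disease, `"lower"`
#'   otherwise.
#' @return A `stats_result`: `kind = "roc"`, `auc`, `direction`, `n`.
#' @export
roc_auc <- function(values, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- values[labels == 1L]; neg <- values[labels == 0L]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  auc <- u / (length(pos) * length(neg))
  if (direction == "lower") auc <- 1 - auc
  structure(list(kind = "roc", auc = auc, direction = direction,
                 n = c(positive = length(pos), negative = length(neg))),
            class = "stats_result")
}

#' Ordinary least-squares regression
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return A `stats_result`: `kind = "regression"`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided, of the slope), `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2, 4] else NA_real_
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0   # constant response: no variance explained
  if (!is.finite(p)) p <- 1
  structure(list(kind = "regression",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, p_value = p, n = length(x)),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("<stats_result:%s> %s\n", x$kind,
              paste(vapply(setdiff(names(x), "kind"), function(nm)
                sprintf("%s=%s", nm, paste(signif(unlist(x[[nm]]), 4),
                                           collapse = ",")), ""),
                collapse = " ")))
  invisible(x)
}

#' Mirror a template-space volume so the more-affected side lies left
#'
#' The more-affected striatal hemisphere is contralateral to the clinically
#' worse side.  If that hemisphere is not already on the left, the volume is
#' mirrored across the mid-sagittal plane; applying the operation twice is
#' the identity.  Requires an axis-aligned left-right (first) axis.
#'
#' @param vol template-space `ct_volume`.
#' @param worse_side the subject's clinically worse side (`"left"` or
#'   `"right"`).
#' @return Possibly mirrored `ct_volume` with `meta$flipped` recorded.
#' @export
flip_worse_left <- function(vol, worse_side = c("left", "right")) {
  worse_side <- match.arg(worse_side)
  offdiag <- vol$affine[1:3, 1:3]
  if (max(abs(offdiag[upper.tri(offdiag) | lower.tri(offdiag)])) > 1e-6)
    stop("left-right axis orientation is not axis-aligned")
  affected <- if (worse_side == "left") "right" else "left"
  out <- vol
  if (affected != "left") {
    out$data <- vol$data[dim(vol$data)[1]:1, , , drop = FALSE]
    out$meta$flipped <- !isTRUE(vol$meta$flipped)
  } else out$meta$flipped <- isTRUE(vol$meta$flipped)
  out
}

#' Voxelwise mean and SD images
#'
#' @param volumes list of >= 2 `ct_volume`s on one grid.
#' @return List with `mean` and `sd` (population SD) `ct_volume`s.
#' @export
mean_sd_images <- function(volumes) {
  stopifnot(length(volumes) >= 2L)
  g <- vol_grid(volumes[[1]])
  n <- length(volumes)
  s1 <- array(0, g$dim)
  for (v in volumes) {
    if (!same_grid(vol_grid(v), g)) stop("grid mismatch between volumes")
    s1 <- s1 + v$data
  }
  mu <- s1 / n
  varp <- array(0, g$dim)
  for (v in volumes) varp <- varp + (v$data - mu)^2
  varp <- varp / n
  list(mean = new_volume(mu, g$affine, volumes[[1]]$unit),
       sd = new_volume(sqrt(varp), g$affine, volumes[[1]]$unit))
}

#' Voxelwise two-sample t-test with permutation max-T correction
#'
#' Pooled-variance t at every in-mask voxel, with the family-wise error
#' threshold taken as the 95th percentile of the maximum absolute t over
#' seeded relabelings of the group assignment (max-T permutation
#' correction).
#'
#' @param group_a,group_b lists of `ct_volume`s (>= 2 each) on one grid.
#' @param mask binary `ct_volume`; statistics are computed inside it.
#' @param n_permutations number of relabelings (values below 100 flag the
#'   result as underpowered).
#' @param seed permutation seed.
#' @param alpha family-wise level.
#' @return List: `t_map` (`ct_volume`, 0 outside the mask), `threshold`
#'   (corrected |t| threshold), `max_t_null` (permutation distribution),
#'   `underpowered` flag.
#' @export
voxelwise_ttest <- function(group_a, group_b, mask, n_permutations = 1000L,
                            seed = 1L, alpha = 0.05) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  g <- vol_grid(group_a[[1]])
  msk <- mask$data > 0
  if (!any(msk)) stop("empty analysis mask")
  X <- vapply(c(group_a, group_b), function(v) {
    if (!same_grid(vol_grid(v), g)) stop("grid mismatch between volumes")
    as.vector(v$data)[as.vector(msk)]
  }, numeric(sum(msk)))
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  tstat <- function(lab_a) {
    xa <- X[, lab_a, drop = FALSE]; xb <- X[, !lab_a, drop = FALSE]
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- rowSums((xa - ma)^2); vb <- rowSums((xb - mb)^2)
    sp <- sqrt((va + vb) / (n - 2) * (1 / n1 + 1 / n2))
    (ma - mb) / pmax(sp, 1e-12)
  }
  labels <- c(rep(TRUE, n1), rep(FALSE, n2))
  t_obs <- tstat(labels)
  set.seed(as.integer(seed))
  max_t <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    perm <- sample(labels)
    max_t[p] <- max(abs(tstat(perm)))
  }
  thr <- stats::quantile(max_t, 1 - alpha, names = FALSE, type = 7)
  tm <- array(0, g$dim)
  tm[msk] <- t_obs
  list(t_map = new_volume(tm, g$affine, "arbitrary"), threshold = thr,
       max_t_null = max_t, underpowered = n_permutations < 100L)
}

#' Evaluate a quantification table
#'
#' Runs the evaluation battery on a [quantify_cohort()] table: per method
#' and region, the HC-vs-PD pooled t-test and ROC AUC of SUVR (lower SUVR
#' indicating disease), the mean/SD of per-subject percent bias by group,
#' and (given severities) the severity-against-SUVR regression in PD.
#'
#' @param uptake long data.frame from [quantify_cohort()].
#' @param severity optional data.frame `id, severity` for the regression.
#' @param side which side's rows to analyze (default `"both"`).
#' @return data.frame, one row per method x region, with columns
#'   `mean_suvr_hc, sd_suvr_hc, mean_suvr_pd, sd_suvr_pd, mean_bias_hc,
#'   mean_bias_pd, t, p_value, auc, sev_slope, sev_r2, sev_p`.
#' @export
evaluate_uptake <- function(uptake, severity = NULL, side = "both") {
  u <- uptake[uptake$side == side, ]
  out <- list()
  for (method in unique(u$method)) for (region in unique(u$region)) {
    d <- u[u$method == method & u$region == region, ]
    hc <- d$suvr[d$group == "HC"]; pd <- d$suvr[d$group == "PD"]
    row <- data.frame(method = method, region = region,
                      mean_suvr_hc = mean(hc), sd_suvr_hc = stats::sd(hc),
                      mean_suvr_pd = mean(pd), sd_suvr_pd = stats::sd(pd),
                      mean_bias_hc = mean(d$bias_percent[d$group == "HC"]),
                      mean_bias_pd = mean(d$bias_percent[d$group == "PD"]),
                      t = NA_real_, p_value = NA_real_, auc = NA_real_,
                      sev_slope = NA_real_, sev_r2 = NA_real_,
                      sev_p = NA_real_, stringsAsFactors = FALSE)
    if (length(hc) >= 2L && length(pd) >= 2L) {
      tt <- group_ttest(hc, pd)
      rc <- roc_auc(d$suvr, d$group == "PD", direction = "lower")
      row$t <- tt$t; row$p_value <- tt$p_value; row$auc <- rc$auc
    }
    if (!is.null(severity)) {
      pd_rows <- d[d$group == "PD", ]
      sev <- severity$severity[match(pd_rows$id, severity$id)]
      if (sum(!is.na(sev)) >= 3L && stats::var(pd_rows$suvr) > 0) {
        lr <- linear_regression(pd_rows$suvr, sev)
        row$sev_slope <- lr$slope; row$sev_r2 <- lr$r_squared
        row$sev_p <- lr$p_value
      }
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
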