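test_that("intensity templates are voxelwise means and reject mismatches", {
  v0 <- fx_uniform_vol(0); v2 <- fx_uniform_vol(2)
  tpl <- build_intensity_template(list(v0, v2))
  expect_true(all(tpl$data == 1))
  same <- build_intensity_template(list(v2, v2, v2))
  expect_equal(same$data, v2$data)
  other <- fx_uniform_vol(1, n = 6L)
  expect_error(build_intensity_template(list(v0, other)), "grid")
  expect_error(build_intensity_template(list(v0)))
  # permutation invariance
  set.seed(31)
  vs <- lapply(1:4, function(i) {
    v <- fx_uniform_vol(0); v$data[] <- stats::rnorm(length(v$data)); v
  })
  expect_equal(build_intensity_template(vs)$data,
               build_intensity_template(rev(vs))$data)
})

test_that("probabilistic maps average binary masks into [0, 1]", {
  g <- iso_grid(8, 2)
  mk <- function(sel) {
    a <- array(0, g$dim); a[sel, , ] <- 1
    new_volume(a, g$affine, "label")
  }
  m1 <- mk(1:4); m2 <- mk(3:6)
  pm <- build_probabilistic_map(list(m1, m2))
  expect_true(all(pm$data >= 0 & pm$data <= 1))
  expect_true(all(pm$data[3:4, , ] == 1))                # intersection
  expect_true(all(pm$data[c(1:2, 5:6), , ] == 0.5))      # symmetric difference
  expect_equal(build_probabilistic_map(list(m1, m1))$data, m1$data,
               ignore_attr = TRUE)
  bad <- m1; bad$data[1] <- 2L
  expect_error(build_probabilistic_map(list(bad)), "binary")
  # maps built from a partition sum to at most 1 everywhere
  parts <- list(mk(1:2), mk(3:5), mk(6:8))
  maps <- lapply(parts, function(m) build_probabilistic_map(list(m)))
  tot <- Reduce(`+`, lapply(maps, function(m) m$data))
  expect_true(all(tot <= 1 + 1e-12))
})

test_that("VOI thresholding is inclusive at 0.8 and argmax on overlap", {
  g <- iso_grid(6, 2)
  mk <- function(vals) new_volume(array(vals, g$dim), g$affine, "probability")
  a <- array(0, g$dim); b <- array(0, g$dim)
  a[1, 1, 1] <- 0.80       # boundary: included
  a[2, 1, 1] <- 0.79       # just below: excluded
  a[3, 1, 1] <- 0.85; b[3, 1, 1] <- 0.90   # overlap: b wins
  b[4, 1, 1] <- 1
  voi <- build_voi_template(list(ra = mk(a), rb = mk(b)), threshold = 0.8)
  expect_equal(voi$labels$data[1, 1, 1], voi$regions[["ra"]])
  expect_equal(voi$labels$data[2, 1, 1], 0L)
  expect_equal(voi$labels$data[3, 1, 1], voi$regions[["rb"]])
  # regions are disjoint by construction (single label volume) and nonempty
  expect_true(all(c("ra", "rb") %in% names(voi$regions)))
  empty <- array(0, g$dim)
  expect_error(build_voi_template(list(ra = mk(a), rc = mk(empty))), "rc")
  # exhaustive check of the argmax rule on a toy two-region map
  set.seed(41)
  pa <- array(stats::runif(216), g$dim); pb <- array(stats::runif(216), g$dim)
  voi2 <- build_voi_template(list(A = mk(pa), B = mk(pb)), threshold = 0.5)
  lab <- voi2$labels$data
  manual <- ifelse(pmax(pa, pb) < 0.5, 0L, ifelse(pa >= pb, 1L, 2L))
  expect_equal(as.vector(lab), as.vector(manual))
})

test_that("striatal parcellation partitions each nucleus", {
  tset <- fx_templates48()
  voi <- tset$voi; sub <- tset$voi_sub
  for (side in c("l", "r")) for (nuc in c("caudate", "putamen")) {
    parent <- voi$labels$data == voi$regions[[paste0(nuc, "_", side)]]
    kids <- sub$labels$data %in% unlist(sub$regions[paste0(
      c(paste0(nuc, "_ant_"), paste0(nuc, "_post_")), side)])
    vs <- sub$labels$data == sub$regions[[paste0("ventral_striatum_", side)]]
    # children + the nucleus' share of ventral striatum tile the parent
    expect_equal(sum(parent), sum((kids | vs) & parent))
    expect_equal(sum(kids & vs), 0)  # disjoint
  }
  # anterior/posterior split of a symmetric synthetic nucleus is near-equal
  g <- iso_grid(24, 2)
  pts <- ctnorm:::grid_world_coords(g)
  ell <- function(c0, s0)
    rowSums(sweep(sweep(pts, 2, c0), 2, s0, `/`)^2) <= 1
  labs <- array(0L, g$dim)
  labs[ell(c(-8, 0, 12), c(4, 8, 5))] <- 1L   # caudate_l
  labs[ell(c(8, 0, 12), c(4, 8, 5))] <- 2L    # caudate_r
  labs[ell(c(-14, 0, 2), c(4, 9, 5))] <- 3L   # putamen_l
  labs[ell(c(14, 0, 2), c(4, 9, 5))] <- 4L    # putamen_r
  toy <- voi_from_labels(new_volume(labs, g$affine, "label"),
                         c(caudate_l = 1L, caudate_r = 2L,
                           putamen_l = 3L, putamen_r = 4L))
  sub2 <- parcellate_striatum(toy)
  # caudates sit fully above the ventral cut, so ant/post tile them evenly
  na <- sum(sub2$labels$data == sub2$regions[["caudate_ant_l"]])
  np <- sum(sub2$labels$data == sub2$regions[["caudate_post_l"]])
  n_slab <- sum(labs == 1L) / (2 * 8 / 2)  # about one coronal slab of voxels
  expect_lt(abs(na - np), n_slab)
  # degenerate single-slice nucleus is rejected
  flat <- labs
  flat[, , ] <- 0L
  flat[10:12, 10:14, 12] <- 1L; flat[14, 10:14, 12] <- 2L
  flat[10:12, 4:8, 12] <- 3L; flat[14, 4:8, 12] <- 4L
  expect_error(parcellate_striatum(
    voi_from_labels(new_volume(flat, g$affine, "label"),
                    c(caudate_l = 1L, caudate_r = 2L,
                      putamen_l = 3L, putamen_r = 4L))), "single-slice")
})

test_that("PD phantoms show the posterior < anterior putaminal gradient", {
  s <- fx_pd48()
  voi <- voi_from_labels(s$truth$labels,
                         phantom_codes()[c("caudate_l", "caudate_r",
                                           "putamen_l", "putamen_r",
                                           "cerebellum")])
  sub <- parcellate_striatum(voi)
  pet <- s$pet$data
  ant <- mean(pet[sub$labels$data %in% unlist(sub$regions[c("putamen_ant_l",
                                                            "putamen_ant_r")])])
  post <- mean(pet[sub$labels$data %in% unlist(sub$regions[c("putamen_post_l",
                                                             "putamen_post_r")])])
  expect_lt(post, ant)
})

test_that("template construction is deterministic and complete", {
  tset <- fx_templates48()
  expect_true(all(c("whole_ct", "itct", "ssct", "mr", "pet", "priors",
                    "scalp_mask", "voi", "voi_sub") %in% names(tset)))
  for (m in list(tset$priors$skull, tset$priors$brain, tset$priors$csf))
    expect_true(all(m$data >= 0 & m$data <= 1))
  # striatal contrast of the PET template reflects the generative ratio
  voi <- tset$voi
  put <- voi$labels$data %in% unlist(voi$regions[c("putamen_l", "putamen_r")])
  cer <- voi$labels$data == voi$regions[["cerebellum"]]
  ratio <- mean(tset$pet$data[put]) / mean(tset$pet$data[cer])
  # PSF dilutes the generative 8.9 ratio; it must remain strongly > 1
  expect_gt(ratio, 3)
  expect_lt(ratio, 8.9 * 1.1)
})
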