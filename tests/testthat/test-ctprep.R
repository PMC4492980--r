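test_that("non-negativity offset shifts only when needed and keeps order", {
  g <- iso_grid(6, 2)
  mk <- function(vals) new_volume(array(vals, g$dim), g$affine, "HU")
  v <- mk(seq(-1000, 500, length.out = 216))
  o <- offset_to_nonnegative(v)
  expect_equal(min(o$data), 0)
  expect_equal(o$meta$offset_shift, 1000)
  expect_equal(diff(range(o$data)), diff(range(v$data)))
  v0 <- mk(seq(0, 100, length.out = 216))
  expect_equal(offset_to_nonnegative(v0)$data, v0$data)
  v5 <- mk(seq(5, 100, length.out = 216))
  o5 <- offset_to_nonnegative(v5)
  expect_equal(o5$data, v5$data)          # no shift for positive minima
  expect_identical(order(o5$data), order(v5$data))
  vb <- mk(c(NaN, rep(0, 215)))
  expect_error(offset_to_nonnegative(vb), "finite")
})

test_that("the piecewise intensity map hits its anchor points exactly", {
  expect_identical(intensity_transform(-100), 900)
  expect_identical(intensity_transform(100), 3100)
  expect_identical(intensity_transform(0), 2000)
  expect_identical(intensity_transform(-500), 500)
  expect_identical(intensity_transform(150), 3150)
})

test_that("the intensity map is continuous, monotone and rank-preserving", {
  hu <- seq(-1024, 3000, by = 0.25)
  out <- intensity_transform(hu)
  expect_true(all(diff(out) >= 0))
  expect_lt(max(abs(diff(out))), 3.1)   # no jumps beyond the local slope
  set.seed(4)
  g <- iso_grid(8, 2)
  v <- new_volume(array(stats::runif(512, -1000, 1500), g$dim), g$affine, "HU")
  tv <- intensity_transform(v)
  expect_identical(dim(tv$data), dim(v$data))
  expect_identical(tv$affine, v$affine)
  expect_identical(order(tv$data), order(v$data))
  # malformed parameter sets are rejected
  expect_error(itct_params(low_break = 100, high_break = -100))
  expect_error(itct_params(low_offset = 500), "discontinuous")
})

test_that("scalp-stripping masks exactly the requested voxels", {
  g <- iso_grid(6, 2)
  ct <- new_volume(array(seq_len(216), g$dim), g$affine, "HU")
  ones <- new_volume(array(1L, g$dim), g$affine, "label")
  expect_equal(strip_scalp(ct, ones)$data, ct$data)
  one_out <- ones; one_out$data[3, 4, 5] <- 0L
  st <- strip_scalp(ct, one_out)
  expect_equal(sum(st$data != ct$data), 1)
  expect_equal(st$data[3, 4, 5], min(ct$data))
  zeros <- ones; zeros$data[] <- 0L
  expect_error(strip_scalp(ct, zeros), "empty")
})

test_that("scalp-stripping a phantom keeps the skull, drops the scalp", {
  s <- fx_hc48()
  lab <- s$truth$labels
  codes <- phantom_codes()
  mask <- lab
  mask$data <- array(as.integer(lab$data %in% codes[c("skull", "brain", "csf",
                                                      "caudate_l", "caudate_r",
                                                      "putamen_l", "putamen_r",
                                                      "cerebellum")]),
                     dim(lab$data))
  st <- strip_scalp(s$ct, mask)
  skull <- lab$data == codes["skull"]
  expect_true(all(st$data[skull] == s$ct$data[skull]))
  scalp <- lab$data == codes["scalp"]
  expect_gte(mean(st$data[scalp] == min(s$ct$data)), 0.99)
})

test_that("MAP segmentation follows priors and intensity evidence", {
  g <- iso_grid(12, 2)
  set.seed(2)
  # three blocks at distinct intensities
  intens <- array(0, g$dim)
  intens[1:4, , ] <- 1000; intens[5:8, , ] <- 30; intens[9:12, , ] <- 5
  ct <- new_volume(intens + stats::rnorm(12^3, 0, 1), g$affine, "arbitrary")
  pm <- function(sel) {
    a <- array(0, g$dim); a[sel, , ] <- 1
    new_volume(a, g$affine, "probability")
  }
  priors <- tissue_maps(skull = pm(1:4), brain = pm(5:8), csf = pm(9:12))
  seg <- segment_tissues(ct, priors)
  codes <- phantom_codes()
  expect_true(all(seg$data[1:4, , ] == codes["skull"]))
  expect_true(all(seg$data[5:8, , ] == codes["brain"]))
  expect_true(all(seg$data[9:12, , ] == codes["csf"]))
  # prior dominance: a brain-certain voxel stays brain whatever its intensity
  pri2 <- tissue_maps(skull = pm(integer(0)), brain = pm(1:12),
                      csf = pm(integer(0)))
  expect_error(segment_tissues(ct, pri2), "zero mass")
  # labels partition the volume: one class per voxel, background only where
  # all priors vanish
  u <- array(1 / 3, g$dim)
  flat <- tissue_maps(
    skull = new_volume(u, g$affine, "probability"),
    brain = new_volume(u, g$affine, "probability"),
    csf = new_volume(u, g$affine, "probability"))
  seg2 <- segment_tissues(ct, flat)
  expect_true(all(seg2$data %in% codes[c("skull", "brain", "csf")]))
})

test_that("template-space segmentation with cohort priors reaches Dice >= 0.90", {
  # a subject outside the prior-building cohort, brought to template space
  # with its gold-standard parameters and segmented with the soft priors
  tset <- fx_templates48()
  s <- fx_pd48()
  codes <- phantom_codes()
  ct_n <- apply_transform(offset_to_nonnegative(s$ct), s$truth$to_subject,
                          tset$grid)
  lab_n <- apply_transform(s$truth$labels, s$truth$to_subject, tset$grid,
                           interpolation = "nearest", fill = 0)
  seg <- segment_tissues(ct_n, tset$priors)
  brain_codes <- codes[c("brain", "caudate_l", "caudate_r", "putamen_l",
                         "putamen_r", "cerebellum")]
  truth <- lab_n$data %in% brain_codes
  est <- seg$data == codes["brain"]
  dice <- 2 * sum(truth & est) / (sum(truth) + sum(est))
  expect_gte(dice, 0.90)
})

test_that("skull-stripping masks to the brain segment and is idempotent", {
  s <- fx_hc48()
  lab <- s$truth$labels
  codes <- phantom_codes()
  brain <- lab
  brain$data <- array(as.integer(lab$data %in%
                                   codes[c("brain", "caudate_l", "caudate_r",
                                           "putamen_l", "putamen_r",
                                           "cerebellum")]), dim(lab$data))
  ss <- skull_strip(s$ct, brain, brain_code = NULL)
  expect_true(all(ss$data[lab$data == codes["skull"]] == min(s$ct$data)))
  expect_true(abs(mean(ss$data[lab$data == codes["brain"]]) - 30) < 10)
  expect_equal(skull_strip(ss, brain, brain_code = NULL)$data, ss$data)
  whole <- brain; whole$data[] <- 1L
  expect_equal(skull_strip(s$ct, whole, brain_code = NULL)$data, s$ct$data)
  none <- brain; none$data[] <- 0L
  expect_error(skull_strip(s$ct, none, brain_code = NULL), "empty")
})

test_that("full ssCT preparation removes the skull on a real pipeline run", {
  tset <- fx_templates48()
  s <- fx_pd48()
  prep <- make_ssct(s$ct, tset)
  lab <- s$truth$labels$data
  codes <- phantom_codes()
  skull <- lab == codes["skull"]
  # virtually no skull-stratum intensities survive in the ssCT
  expect_lt(mean(prep$ssct$data[skull] > 500), 0.02)
  truth_brain <- lab %in% codes[c("brain", "caudate_l", "caudate_r",
                                  "putamen_l", "putamen_r", "cerebellum")]
  est <- prep$segmentation$data == codes["brain"]
  dice <- 2 * sum(truth_brain & est) / (sum(truth_brain) + sum(est))
  expect_gte(dice, 0.85)
})
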