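test_that("pooled t-test matches the hand-computed example", {
  r <- group_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$t), 3.674, tolerance = 1e-3)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-2)
  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_ttest(c(2, 2), c(2, 2)), "zero variance")
  # Welch flag reaches the unpooled test
  w <- group_ttest(c(1, 2, 3, 9), c(4, 4.1, 4.2), equal_var = FALSE)
  expect_lt(w$df, 5)
})

test_that("t-test type-I error is nominal under the null", {
  set.seed(55)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i)
    group_ttest(stats::rnorm(12), stats::rnorm(12))$p_value, 0)
  rate <- mean(p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), tol)
})

test_that("AUC equals exhaustive pair counting, with ties at one half", {
  # worked example: controls {3,4,5} vs patients {1,2,3}, lower = disease
  r <- roc_auc(c(3, 4, 5, 1, 2, 3), c(0, 0, 0, 1, 1, 1), direction = "lower")
  expect_equal(r$auc, 8.5 / 9)
  # exhaustive oracle on random small instances
  set.seed(66)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    pos <- sample(1:5, n1, replace = TRUE)
    neg <- sample(1:5, n0, replace = TRUE)
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(c(pos, neg), rep(c(1, 0), c(n1, n0)))$auc,
                 mean(pairs))
  }
  # label inversion mirrors the AUC
  v <- c(0.3, 0.8, 0.2, 0.9, 0.5); l <- c(0, 1, 0, 1, 1)
  expect_equal(roc_auc(v, l)$auc, 1 - roc_auc(v, 1 - l)$auc)
  # perfect separation and degenerate input
  expect_equal(roc_auc(c(1, 2, 8, 9), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(68)
  v <- stats::rnorm(40); l <- rep(c(0, 1), 20)
  ours <- roc_auc(v, l)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(l, v, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("least-squares regression matches closed-form results", {
  perfect <- linear_regression(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 2)
  flat <- linear_regression(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(flat$r_squared, 0)
  hand <- linear_regression(c(1, 2, 3), c(2, 2, 4))
  expect_equal(hand$slope, 1)
  expect_equal(hand$r_squared, 0.75)
  expect_error(linear_regression(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("worse-side flipping is an involution that moves hemispheres", {
  g <- iso_grid(10, 2)
  v <- new_volume(array(stats::runif(1000), g$dim), g$affine, "SUV")
  # clinically worse right side: affected striatum is LEFT, already left
  f1 <- flip_worse_left(v, "right")
  expect_equal(f1$data, v$data)
  # clinically worse left side: affected striatum right -> must mirror
  f2 <- flip_worse_left(v, "left")
  expect_false(identical(f2$data, v$data))
  f3 <- flip_worse_left(f2, "left")  # flipping twice restores parity
  expect_equal(f3$data[dim(f3$data)[1]:1, , ], f2$data)
  # left-hemisphere-only mass moves to the right half under the flip
  half <- v; half$data[] <- 0; half$data[1:4, , ] <- 1
  flipped <- flip_worse_left(half, "left")
  expect_equal(sum(flipped$data[7:10, , ]), sum(half$data[1:4, , ]))
  expect_equal(sum(flipped$data[1:4, , ]), 0)
  # symmetric volumes are unchanged
  sym <- v; sym$data <- (sym$data + sym$data[10:1, , ]) / 2
  expect_equal(flip_worse_left(sym, "left")$data, sym$data)
  # oblique affines are rejected
  ob <- v; ob$affine[1, 2] <- 0.3
  expect_error(flip_worse_left(ob, "left"), "axis")
})

test_that("mean/SD images are exact and permutation invariant", {
  g <- iso_grid(8, 2)
  set.seed(71)
  v <- new_volume(array(stats::rnorm(512), g$dim), g$affine, "SUV")
  nv <- v; nv$data <- -v$data
  ms <- mean_sd_images(list(v, nv))
  expect_true(all(abs(ms$mean$data) < 1e-12))
  expect_equal(ms$sd$data, abs(v$data))
  same <- mean_sd_images(list(v, v, v))
  expect_lt(max(same$sd$data), 1e-12)
  vs <- lapply(1:4, function(i) {
    w <- v; w$data[] <- stats::rnorm(512); w
  })
  a <- mean_sd_images(vs); b <- mean_sd_images(rev(vs))
  expect_equal(a$mean$data, b$mean$data)
  expect_equal(a$sd$data, b$sd$data)
})

test_that("voxelwise t-maps are antisymmetric and null-calibrated", {
  g <- iso_grid(8, 2)
  mask <- new_volume(array(1L, g$dim), g$affine, "label")
  mk <- function(seed) {
    set.seed(seed)
    new_volume(array(stats::rnorm(512), g$dim), g$affine, "SUV")
  }
  a <- lapply(1:5, mk); b <- lapply(6:10, mk)
  r1 <- voxelwise_ttest(a, b, mask, n_permutations = 150, seed = 2)
  r2 <- voxelwise_ttest(b, a, mask, n_permutations = 150, seed = 2)
  expect_equal(r1$t_map$data, -r2$t_map$data, tolerance = 1e-10)
  expect_false(r1$underpowered)
  expect_true(voxelwise_ttest(a, b, mask, n_permutations = 50,
                              seed = 2)$underpowered)
  # family-wise null calibration: identical-distribution groups exceed the
  # corrected threshold in about 5% of replicate experiments
  set.seed(83)
  hits <- vapply(1:60, function(i) {
    ga <- lapply(seq_len(6), function(j)
      new_volume(array(stats::rnorm(512), g$dim), g$affine, "SUV"))
    gb <- lapply(seq_len(6), function(j)
      new_volume(array(stats::rnorm(512), g$dim), g$affine, "SUV"))
    r <- voxelwise_ttest(ga, gb, mask, n_permutations = 200, seed = i)
    max(abs(r$t_map$data)) > r$threshold
  }, NA)
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 60) + 0.02)
})

test_that("group t-maps light up the true striatal deficit", {
  # template-space PET images via ground truth; PD lesion sits in the putamen
  coh <- fx_get("tmap_cohort", function()
    generate_cohort(8, 8, fx_params32(), seed = 33))
  hc_s <- Filter(function(s) s$group == "HC", coh$subjects)
  tset <- fx_get("tmap_templates", function() build_template_set(hc_s))
  norm_pet <- function(s)
    apply_transform(s$pet, s$truth$to_subject, tset$grid, fill = 0)
  hc <- lapply(hc_s, norm_pet)
  pd <- lapply(Filter(function(s) s$group == "PD", coh$subjects), norm_pet)
  brain <- tset$priors$brain
  mask <- new_volume(array(as.integer(brain$data > 0.5), tset$grid$dim),
                     tset$grid$affine, "label")
  r <- voxelwise_ttest(hc, pd, mask, n_permutations = 200, seed = 4)
  supra <- r$t_map$data > r$threshold
  put <- tset$voi$labels$data %in% unlist(tset$voi$regions[c("putamen_l",
                                                             "putamen_r")])
  expect_gt(sum(supra & put), 0)
  expect_gt(mean(supra[put]), mean(supra[!put & mask$data > 0]))
})

test_that("evaluate_uptake summarizes per method and region", {
  set.seed(90)
  mkrows <- function(method, region, hc_mu, pd_mu) {
    data.frame(id = c(sprintf("HC%02d", 1:8), sprintf("PD%02d", 1:8)),
               group = rep(c("HC", "PD"), each = 8), method = method,
               region = region, side = "both",
               suv = 1, suvr = c(stats::rnorm(8, hc_mu, 0.5),
                                 stats::rnorm(8, pd_mu, 0.5)),
               bias_percent = stats::rnorm(16, 5, 1))
  }
  up <- rbind(mkrows("TRUTH", "putamen", 8.9, 4.6),
              mkrows("PET", "putamen", 8.9, 6.1))
  sev <- data.frame(id = sprintf("PD%02d", 1:8),
                    severity = stats::rnorm(8, 28, 8))
  st <- evaluate_uptake(up, severity = sev)
  expect_identical(nrow(st), 2L)
  expect_true(all(st$auc > 0.5))
  expect_true(all(is.finite(st$t)))
  truth_row <- st[st$method == "TRUTH", ]
  expect_equal(truth_row$mean_suvr_hc, 8.9, tolerance = 0.8)
})
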