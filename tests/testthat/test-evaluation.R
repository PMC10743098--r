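make_jmap <- function(vals, shape = c(10, 10, 10), spacing = 3) {
  jacobian_map(volume3d(array(vals, shape), spacing, kind = "jacobian"))
}

test_that("identity prediction yields perfect local metrics", {
  set.seed(1)
  shape <- c(10, 10, 10)
  j <- make_jmap(exp(rnorm(prod(shape), 0.4, 0.2)), shape)
  m <- lung_mask(array(1, shape), 3)
  lm <- local_metrics(j, j, m)
  expect_equal(lm$mae, 0)
  expect_equal(lm$spearman, 1)
  expect_equal(lm$ssim, 1, tolerance = 1e-9)
  expect_true(is.infinite(lm$psnr))
  expect_equal(lm$dice_low, 1)
  expect_equal(lm$dice_high, 1)
})

test_that("Spearman matches a brute-force rank formula on listed values", {
  shape <- c(10, 1, 1)
  ja <- c(1.2, 0.8, 1.5, 1.1, 0.9, 2.0, 1.05, 0.7, 1.3, 1.6)
  jb <- c(1.1, 0.9, 1.4, 1.0, 1.2, 1.8, 1.00, 0.8, 1.5, 1.3)
  m <- lung_mask(array(1, shape), 3)
  lm <- local_metrics(make_jmap(ja, shape), make_jmap(jb, shape), m)
  a <- abs(log2(ja)); b <- abs(log2(jb))
  ra <- rank(a); rb <- rank(b)
  rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(lm$spearman, rho, tolerance = 1e-12)
})

test_that("permuted predictions behave like the null", {
  set.seed(42)
  shape <- c(10, 10, 10)
  vals <- exp(rnorm(1000, 0.5, 0.25))
  j <- make_jmap(vals, shape)
  jp <- make_jmap(sample(vals), shape)
  m <- lung_mask(array(1, shape), 3)
  lm <- local_metrics(j, jp, m)
  expect_lt(abs(lm$spearman), 0.2)
})

test_that("constant maps flag Spearman as undefined", {
  shape <- c(6, 6, 6)
  j1 <- make_jmap(1.5, shape)
  set.seed(2)
  j2 <- make_jmap(exp(rnorm(216, 0.3, 0.1)), shape)
  m <- lung_mask(array(1, shape), 3)
  expect_warning(dice_quartile(j1, j2, m, "low"), "degenerate")
  lm <- suppressWarnings(local_metrics(j1, j2, m))
  expect_true(is.na(lm$spearman))
  expect_true(lm$spearman_undefined)
  expect_equal(lm$dice_low, 0)
})

test_that("quartile Dice matches hand counts and detects reversal", {
  # 8 in-mask voxels with known quartiles
  shape <- c(8, 1, 1)
  ja <- c(1, 2, 3, 4, 5, 6, 7, 8)
  jb <- c(1, 2, 3, 4, 5, 6, 7, 8)
  m <- lung_mask(array(1, shape), 3)
  expect_equal(dice_quartile(make_jmap(ja, shape), make_jmap(jb, shape),
                             m, "low"), 1)
  jb2 <- c(2, 1, 3, 4, 5, 6, 8, 7)  # same quartile membership
  expect_equal(dice_quartile(make_jmap(ja, shape), make_jmap(jb2, shape),
                             m, "high"), 1)
  # reversed gradient: opposite quartiles have no overlap
  grad <- seq(0.5, 2, length.out = 1000)
  shape2 <- c(10, 10, 10)
  d <- dice_quartile(make_jmap(grad, shape2), make_jmap(rev(grad), shape2),
                     lung_mask(array(1, shape2), 3), "low")
  expect_lt(d, 0.05)
})

test_that("quartile regions hold a quarter of the mask each", {
  set.seed(3)
  shape <- c(12, 12, 12)
  vals <- exp(rnorm(prod(shape), 0.3, 0.2))
  j <- make_jmap(vals, shape)
  m <- lung_mask(array(1, shape), 3)
  q <- quantile(vals, 0.25, names = FALSE)
  expect_equal(sum(vals < q) / prod(shape), 0.25, tolerance = 2 / prod(shape))
})

test_that("global statistics use the population standard deviation", {
  shape <- c(2, 1, 1)
  gs <- global_stats(make_jmap(c(1, 3), shape),
                     lung_mask(array(1, shape), 3))
  expect_equal(gs$j_mean, 2)
  expect_equal(gs$j_cv, 0.5)
  gs2 <- global_stats(make_jmap(2, c(4, 4, 4)),
                      lung_mask(array(1, c(4, 4, 4)), 3))
  expect_equal(gs2$j_mean, 2)
  expect_equal(gs2$j_cv, 0)
})

test_that("ROI volume change follows the partition identity", {
  shape <- c(8, 8, 2)
  m <- lung_mask(array(1, shape), 3)
  labs <- array(rep(c(1L, 2L), each = 64), shape)
  rois <- roi_label_map(labs, c(a = 1, b = 2), 3)
  j <- array(1, shape)
  j[labs == 1] <- 1.5
  j[labs == 2] <- 2.5
  dv <- roi_volume_change(make_jmap(j, shape), rois, m)
  expect_equal(dv$table$dv_pct, c(25, 75), tolerance = 1e-9)
  expect_equal(sum(dv$table$dv_pct), 100, tolerance = 1e-6)
  expect_false(dv$excluded)
  # zero-change ROI contributes zero volume change
  j2 <- j; j2[labs == 1] <- 1
  dv2 <- roi_volume_change(make_jmap(j2, shape), rois, m)
  expect_equal(dv2$table$dv_mm3[1], 0)
})

test_that("volume-change percentages sum to 100 on random partitions", {
  set.seed(9)
  shape <- c(10, 10, 10)
  m <- lung_mask(array(1, shape), 3)
  for (rep in 1:3) {
    labs <- array(sample(1:4, prod(shape), TRUE), shape)
    rois <- roi_label_map(labs, setNames(1:4, paste0("r", 1:4)), 3)
    j <- make_jmap(exp(rnorm(prod(shape), 0.3, 0.3)), shape)
    dv <- roi_volume_change(j, rois, m)
    expect_equal(sum(dv$table$dv_pct), 100, tolerance = 1e-6)
  }
})

test_that("near-unity mean Jacobian triggers the exclusion flag", {
  shape <- c(6, 6, 6)
  m <- lung_mask(array(1, shape), 3)
  rois <- roi_label_map(array(1L, shape), c(all = 1), 3)
  dv <- roi_volume_change(make_jmap(1.01, shape), rois, m)
  expect_true(dv$excluded)
  dv2 <- roi_volume_change(make_jmap(1.05, shape), rois, m)
  expect_false(dv2$excluded)
})

test_that("PRM classification applies the HU threshold rules", {
  shape <- c(3, 1, 1)
  frc <- volume3d(array(c(-900, -900, -800), shape), 3, kind = "HU")
  tlc <- volume3d(array(c(-960, -940, -940), shape), 3, kind = "HU")
  m <- lung_mask(array(1, shape), 3)
  prm <- prm_classify(frc, tlc, m)
  expect_equal(as.vector(prm$data), c(3L, 2L, 1L))  # emphysema, fSAD, normal
  expect_true(check_partition(prm, m))
})

test_that("PRM classes partition a phantom lung", {
  ph <- clean_phantom(seed = 10, shape = c(24, 24, 24),
                      disease_fraction = 0.2)
  # exact voxel correspondence: resample TLC intensities through h
  m <- ph$M_FRC$data == 1
  pts <- jacreg:::grid_points(grid3d(dim(ph$I_FRC$data), 3))
  hx <- deform_apply(ph$h, pts[m, ])
  i_tlc_warp <- array(-1000, dim(ph$I_TLC$data))
  i_tlc_warp[m] <- jacreg:::interp_trilinear(ph$I_TLC$data, 3, c(0, 0, 0), hx)
  prm <- prm_classify(ph$I_FRC,
                      volume3d(i_tlc_warp, 3, kind = "HU"), ph$M_FRC)
  expect_true(check_partition(prm, ph$M_FRC))
  expect_gte(length(unique(prm$data[m])), 2)
})

test_that("agreement summary recovers exact and shifted relations", {
  set.seed(4)
  ref <- rnorm(20, 10, 3)
  ag <- agreement_summary(ref, ref)
  expect_equal(ag$slope, 1, tolerance = 1e-12)
  expect_equal(ag$intercept, 0, tolerance = 1e-12)
  expect_equal(ag$r_squared, 1, tolerance = 1e-12)
  expect_equal(ag$bland_altman$mean_diff[1], 0)
  expect_equal(ag$bland_altman$lo[1], 0)
  ag2 <- agreement_summary(ref + 2.5, ref)
  expect_equal(ag2$slope, 1, tolerance = 1e-12)
  expect_equal(ag2$bland_altman$mean_diff[1], 2.5)
})

test_that("agreement regression matches the normal equations on 4 pairs", {
  ref <- c(1, 2, 3, 4)
  pred <- c(1.1, 1.9, 3.3, 3.9)
  ag <- agreement_summary(pred, ref)
  sxx <- sum((ref - mean(ref))^2)
  sxy <- sum((ref - mean(ref)) * (pred - mean(pred)))
  expect_equal(ag$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(ag$intercept, mean(pred) - ag$slope * mean(ref),
               tolerance = 1e-12)
  expect_equal(ag$r_squared, cor(pred, ref)^2, tolerance = 1e-12)
  expect_error(agreement_summary(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("metrics are invariant to voxel traversal order", {
  set.seed(12)
  shape <- c(8, 8, 8)
  vals_a <- exp(rnorm(prod(shape), 0.3, 0.2))
  vals_b <- exp(rnorm(prod(shape), 0.3, 0.2))
  m <- lung_mask(array(1, shape), 3)
  lm1 <- local_metrics(make_jmap(vals_a, shape), make_jmap(vals_b, shape), m)
  # reverse all three axes consistently: same multiset of paired voxels
  rev_arr <- function(x) x[shape[1]:1, shape[2]:1, shape[3]:1]
  ja2 <- make_jmap(rev_arr(array(vals_a, shape)), shape)
  jb2 <- make_jmap(rev_arr(array(vals_b, shape)), shape)
  lm2 <- local_metrics(ja2, jb2, m)
  expect_equal(lm1$mae, lm2$mae)
  expect_equal(lm1$spearman, lm2$spearman)
  expect_equal(lm1$dice_low, lm2$dice_low)
})

test_that("cohort reports carry the full metric schema and identity controls", {
  cohort <- lapply(1:6, function(s) clean_phantom(seed = 40 + s,
                                                  shape = c(16, 16, 16)))
  fact <- run_factorial(cohort, network_config(L = 2, base_filters = 2),
                        loss_config(),
                        train_config(epochs = 1, batch_size = 2, seed = 4),
                        test_fraction = 1 / 3)
  report <- evaluate_cohort(fact, cohort, include_controls = TRUE)
  pc <- report$per_case
  metrics <- c("mae", "spearman", "psnr", "ssim", "dice_low", "dice_high")
  expect_true(all(metrics %in% names(pc)))
  n_test <- length(fact$test_idx)
  expect_equal(sum(pc$arm != "control_frc"), 4 * n_test)
  # ground-truth-as-prediction rows show the identity values
  ctrl <- pc[pc$arm == "control_frc", ]
  expect_equal(nrow(ctrl), n_test)
  expect_equal(max(ctrl$mae), 0)
  expect_equal(min(ctrl$spearman), 1)
  expect_equal(min(ctrl$dice_low), 1)
  # agreement covers J-mean plus lobar and PRM volume-change fractions
  expect_true(all(c("j_mean_r2", "dv_pct_r2", "dv_prm_r2") %in%
                    names(report$agreement)))
  out <- withr::local_tempdir()
  write_metrics_report(report, out)
  expect_true(file.exists(file.path(out, "per_case_metrics.csv")))
  expect_true(file.exists(file.path(out, "agreement_summary.csv")))
})
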