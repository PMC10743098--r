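#' Local and regional similarity metrics between Jacobian maps
#'
#' All metrics are computed on the magnitude scale `|log2 J|`, so expansion
#' and contraction maps are comparable: MAE, voxelwise Spearman correlation
#' (average ranks for ties), PSNR (`10 log10(peak^2 / MSE)`, peak = the
#' SSIM dynamic range), masked mean SSIM, and Dice overlap of the low/high
#' Jacobian quartile regions.
#'
#' A constant reference or prediction leaves Spearman undefined; it is then
#' reported as `NA` with the `spearman_undefined` flag.
#'
#' @param j_ref,j_pred `jr_jacmap`s (or `jr_volume`s of Jacobian values) on
#'   the same grid.
#' @param mask `jr_mask`.
#' @param params A `jr_ssim_params` (supplies the PSNR peak).
#' @return A one-row `data.frame`: mae, spearman, psnr, ssim, dice_low,
#'   dice_high, plus flag columns.
#' @export
local_metrics <- function(j_ref, j_pred, mask, params = ssim_params()) {
  a <- abs_log2(j_ref)
  b <- abs_log2(j_pred)
  m <- as_mask_arr(mask)
  if (!any(m)) stop("empty mask")
  av <- a[m]; bv <- b[m]
  mae <- mean(abs(av - bv))
  undef <- (sd(av) == 0 || sd(bv) == 0)
  rho <- if (undef) NA_real_ else cor(av, bv, method = "spearman")
  mse <- mean((av - bv)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(params$dynamic_range^2 / mse)
  ssim <- {
    s <- ssim_map(a, b, params)
    mean(s[m])
  }
  data.frame(mae = mae, spearman = rho, psnr = psnr, ssim = ssim,
             dice_low = dice_quartile(j_ref, j_pred, mask, "low"),
             dice_high = dice_quartile(j_ref, j_pred, mask, "high"),
             spearman_undefined = undef)
}

abs_log2 <- function(j) {
  x <- if (inherits(j, "jr_jacmap")) j$J$data else as_arr(j)
  abs(log2(pmax(x, .Machine$double.xmin)))
}

#' Dice overlap of Jacobian quartile regions
#'
#' Binary regions are the in-mask voxels below each map's own 25th
#' percentile (`"low"`) or above its own 75th percentile (`"high"`) of
#' Jacobian values; Dice = `2|A n B| / (|A| + |B|)`. Degenerate (constant)
#' maps give an empty region and Dice 0 with a warning.
#'
#' @inheritParams local_metrics
#' @param which `"low"` or `"high"` quartile region.
#' @return Scalar Dice coefficient in `[0, 1]`.
#' @export
dice_quartile <- function(j_ref, j_pred, mask, which = c("low", "high")) {
  which <- match.arg(which)
  m <- as_mask_arr(mask)
  if (sum(m) < 4) stop("mask too small for quartile regions")
  ja <- if (inherits(j_ref, "jr_jacmap")) j_ref$J$data else as_arr(j_ref)
  jb <- if (inherits(j_pred, "jr_jacmap")) j_pred$J$data else as_arr(j_pred)
  region <- function(x) {
    v <- x[m]
    q <- quantile(v, if (which == "low") 0.25 else 0.75, names = FALSE,
                  type = 7)
    if (which == "low") v < q else v > q
  }
  A <- region(ja)
  B <- region(jb)
  if (!any(A) || !any(B)) {
    warning("degenerate quartile region (constant map); Dice reported 0")
    return(0)
  }
  2 * sum(A & B) / (sum(A) + sum(B))
}

#' Whole-lung global Jacobian statistics
#'
#' Mean Jacobian and coefficient of variation over the lung mask
#' (population standard deviation).
#'
#' @param j A `jr_jacmap` or Jacobian `jr_volume`/array.
#' @param mask `jr_mask`.
#' @return A one-row `data.frame` with `j_mean`, `j_cv`.
#' @export
global_stats <- function(j, mask) {
  x <- if (inherits(j, "jr_jacmap")) j$J$data else as_arr(j)
  m <- as_mask_arr(mask)
  if (!any(m)) stop("empty mask")
  v <- x[m]
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  data.frame(j_mean = mu, j_cv = sd_pop / mu)
}

#' Regional volume change by ROI
#'
#' For each ROI of a partition of the lung, the volume change is
#' `dV_ROI = (J_mean_ROI - 1) * V_ROI` and is expressed as a percent of the
#' total lung volume change, `dV_ROI% = 100 dV_ROI / dV_L`. Because the
#' ROIs partition the mask, the percentages sum to exactly 100. Cases with
#' almost no total volume change (`|J_mean - 1| < 0.02`) are flagged as
#' excluded to avoid division by near-zero.
#'
#' @param j A `jr_jacmap` or Jacobian volume.
#' @param rois A `jr_labelmap` partitioning the mask.
#' @param mask `jr_mask`.
#' @return A `jr_roi_dv` list: `table` (data.frame roi, label, v_roi_mm3,
#'   j_mean_roi, dv_mm3, dv_pct), `dv_total_mm3`, `j_mean`, `excluded`.
#' @export
roi_volume_change <- function(j, rois, mask) {
  jm <- if (inherits(j, "jr_jacmap")) j$J else j
  x <- as_arr(jm)
  m <- as_mask_arr(mask)
  check_partition(rois, mask)
  voxvol <- prod(mask$spacing)
  labs <- sort(unique(rois$data[m]))
  rows <- lapply(labs, function(lb) {
    sel <- m & (rois$data == lb)
    v_roi <- sum(sel) * voxvol
    jmu <- mean(x[sel])
    data.frame(roi = lb, v_roi_mm3 = v_roi, j_mean_roi = jmu,
               dv_mm3 = (jmu - 1) * v_roi)
  })
  tab <- do.call(rbind, rows)
  lt <- rois$label_table
  tab$label <- if (!is.null(lt)) names(lt)[match(tab$roi, lt)]
               else as.character(tab$roi)
  dv_total <- sum(tab$dv_mm3)
  jmu_all <- mean(x[m])
  excluded <- abs(jmu_all - 1) < 0.02
  tab$dv_pct <- if (dv_total != 0) 100 * tab$dv_mm3 / dv_total else NA_real_
  structure(list(table = tab, dv_total_mm3 = dv_total, j_mean = jmu_all,
                 excluded = excluded), class = "jr_roi_dv")
}

#' Parametric response mapping (PRM) classification
#'
#' Voxelwise two-threshold classification of spatially corresponding
#' paired-inflation HU values: emphysema if TLC < -950 and FRC < -856;
#' functional small-airways disease (fSAD) if TLC >= -950 and FRC < -856;
#' normal if FRC >= -856.
#'
#' @param i_frc_aligned HU `jr_volume` in (or aligned to) the TLC frame, or
#'   any frame in which the two volumes correspond voxelwise.
#' @param i_tlc HU `jr_volume` on the same grid.
#' @param mask `jr_mask` on the same grid.
#' @param frc_threshold,tlc_threshold HU thresholds (defaults -856, -950).
#' @return A `jr_labelmap` with labels 1 = normal, 2 = fSAD,
#'   3 = emphysema, partitioning the mask.
#' @export
prm_classify <- function(i_frc_aligned, i_tlc, mask,
                         frc_threshold = -856, tlc_threshold = -950) {
  same_grid(i_frc_aligned, i_tlc); same_grid(i_frc_aligned, mask)
  f <- as_arr(i_frc_aligned)
  t <- as_arr(i_tlc)
  m <- as_mask_arr(mask)
  lb <- array(0L, dim(f))
  lb[m] <- 1L                                   # normal: FRC >= -856
  fs <- m & (f < frc_threshold)
  lb[fs] <- 2L                                  # fSAD: FRC < -856
  lb[fs & (t < tlc_threshold)] <- 3L            # emphysema: both low
  roi_label_map(lb, c(normal = 1, fSAD = 2, emphysema = 3),
                mask$spacing, mask$origin)
}

#' Agreement summary: regression and Bland-Altman
#'
#' Ordinary least-squares regression of predicted on reference values
#' (slope, intercept, r^2) plus Bland-Altman mean difference and 95% limits
#' of agreement (mean +/- 1.96 population standard deviations), overall and
#' per group when `groups` is given.
#'
#' @param predicted,reference Numeric vectors (n >= 3).
#' @param groups Optional grouping labels for per-group Bland-Altman rows.
#' @return A `jr_agreement` list: `slope`, `intercept`, `r_squared`,
#'   `bland_altman` (data.frame group/mean_diff/lo/hi/n).
#' @export
agreement_summary <- function(predicted, reference, groups = NULL) {
  stopifnot(length(predicted) == length(reference),
            length(predicted) >= 3)
  if (sd(reference) == 0) stop("zero variance in reference")
  fit <- lm(predicted ~ reference)
  r2 <- cor(predicted, reference)^2
  ba_row <- function(idx, gname) {
    d <- predicted[idx] - reference[idx]
    mu <- mean(d)
    s <- sqrt(mean((d - mu)^2))
    data.frame(group = gname, mean_diff = mu, lo = mu - 1.96 * s,
               hi = mu + 1.96 * s, n = length(idx))
  }
  ba <- ba_row(seq_along(predicted), "all")
  if (!is.null(groups))
    for (g in unique(groups))
      ba <- rbind(ba, ba_row(which(groups == g), as.character(g)))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = unname(r2), bland_altman = ba,
                 n = length(predicted)), class = "jr_agreement")
}

#' @export
print.jr_agreement <- function(x, ...) {
  cat(sprintf("<jr_agreement> slope %.3f, intercept %.3f, r^2 %.3f, n=%d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Evaluate trained factorial arms on held-out cases
#'
#' For every test case and every arm: local/regional metrics and global
#' statistics of the predicted versus reference Jacobian; cohort-level
#' agreement summaries for the global Jacobian mean and the effort-corrected
#' lobar volume-change percentages.
#'
#' @param fact A `jr_factorial` from [run_factorial()] (or a named list of
#'   `jr_checkpoint`s plus `test_idx`).
#' @param cohort The full cohort list the factorial was run on.
#' @param prep_cfg A `jr_prep_config`.
#' @param include_controls Add per-case rows (arm `"control_frc"`) that feed
#'   the ground truth back through the metric pipeline; these must come out
#'   as the identity values and act as a pipeline control.
#' @return A `jr_metrics_report`: `per_case` (data.frame of metrics per
#'   case x arm), `agreement` (data.frame per arm: j_mean slope/r2 plus
#'   lobar and PRM dv_pct r2), `j_mean_pairs`, `dv_pairs`, `prm_pairs`
#'   (raw pairs for plotting).
#' @export
evaluate_cohort <- function(fact, cohort, prep_cfg = preprocess_config(),
                            include_controls = FALSE) {
  test_cases <- cohort[fact$test_idx]
  per_case <- list()
  jm_pairs <- list()
  dv_pairs <- list()
  prm_pairs <- list()
  lobe_tab <- c(left_upper = 1, left_lower = 2, right_upper = 3,
                right_lower = 4)
  prm_tab <- c(normal = 1, fSAD = 2, emphysema = 3)

  eval_one <- function(aid, ph, cs, pred) {
    mask_c <- unpad_volume(cs$mask, cs$pad)
    sp <- cs$spacing
    mref <- lung_mask(mask_c, sp)
    jref <- jacobian_map(volume3d(cs$j_ref, sp, kind = "jacobian"),
                         frame = cs$output_space, mask = mref)
    lm_row <- local_metrics(jref, pred, mref)
    gs_ref <- global_stats(jref, mref)
    gs_pred <- global_stats(pred, mref)
    rois <- roi_label_map(cs$lobes, lobe_tab, sp)
    dv_ref <- roi_volume_change(jref, rois, mref)
    dv_pred <- roi_volume_change(pred, rois, mref)
    per_case[[length(per_case) + 1L]] <<- cbind(
      data.frame(case_id = ph$case_id, arm = aid,
                 effort_true = ph$effort_true),
      lm_row,
      data.frame(j_mean_ref = gs_ref$j_mean, j_mean_pred = gs_pred$j_mean,
                 j_cv_ref = gs_ref$j_cv, j_cv_pred = gs_pred$j_cv,
                 excluded = dv_ref$excluded))
    jm_pairs[[length(jm_pairs) + 1L]] <<- data.frame(
      arm = aid, case_id = ph$case_id,
      predicted = gs_pred$j_mean, reference = gs_ref$j_mean)
    if (!dv_ref$excluded && !dv_pred$excluded)
      dv_pairs[[length(dv_pairs) + 1L]] <<- data.frame(
        arm = aid, case_id = ph$case_id, roi = dv_ref$table$label,
        predicted = dv_pred$table$dv_pct, reference = dv_ref$table$dv_pct)
    if (!is.null(cs$prm) && !dv_ref$excluded) {
      prois <- roi_label_map(cs$prm, prm_tab, sp)
      pv_ref <- roi_volume_change(jref, prois, mref)
      pv_pred <- roi_volume_change(pred, prois, mref)
      if (!pv_pred$excluded)
        prm_pairs[[length(prm_pairs) + 1L]] <<- data.frame(
          arm = aid, case_id = ph$case_id, roi = pv_ref$table$label,
          predicted = pv_pred$table$dv_pct,
          reference = pv_ref$table$dv_pct)
    }
  }

  for (aid in names(fact$checkpoints)) {
    ck <- fact$checkpoints[[aid]]
    arm <- ck$arm
    multiple <- 2L^(ck$net_cfg$L - 1L)
    for (ph in test_cases) {
      cs <- prepare_case(ph, output_space = arm$output_space,
                         paired = arm$input_factor == "paired",
                         cfg = prep_cfg, multiple = multiple)
      pred <- predict_jacobian(ck$net, cs, arm)
      eval_one(aid, ph, cs, pred)
    }
  }
  if (include_controls) {
    for (ph in test_cases) {
      cs <- prepare_case(ph, "FRC", paired = TRUE, cfg = prep_cfg,
                         multiple = 2L)
      ctrl <- jacobian_map(volume3d(cs$j_ref, cs$spacing,
                                    kind = "jacobian"),
                           frame = "FRC",
                           mask = lung_mask(unpad_volume(cs$mask, cs$pad),
                                            cs$spacing))
      eval_one("control_frc", ph, cs, ctrl)
    }
  }

  per_case <- do.call(rbind, per_case)
  jm_pairs <- do.call(rbind, jm_pairs)
  dv_pairs <- do.call(rbind, dv_pairs)
  prm_pairs <- do.call(rbind, prm_pairs)
  arm_ids <- unique(per_case$arm)
  pair_r2 <- function(df, aid) {
    sub <- if (is.null(df)) NULL else df[df$arm == aid, ]
    if (!is.null(sub) && nrow(sub) >= 3)
      agreement_summary(sub$predicted, sub$reference)$r_squared
    else NA_real_
  }
  agreement <- do.call(rbind, lapply(arm_ids, function(aid) {
    jp <- jm_pairs[jm_pairs$arm == aid, ]
    ag <- if (nrow(jp) >= 3) agreement_summary(jp$predicted, jp$reference)
          else list(slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_)
    data.frame(arm = aid, j_mean_slope = ag$slope,
               j_mean_intercept = ag$intercept, j_mean_r2 = ag$r_squared,
               dv_pct_r2 = pair_r2(dv_pairs, aid),
               dv_prm_r2 = pair_r2(prm_pairs, aid))
  }))
  structure(list(per_case = per_case, agreement = agreement,
                 j_mean_pairs = jm_pairs, dv_pairs = dv_pairs,
                 prm_pairs = prm_pairs,
                 metadata = list(
                   psnr_peak = "SSIM dynamic range (default 5)",
                   sd_convention = "population",
                   dice_thresholds = "per-map quartiles")),
            class = "jr_metrics_report")
}

#' @export
print.jr_metrics_report <- function(x, ...) {
  cat("<jr_metrics_report>\n")
  print(x$agreement, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to CSV/JSON files
#'
#' @param report A `jr_metrics_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_case, file.path(dir, "per_case_metrics.csv"),
            row.names = FALSE)
  write.csv(report$agreement, file.path(dir, "agreement_summary.csv"),
            row.names = FALSE)
  write.csv(report$j_mean_pairs, file.path(dir, "j_mean_pairs.csv"),
            row.names = FALSE)
  if (!is.null(report$dv_pairs))
    write.csv(report$dv_pairs, file.path(dir, "dv_pct_pairs.csv"),
              row.names = FALSE)
  if (!is.null(report$prm_pairs))
    write.csv(report$prm_pairs, file.path(dir, "dv_pct_prm_pairs.csv"),
              row.names = FALSE)
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
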