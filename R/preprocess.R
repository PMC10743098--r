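#' Preprocessing configuration
#'
#' Defaults follow the standard paired-inflation CT pipeline: anti-alias
#' Gaussian smoothing, resampling to 3 mm isotropic voxels, cropping to the
#' union lung bounding box, masking with background air, clamping HU to
#' `[-1024, 200]` and affine rescaling to `[-1, 1]`.
#'
#' @param target_spacing Isotropic target voxel size in mm.
#' @param clamp_lo,clamp_hi HU clamping interval.
#' @param rescale_lo,rescale_hi Normalized output interval.
#' @param background_hu HU value assigned outside the lung mask.
#' @param smooth_factor Anti-alias sigma as a fraction of the per-axis
#'   downsampling ratio (in input voxels); smoothing is skipped when the
#'   ratio is <= 1 (upsampling).
#' @return A `jr_prep_config` list.
#' @export
preprocess_config <- function(target_spacing = 3, clamp_lo = -1024,
                              clamp_hi = 200, rescale_lo = -1,
                              rescale_hi = 1, background_hu = -1024,
                              smooth_factor = 0.5) {
  stopifnot(clamp_lo < clamp_hi, rescale_lo < rescale_hi, target_spacing > 0)
  structure(list(target_spacing = target_spacing, clamp_lo = clamp_lo,
                 clamp_hi = clamp_hi, rescale_lo = rescale_lo,
                 rescale_hi = rescale_hi, background_hu = background_hu,
                 smooth_factor = smooth_factor), class = "jr_prep_config")
}

# --- separable filtering ----------------------------------------------------

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# banded filter matrix; border rows renormalized so constants are preserved
axis_filter_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[o + r + 1L]
  }
  K / rowSums(K)
}

# separable filtering along the three axes of a 3D array; transpose = TRUE
# applies the adjoint (transposed per-axis matrices)
filter3_separable <- function(x, kernels, transpose = FALSE) {
  d <- dim(x)
  if (length(kernels) == 1L) kernels <- rep(kernels, 3L)
  amat <- function(n, kern) {
    K <- axis_filter_matrix(n, kern)
    if (transpose) t(K) else K
  }
  if (length(kernels[[1]]) > 1)
    x <- array(amat(d[1], kernels[[1]]) %*%
                 matrix(x, d[1], d[2] * d[3]), dim = d)
  if (length(kernels[[2]]) > 1) {
    xp <- aperm(x, c(2, 1, 3))
    xp <- array(amat(d[2], kernels[[2]]) %*%
                  matrix(xp, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    x <- aperm(xp, c(2, 1, 3))
  }
  if (length(kernels[[3]]) > 1) {
    xp <- aperm(x, c(3, 2, 1))
    xp <- array(amat(d[3], kernels[[3]]) %*%
                  matrix(xp, d[3], d[2] * d[1]), dim = c(d[3], d[2], d[1]))
    x <- aperm(xp, c(3, 2, 1))
  }
  x
}

gaussian_smooth <- function(x, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  filter3_separable(x, lapply(sigma_vox, gauss_kernel1d))
}

# --- interpolation ----------------------------------------------------------

# trilinear interpolation of a 3D array at physical points (mm);
# continuous indices are clamped to the grid (edge extension)
interp_trilinear <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  ci <- sweep(sweep(pts, 2, origin), 2, spacing, "/")
  for (ax in 1:3) ci[, ax] <- pmin(pmax(ci[, ax], 0), d[ax] - 1)
  i0 <- floor(ci)
  fr <- ci - i0
  i0 <- i0 + 1L  # 1-based corner
  i1 <- pmin(i0 + 1L, matrix(d, nrow(ci), 3, byrow = TRUE))
  gather <- function(a, b, c) arr[cbind(a, b, c)]
  v000 <- gather(i0[, 1], i0[, 2], i0[, 3]); v100 <- gather(i1[, 1], i0[, 2], i0[, 3])
  v010 <- gather(i0[, 1], i1[, 2], i0[, 3]); v110 <- gather(i1[, 1], i1[, 2], i0[, 3])
  v001 <- gather(i0[, 1], i0[, 2], i1[, 3]); v101 <- gather(i1[, 1], i0[, 2], i1[, 3])
  v011 <- gather(i0[, 1], i1[, 2], i1[, 3]); v111 <- gather(i1[, 1], i1[, 2], i1[, 3])
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  (((v000 * (1 - fx) + v100 * fx) * (1 - fy) +
    (v010 * (1 - fx) + v110 * fx) * fy) * (1 - fz) +
   ((v001 * (1 - fx) + v101 * fx) * (1 - fy) +
    (v011 * (1 - fx) + v111 * fx) * fy) * fz)
}

interp_nearest <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  ci <- sweep(sweep(pts, 2, origin), 2, spacing, "/")
  for (ax in 1:3) ci[, ax] <- pmin(pmax(ci[, ax], 0), d[ax] - 1)
  i <- round(ci) + 1L
  arr[cbind(i[, 1], i[, 2], i[, 3])]
}

#' Resample a volume to isotropic spacing
#'
#' Intensity volumes are Gaussian smoothed (anti-aliasing, sigma =
#' `smooth_factor * downsample ratio` voxels per axis, skipped when
#' upsampling) and then trilinearly interpolated; masks and label maps are
#' nearest-neighbor interpolated with no smoothing. The output grid keeps
#' the input origin and has `ceil(extent / target_spacing)` voxels per axis.
#'
#' @param v A `jr_volume` (or `jr_mask` / `jr_labelmap`).
#' @param cfg A `jr_prep_config`.
#' @param interpolation `"linear"` or `"nearest"`; defaults to `"nearest"`
#'   for masks/labels and `"linear"` otherwise.
#' @return Resampled object of the same class.
#' @export
resample_isotropic <- function(v, cfg = preprocess_config(),
                               interpolation = NULL) {
  if (is.null(interpolation))
    interpolation <- if (v$kind == "label") "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  t <- cfg$target_spacing
  d <- dim(v$data)
  ratio <- t / v$spacing
  out_shape <- as.integer(ceiling(d * v$spacing / t))
  arr <- v$data
  if (interpolation == "linear" && any(ratio > 1)) {
    sig <- ifelse(ratio > 1, cfg$smooth_factor * ratio, 0)
    arr <- gaussian_smooth(arr, sig)
  }
  gout <- grid3d(out_shape, t, v$origin)
  pts <- grid_points(gout)
  vals <- if (interpolation == "linear")
    interp_trilinear(arr, v$spacing, v$origin, pts)
  else
    interp_nearest(arr, v$spacing, v$origin, pts)
  out <- v
  out$data <- array(vals, dim = out_shape)
  out$spacing <- rep(t, 3)
  out
}

#' Crop, mask and normalize a paired-inflation case
#'
#' Both images are cropped to the union bounding box of the two masks,
#' out-of-mask voxels are set to `background_hu`, intensities are clamped to
#' `[clamp_lo, clamp_hi]` and affinely rescaled so that `clamp_lo` maps to
#' `rescale_lo` and `clamp_hi` to `rescale_hi`.
#'
#' @param i_frc,i_tlc HU `jr_volume`s on a shared grid.
#' @param m_frc,m_tlc `jr_mask`s on the same grid.
#' @param cfg A `jr_prep_config`.
#' @return List with normalized `i_frc`, `i_tlc`, cropped `m_frc`, `m_tlc`,
#'   and the crop `box` (0-based half-open).
#' @export
crop_mask_normalize <- function(i_frc, i_tlc, m_frc, m_tlc,
                                cfg = preprocess_config()) {
  same_grid(i_frc, i_tlc); same_grid(i_frc, m_frc); same_grid(i_frc, m_tlc)
  box <- bounding_box_union(m_frc, m_tlc)
  norm1 <- function(iv, mv) {
    iv <- crop_to_box(iv, box)
    mv2 <- crop_to_box(mv, box)
    x <- iv$data
    x[mv2$data != 1] <- cfg$background_hu
    x <- pmin(pmax(x, cfg$clamp_lo), cfg$clamp_hi)
    x <- cfg$rescale_lo + (x - cfg$clamp_lo) / (cfg$clamp_hi - cfg$clamp_lo) *
      (cfg$rescale_hi - cfg$rescale_lo)
    iv$data <- x
    iv$kind <- "normalized"
    list(i = iv, m = mv2)
  }
  a <- norm1(i_frc, m_frc)
  b <- norm1(i_tlc, m_tlc)
  list(i_frc = a$i, i_tlc = b$i, m_frc = a$m, m_tlc = b$m, box = box)
}

#' Pad a volume so every extent is divisible by a multiple
#'
#' Symmetric constant padding (default fill -1, the normalized background).
#' The pad amounts are recorded in the `"pad"` attribute for exact inversion
#' with [unpad_volume()].
#'
#' @param v A `jr_volume` or plain 3D array.
#' @param multiple Required divisor of each spatial extent.
#' @param fill Fill value.
#' @return Padded object of the same type; `attr(, "pad")` holds `lo`/`hi`.
#' @export
pad_to_multiple <- function(v, multiple, fill = -1) {
  arr <- if (inherits(v, "jr_volume")) v$data else v
  d <- dim(arr)
  tgt <- as.integer(ceiling(d / multiple) * multiple)
  pad <- tgt - d
  lo <- pad %/% 2L
  hi <- pad - lo
  out <- array(fill, dim = tgt)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
  res <- if (inherits(v, "jr_volume")) {
    v2 <- v
    v2$data <- out
    v2$origin <- v$origin - lo * v$spacing
    v2
  } else out
  attr(res, "pad") <- list(lo = lo, hi = hi)
  res
}

#' @rdname pad_to_multiple
#' @param pad The pad record from `attr(padded, "pad")`.
#' @export
unpad_volume <- function(v, pad) {
  arr <- if (inherits(v, "jr_volume")) v$data else v
  d <- dim(arr)
  sl <- lapply(1:3, function(ax)
    seq.int(pad$lo[ax] + 1L, d[ax] - pad$hi[ax]))
  out <- arr[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  if (inherits(v, "jr_volume")) {
    v2 <- v
    v2$data <- out
    v2$origin <- v$origin + pad$lo * v$spacing
    attr(v2, "pad") <- NULL
    return(v2)
  }
  out
}

#' Prepare a phantom case for network training or prediction
#'
#' Runs the full chain on one phantom: resample to the target spacing (a
#' no-op at native phantom resolution), crop to the union mask bounding box,
#' mask + clamp + rescale intensities, pad to the network's divisibility
#' requirement, and assemble input channels and the log2-Jacobian target for
#' the requested study arm.
#'
#' @param ph A `jr_phantom`.
#' @param output_space `"FRC"` or `"TLC"`: the frame the Jacobian target
#'   lives in.
#' @param paired If TRUE, both normalized images form two input channels
#'   (FRC first); if FALSE only the image matching the output space is used.
#' @param cfg A `jr_prep_config`.
#' @param multiple Pad extents to this divisor (use `2^(L-1)` of the
#'   network).
#' @return List with `x` (D x H x W x C input array), `y` (target log2
#'   Jacobian, 0 outside the mask), `mask` (0/1 array), `j_ref` (reference
#'   Jacobian array), `lobes` (ROI label array), `box`, `pad`, `spacing`,
#'   `case_id`, `effort_true`, `output_space`, `paired`.
#' @export
prepare_case <- function(ph, output_space = c("FRC", "TLC"), paired = TRUE,
                         cfg = preprocess_config(), multiple = 8L) {
  output_space <- match.arg(output_space)
  rs <- function(v, interp = NULL) {
    if (max(abs(v$spacing - cfg$target_spacing)) < 1e-9) v
    else resample_isotropic(v, cfg, interp)
  }
  i_frc <- rs(ph$I_FRC); i_tlc <- rs(ph$I_TLC)
  m_frc <- rs(ph$M_FRC); m_tlc <- rs(ph$M_TLC)
  cn <- crop_mask_normalize(i_frc, i_tlc, m_frc, m_tlc, cfg)

  jmap <- if (output_space == "FRC") ph$J_FRC else ph$J_TLC
  mref <- if (output_space == "FRC") cn$m_frc else cn$m_tlc
  jv <- crop_to_box(rs(jmap$J), cn$box)
  lobes <- crop_to_box(rs(ph$lobes[[output_space]]), cn$box)
  prm <- if (!is.null(ph$prm))
    crop_to_box(rs(ph$prm[[output_space]]), cn$box)

  mask_arr <- mref$data
  y <- array(0, dim(mask_arr))
  inm <- mask_arr == 1
  y[inm] <- log2(pmax(jv$data[inm], .Machine$double.xmin))

  fill <- cfg$rescale_lo
  chans <- if (paired) list(cn$i_frc$data, cn$i_tlc$data)
           else list(if (output_space == "FRC") cn$i_frc$data else cn$i_tlc$data)
  xp <- lapply(chans, pad_to_multiple, multiple = multiple, fill = fill)
  pad <- attr(xp[[1]], "pad")
  x <- array(0, dim = c(dim(xp[[1]]), length(xp)))
  for (ci in seq_along(xp)) x[, , , ci] <- xp[[ci]]
  yp <- pad_to_multiple(y, multiple, fill = 0)
  mp <- pad_to_multiple(mask_arr, multiple, fill = 0)

  list(x = x, y = unclass_arr(yp), mask = unclass_arr(mp),
       j_ref = jv$data, lobes = lobes$data,
       prm = if (!is.null(prm)) prm$data, box = cn$box, pad = pad,
       spacing = rep(cfg$target_spacing, 3), case_id = ph$case_id,
       effort_true = ph$effort_true, output_space = output_space,
       paired = paired)
}

unclass_arr <- function(x) {
  attr(x, "pad") <- NULL
  x
}
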