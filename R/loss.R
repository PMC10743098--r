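#' SSIM parameters
#'
#' Local structural-similarity statistics are computed with a Gaussian
#' window truncated to `patch_size^3` voxels; window weights are
#' renormalized where the patch is clipped by the volume border, so
#' constant images keep exactly constant local statistics everywhere.
#' `C1 = (K1 * dynamic_range)^2`, `C2 = (K2 * dynamic_range)^2`.
#'
#' @param patch_size Odd patch edge length (default 7).
#' @param gaussian_sigma Window sigma in voxels (default 1.5).
#' @param dynamic_range Assumed dynamic range of the inputs (default 5,
#'   suited to the log2-Jacobian scale).
#' @param K1,K2 Stability constants (defaults 0.01, 0.03).
#' @return A `jr_ssim_params` list with derived `C1`, `C2`.
#' @export
ssim_params <- function(patch_size = 7L, gaussian_sigma = 1.5,
                        dynamic_range = 5, K1 = 0.01, K2 = 0.03) {
  stopifnot(patch_size %% 2 == 1, patch_size >= 1)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  stopifnot(C1 > 0, C2 > 0)
  structure(list(patch_size = as.integer(patch_size),
                 gaussian_sigma = gaussian_sigma,
                 dynamic_range = dynamic_range, K1 = K1, K2 = K2,
                 C1 = C1, C2 = C2), class = "jr_ssim_params")
}

#' Loss configuration
#'
#' Total loss `alpha * MAE + (1 - alpha) * SSIM-loss`.
#' @param alpha Mixing weight in \code{[0, 1]} (default 0.5).
#' @param ssim A `jr_ssim_params`.
#' @return A `jr_loss_config`.
#' @export
loss_config <- function(alpha = 0.5, ssim = ssim_params()) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha, ssim = ssim), class = "jr_loss_config")
}

ssim_window <- function(p) {
  r <- (p$patch_size - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * p$gaussian_sigma^2))
  k / sum(k)
}

as_arr <- function(x) if (inherits(x, "jr_volume")) x$data else x
as_mask_arr <- function(m) {
  a <- as_arr(x = m)
  a == 1
}

#' Mean absolute error over the lung mask
#'
#' @param Y,Yhat log2-Jacobian volumes (`jr_volume` or arrays of equal
#'   shape).
#' @param mask `jr_mask` or 0/1 array; the loss is averaged over in-mask
#'   voxels only.
#' @return Scalar loss.
#' @export
loss_mae <- function(Y, Yhat, mask) {
  y <- as_arr(Y); yh <- as_arr(Yhat); m <- as_mask_arr(mask)
  if (!identical(dim(y), dim(yh))) stop("shape mismatch")
  if (!any(m)) stop("empty mask")
  mean(abs(y[m] - yh[m]))
}

loss_mae_grad <- function(Y, Yhat, mask) {
  y <- as_arr(Y); yh <- as_arr(Yhat); m <- as_mask_arr(mask)
  n <- sum(m)
  g <- array(0, dim(y))
  g[m] <- sign(yh[m] - y[m]) / n
  list(value = mean(abs(y[m] - yh[m])), grad = g)
}

# local first and second moments with a renormalized Gaussian window
ssim_stats <- function(a, b, p) {
  w <- ssim_window(p)
  kern <- list(w, w, w)
  F <- function(x) filter3_separable(x, kern)
  list(mu_a = F(a), mu_b = F(b), e_aa = F(a * a), e_bb = F(b * b),
       e_ab = F(a * b))
}

#' Per-voxel SSIM map
#'
#' Structural similarity between two volumes from Gaussian-weighted local
#' means, variances and covariance. Symmetric in its arguments; values are
#' at most 1, with 1 exactly where the local structure is identical.
#'
#' @param Y,Yhat Volumes (`jr_volume` or arrays of equal shape).
#' @param params A `jr_ssim_params`.
#' @return Array of per-voxel SSIM values (same shape as the input).
#' @export
ssim_map <- function(Y, Yhat, params = ssim_params()) {
  a <- as_arr(Y); b <- as_arr(Yhat)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  st <- ssim_stats(a, b, params)
  va <- st$e_aa - st$mu_a^2
  vb <- st$e_bb - st$mu_b^2
  cab <- st$e_ab - st$mu_a * st$mu_b
  A1 <- 2 * st$mu_a * st$mu_b + params$C1
  A2 <- 2 * cab + params$C2
  B1 <- st$mu_a^2 + st$mu_b^2 + params$C1
  B2 <- va + vb + params$C2
  (A1 * A2) / (B1 * B2)
}

#' SSIM loss over the lung mask
#'
#' Mean of `1 - SSIM` over in-mask voxels. The SSIM map is computed over
#' the full volume (patches near the mask edge see the background) and the
#' average is restricted to the mask.
#'
#' @inheritParams loss_mae
#' @param params A `jr_ssim_params`.
#' @return Scalar loss in `[0, 2]`.
#' @export
loss_ssim <- function(Y, Yhat, mask, params = ssim_params()) {
  m <- as_mask_arr(mask)
  if (!any(m)) stop("empty mask")
  s <- ssim_map(Y, Yhat, params)
  mean(1 - s[m])
}

# value + gradient w.r.t. Yhat of the masked SSIM loss.
# With E[.] the renormalized Gaussian filter, S depends on b through
# e1 = E[b], e2 = E[b^2], e3 = E[ab]; the adjoint of the (row-normalized)
# separable filter is the transposed filter applied per axis.
loss_ssim_grad <- function(Y, Yhat, mask, params = ssim_params()) {
  a <- as_arr(Y); b <- as_arr(Yhat); m <- as_mask_arr(mask)
  n <- sum(m)
  if (n == 0) stop("empty mask")
  w <- ssim_window(params)
  kern <- list(w, w, w)
  F <- function(x) filter3_separable(x, kern)
  Ft <- function(x) filter3_separable(x, kern, transpose = TRUE)

  mu_a <- F(a); mu_b <- F(b)
  e_bb <- F(b * b); e_ab <- F(a * b); e_aa <- F(a * a)
  va <- e_aa - mu_a^2
  vb <- e_bb - mu_b^2
  cab <- e_ab - mu_a * mu_b
  A1 <- 2 * mu_a * mu_b + params$C1
  A2 <- 2 * cab + params$C2
  B1 <- mu_a^2 + mu_b^2 + params$C1
  B2 <- va + vb + params$C2
  S <- (A1 * A2) / (B1 * B2)

  # dL/dS = -1/n on the mask
  c0 <- array(0, dim(a))
  c0[m] <- -1 / n

  dS_dmu_b <- (2 * mu_a * A2) / (B1 * B2) - S * (2 * mu_b) / B1
  dS_dvb <- -S / B2
  dS_dcab <- 2 * A1 / (B1 * B2)
  # through e1 = E[b]: vb depends via -2 mu_b, cab via -mu_a
  dL_de1 <- c0 * (dS_dmu_b + dS_dvb * (-2 * mu_b) + dS_dcab * (-mu_a))
  dL_de2 <- c0 * dS_dvb
  dL_de3 <- c0 * dS_dcab

  grad <- Ft(dL_de1) + 2 * b * Ft(dL_de2) + a * Ft(dL_de3)
  list(value = mean(1 - S[m]), grad = grad)
}

#' Composite training loss
#'
#' `alpha * MAE + (1 - alpha) * SSIM-loss`, both restricted to the mask.
#' Zero exactly when prediction and target agree in-mask (for any alpha).
#'
#' @inheritParams loss_mae
#' @param cfg A `jr_loss_config`.
#' @return Scalar loss.
#' @export
loss_total <- function(Y, Yhat, mask, cfg = loss_config()) {
  al <- cfg$alpha
  v <- 0
  if (al > 0) v <- v + al * loss_mae(Y, Yhat, mask)
  if (al < 1) v <- v + (1 - al) * loss_ssim(Y, Yhat, mask, cfg$ssim)
  v
}

loss_total_grad <- function(Y, Yhat, mask, cfg = loss_config()) {
  al <- cfg$alpha
  v <- 0
  g <- 0
  if (al > 0) {
    mg <- loss_mae_grad(Y, Yhat, mask)
    v <- v + al * mg$value
    g <- g + al * mg$grad
  }
  if (al < 1) {
    sg <- loss_ssim_grad(Y, Yhat, mask, cfg$ssim)
    v <- v + (1 - al) * sg$value
    g <- g + (1 - al) * sg$grad
  }
  list(value = v, grad = g)
}
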