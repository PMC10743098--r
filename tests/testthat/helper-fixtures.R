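# Shared fixtures, built in code at test time.

tiny_volume <- function(shape = c(8, 8, 8), spacing = 3, value = NULL,
                        kind = "HU", seed = 1) {
  data <- if (is.null(value)) {
    set.seed(seed)
    array(rnorm(prod(shape), -500, 200), dim = shape)
  } else array(value, dim = shape)
  volume3d(data, spacing = spacing, kind = kind)
}

slab_mask <- function(shape = c(10, 10, 10), from = 3, to = 6, spacing = 3) {
  m <- array(0, dim = shape)
  m[from:to, from:to, from:to] <- 1
  lung_mask(m, spacing = spacing)
}

# noiseless phantom for identity-sensitive checks
clean_phantom <- function(seed = 1, ...) {
  simulate_phantom(noise_sd_frc = 0, noise_sd_tlc = 0, seed = seed, ...)
}

# brute-force SSIM oracle: per-voxel clipped patch, renormalized Gaussian
# weights, weighted moments — independent of the filter-based implementation
ssim_bruteforce <- function(a, b, p = ssim_params()) {
  d <- dim(a)
  r <- (p$patch_size - 1) %/% 2
  k1 <- exp(-(seq(-r, r))^2 / (2 * p$gaussian_sigma^2))
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- max(1, i - r):min(d[1], i + r)
    jj <- max(1, j - r):min(d[2], j + r)
    kk <- max(1, k - r):min(d[3], k + r)
    w <- outer(outer(k1[ii - i + r + 1], k1[jj - j + r + 1]),
               k1[kk - k + r + 1])
    w <- w / sum(w)
    pa <- a[ii, jj, kk]
    pb <- b[ii, jj, kk]
    mua <- sum(w * pa); mub <- sum(w * pb)
    va <- sum(w * pa^2) - mua^2
    vb <- sum(w * pb^2) - mub^2
    cab <- sum(w * pa * pb) - mua * mub
    out[i, j, k] <- ((2 * mua * mub + p$C1) * (2 * cab + p$C2)) /
      ((mua^2 + mub^2 + p$C1) * (va + vb + p$C2))
  }
  out
}
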