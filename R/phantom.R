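#' Simulate a paired-inflation lung phantom
#'
#' Builds a two-lung ellipsoidal phantom with known analytic ground truth,
#' emulating the statistical structure of paired inspiratory/expiratory CT:
#'
#' * The FRC-to-TLC deformation is a composition of localized radial
#'   contraction bumps (low-distensibility "trapped" pockets), a separable
#'   sinusoidal heterogeneity field, and a global affine inflation whose
#'   magnitude is set by the latent effort. The Jacobian is exact (closed
#'   form) in both frames.
#' * FRC intensities follow a tissue-fraction model,
#'   `HU = -1000 * airfrac + 40 * (1 - airfrac)`, with air fraction textured
#'   by the (effort-independent) heterogeneity pattern and raised inside
#'   disease pockets, so regional distensibility is visible in a single
#'   image while the global effort is not.
#' * TLC intensities are derived on their own frame through tissue-mass
#'   conservation: `I_TLC(h(x)) + 1000 = (I_FRC(x) + 1000) / J_FRC(x)`,
#'   sampling through the analytic inverse deformation.
#' * Independent Gaussian HU noise is added per frame after the coupling,
#'   with the FRC scan noisier (emulating low-dose expiratory acquisition).
#'
#' The latent effort is the drive of healthy parenchyma; the achieved
#' whole-lung mean Jacobian (recorded as `effort_true`) falls below the
#' drive as the disease fraction grows, mirroring severity trends.
#'
#' @param shape Grid voxel counts (length 3 or scalar), default 32.
#' @param spacing Isotropic voxel size in mm, default 3.
#' @param effort Target healthy-tissue inflation ratio TLC/FRC (> 1; 1 =
#'   no inflation).
#' @param heterogeneity Amplitude of the sinusoidal Jacobian modulation
#'   (dimensionless, < 1).
#' @param disease_fraction Fraction of lung volume assigned to
#'   low-distensibility pockets, in [0, 1).
#' @param air_fraction_range Baseline FRC air-fraction range of normal
#'   parenchyma.
#' @param noise_sd_frc,noise_sd_tlc Additive HU noise standard deviations.
#' @param seed Random seed (integer).
#' @param case_id Optional case identifier string.
#' @return A `jr_phantom` list: `I_FRC`, `I_TLC` (`jr_volume`, HU), `M_FRC`,
#'   `M_TLC` (`jr_mask`), `lobes` (list of `jr_labelmap` per frame),
#'   `J_FRC`, `J_TLC` (`jr_jacmap`), `h` and `h_inv` (`jr_deform`),
#'   `effort_true`, `effort_drive`, `severity`, `params`, `case_id`.
#' @export
simulate_phantom <- function(shape = c(32, 32, 32), spacing = 3,
                             effort = 1.6, heterogeneity = 0.25,
                             disease_fraction = 0.15,
                             air_fraction_range = c(0.70, 0.82),
                             noise_sd_frc = 30, noise_sd_tlc = 15,
                             seed = 1L, case_id = NULL) {
  stopifnot(effort >= 1, heterogeneity >= 0, heterogeneity < 1,
            disease_fraction >= 0, disease_fraction < 1,
            noise_sd_frc >= 0, noise_sd_tlc >= 0)
  g <- grid3d(shape, spacing)
  extent <- g$shape * g$spacing
  ctr <- g$origin + (g$shape - 1) * g$spacing / 2

  with_seed(seed, {
    # --- lung support: two ellipsoids with per-case anatomical variation.
    # Subjects differ in lung size/shape, so absolute lung size in a single
    # image must not reveal the inflation effort (size = anatomy x effort).
    anat <- runif(1, 0.85, 1.05) * runif(3, 0.96, 1.04)
    offs <- 0.18 * extent[1] * anat[1]
    semi <- c(0.14, 0.24, 0.26) * extent * anat
    lung_centers <- rbind(ctr + c(-offs, 0, 0), ctr + c(offs, 0, 0))

    # --- heterogeneity: separable sinusoid, effort-independent -----------
    # per-axis modulation depths a_i * k_i summing to `heterogeneity`
    k <- 2 * pi / (extent * runif(3, 0.85, 1.15))
    phase <- runif(3, 0, 2 * pi)
    depth <- heterogeneity * c(0.45, 0.33, 0.22)
    sin_def <- deform_sinusoid(amplitude = depth / k, freq = k, phase = phase)

    # --- disease pockets -------------------------------------------------
    v_lung <- 2 * (4 / 3) * pi * prod(semi)
    pockets <- sample_pockets(disease_fraction, v_lung, lung_centers, semi)

    # healthy-drive affine scale: compensate the sinusoid mean so healthy
    # tissue inflates by `effort` on average
    probe <- grid_points(g)
    in_probe <- in_lung(probe, lung_centers, semi)
    js_probe <- deform_jacobian(sin_def, probe[in_probe, , drop = FALSE])
    drive_det <- effort / mean(js_probe)
    s_axis <- drive_det^(1 / 3)
    aff <- deform_affine(rep(s_axis, 3), ctr)

    # pocket bumps cancel the local drive: J ~ 1 at pocket centers
    parts <- list()
    if (nrow(pockets) > 0) {
      epsb <- drive_det^(-1 / 3) - 1
      parts <- c(parts, list(deform_radial(pockets[, 1:3, drop = FALSE],
                                           eps = rep(epsb, nrow(pockets)),
                                           width = pockets[, "w"])))
    }
    parts <- c(parts, list(sin_def, aff))
    h <- deform_composite(parts)
    h_inv <- invert_analytic(h)

    # --- FRC frame -------------------------------------------------------
    pts <- probe
    m_frc <- in_probe
    j_frc_vals <- deform_jacobian(h, pts)
    ripple <- make_ripple()

    af_fun <- airfrac_function(sin_def, pockets, air_fraction_range, ripple)
    i_frc_clean <- hu_from_airfrac(af_fun(pts))
    i_frc_clean[!m_frc] <- 20  # soft-tissue body background

    # --- TLC frame (same grid) -------------------------------------------
    x_back <- deform_apply(h_inv, pts)
    m_tlc <- in_lung(x_back, lung_centers, semi)
    j_at_back <- deform_jacobian(h, x_back)
    i_tlc_clean <- rep(20, nrow(pts))
    if (any(m_tlc)) {
      xb <- x_back[m_tlc, , drop = FALSE]
      i_tlc_clean[m_tlc] <-
        (hu_from_airfrac(af_fun(xb)) + 1000) / j_at_back[m_tlc] - 1000
    }

    if (!any(m_frc) || !any(m_tlc)) stop("degenerate phantom: empty lung")

    # --- lobes: axial split of each lung (4 compartments) ----------------
    lobes_frc <- lobe_labels(pts, m_frc, lung_centers)
    lobes_tlc <- lobe_labels(x_back, m_tlc, lung_centers)

    # --- noise ------------------------------------------------------------
    n <- nrow(pts)
    i_frc <- i_frc_clean + if (noise_sd_frc > 0) rnorm(n, 0, noise_sd_frc) else 0
    i_tlc <- i_tlc_clean + if (noise_sd_tlc > 0) rnorm(n, 0, noise_sd_tlc) else 0
  })

  # PRM ground truth from the measured (noisy) images and the exact
  # correspondence: warp the opposite-frame image through h / h^-1
  shp0 <- g$shape
  i_frc_arr <- array(i_frc, dim = shp0)
  i_tlc_arr <- array(i_tlc, dim = shp0)
  itlc_at_h <- ifelse(m_frc,
                      interp_trilinear(i_tlc_arr, g$spacing, g$origin,
                                       deform_apply(h, pts)), -1000)
  ifrc_at_hinv <- ifelse(m_tlc,
                         interp_trilinear(i_frc_arr, g$spacing, g$origin,
                                          x_back), -1000)

  shp <- g$shape
  as_vol <- function(x, kind) volume3d(array(x, dim = shp), g$spacing,
                                       g$origin, kind = kind)
  mk_mask <- function(m) lung_mask(array(as.numeric(m), dim = shp),
                                   g$spacing, g$origin)
  lobe_tab <- c(left_upper = 1, left_lower = 2, right_upper = 3,
                right_lower = 4)
  mk_lobes <- function(lb) roi_label_map(array(lb, dim = shp), lobe_tab,
                                         g$spacing, g$origin)

  M_FRC <- mk_mask(m_frc)
  M_TLC <- mk_mask(m_tlc)
  J_FRC <- jacobian_map(as_vol(j_frc_vals, "jacobian"), frame = "FRC")
  J_TLC <- jacobian_map(as_vol(1 / j_at_back, "jacobian"), frame = "TLC")
  effort_true <- mean(j_frc_vals[m_frc])
  prm <- list(
    FRC = prm_classify(as_vol(i_frc, "HU"), as_vol(itlc_at_h, "HU"), M_FRC),
    TLC = prm_classify(as_vol(ifrc_at_hinv, "HU"), as_vol(i_tlc, "HU"),
                       M_TLC))

  structure(list(
    I_FRC = as_vol(i_frc, "HU"), I_TLC = as_vol(i_tlc, "HU"),
    M_FRC = M_FRC, M_TLC = M_TLC,
    lobes = list(FRC = mk_lobes(lobes_frc), TLC = mk_lobes(lobes_tlc)),
    prm = prm,
    J_FRC = J_FRC, J_TLC = J_TLC,
    h = h, h_inv = h_inv,
    effort_true = effort_true, effort_drive = effort,
    params = list(shape = g$shape, spacing = g$spacing, effort = effort,
                  heterogeneity = heterogeneity,
                  disease_fraction = disease_fraction,
                  air_fraction_range = air_fraction_range,
                  noise_sd_frc = noise_sd_frc, noise_sd_tlc = noise_sd_tlc,
                  seed = seed),
    case_id = if (is.null(case_id)) sprintf("case_seed%d", seed) else case_id
  ), class = "jr_phantom")
}

#' @export
print.jr_phantom <- function(x, ...) {
  cat(sprintf(
    "<jr_phantom %s> grid %s, effort drive %.2f, achieved TLC/FRC %.3f\n",
    x$case_id, paste(x$params$shape, collapse = "x"),
    x$effort_drive, x$effort_true))
  invisible(x)
}

# run expr with a local RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

in_lung <- function(pts, lung_centers, semi) {
  inside <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(lung_centers))) {
    d <- sweep(pts, 2, lung_centers[j, ])
    inside <- inside | (rowSums(sweep(d, 2, semi, "/")^2) <= 1)
  }
  inside
}

lobe_labels <- function(pts, inmask, lung_centers) {
  lb <- integer(nrow(pts))
  right <- pts[, 1] > mean(lung_centers[, 1])
  upper <- pts[, 3] > lung_centers[1, 3]
  lb[inmask] <- 1L + 2L * right[inmask] + !upper[inmask]
  lb
}

# pocket table: columns x, y, z, w (bump width), R (intensity radius), type
sample_pockets <- function(disease_fraction, v_lung, lung_centers, semi) {
  out <- matrix(numeric(0), ncol = 6,
                dimnames = list(NULL, c("x", "y", "z", "w", "R", "type")))
  if (disease_fraction <= 0) return(out)
  target <- disease_fraction * v_lung
  vol <- 0
  tries <- 0
  while (vol < target && tries < 500) {
    tries <- tries + 1
    lungi <- sample(nrow(lung_centers), 1)
    u <- runif(3, -0.75, 0.75)
    p <- lung_centers[lungi, ] + u * semi
    if (sum((u)^2 / 0.75^2) > 1) next   # stay inside the ellipsoid core
    w <- runif(1, 4, 8)
    R <- 1.5 * w
    if (nrow(out) > 0) {
      dd <- sqrt(rowSums(sweep(out[, 1:3, drop = FALSE], 2, p)^2))
      if (any(dd < 0.9 * (out[, "R"] + R))) next
    }
    type <- sample(c(1, 2), 1, prob = c(0.7, 0.3))  # 1 fSAD, 2 emphysema
    out <- rbind(out, c(p, w, R, type))
    vol <- vol + (4 / 3) * pi * R^3
  }
  out
}

# smooth analytic ripple texture: sum of random-phase plane waves
make_ripple <- function(n_waves = 3, amp = 0.008) {
  dirs <- matrix(rnorm(n_waves * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  kk <- 2 * pi / runif(n_waves, 30, 60)   # wavelengths 30-60 mm
  ph <- runif(n_waves, 0, 2 * pi)
  function(pts) {
    s <- 0
    for (q in seq_len(n_waves))
      s <- s + amp * cos(kk[q] * (pts %*% dirs[q, ]) + ph[q])
    as.numeric(s)
  }
}

# analytic FRC air-fraction field; effort-independent by construction
airfrac_function <- function(sin_def, pockets, af_range, ripple,
                             coupling = 0.35) {
  af_mid <- mean(af_range)
  af_pocket <- c(0.90, 0.97)  # fSAD, emphysema
  function(pts) {
    js <- deform_jacobian(sin_def, pts)
    af <- af_mid + coupling * (1 - js) + ripple(pts)
    if (nrow(pockets) > 0) {
      bump <- 0
      for (j in seq_len(nrow(pockets))) {
        d2 <- rowSums(sweep(pts, 2, pockets[j, 1:3])^2)
        m <- exp(-d2 / (2 * (0.7 * pockets[j, "R"])^2))
        bump <- pmax(bump, (af_pocket[pockets[j, "type"]] - af_mid) * m)
      }
      af <- af + bump
    }
    pmin(pmax(af, 0.30), 0.985)
  }
}

hu_from_airfrac <- function(af, tissue_hu = 40) {
  -1000 * af + tissue_hu * (1 - af)
}

#' Simulate a severity-stratified phantom cohort
#'
#' Cases are assigned round-robin to severity bins spanning `[0, 1]`; severity
#' maps linearly to decreasing effort and increasing disease fraction, so the
#' cohort reproduces the canonical trend of lower whole-lung mean Jacobian
#' with increasing disease severity. Deterministic given `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param effort_range Healthy-drive range, least to most (default
#'   `c(1.2, 2.2)`); severity 0 draws the top of the range.
#' @param disease_range Disease-fraction range across severity.
#' @param n_bins Number of severity bins (default `min(n, 7)`).
#' @param seed Cohort seed; per-case seeds are derived from it.
#' @param ... Further arguments passed to [simulate_phantom()]
#'   (grid shape, spacing, noise levels, ...).
#' @return List of `jr_phantom` objects with unique `case_id`s; each carries
#'   a `severity` and `severity_bin` element.
#' @export
simulate_cohort <- function(n, effort_range = c(1.2, 2.2),
                            disease_range = c(0, 0.25),
                            n_bins = NULL, seed = 1L, ...) {
  stopifnot(n >= 1)
  n_bins <- as.integer(if (is.null(n_bins)) min(n, 7L) else n_bins)
  bins <- ((seq_len(n) - 1L) %% n_bins) + 1L
  jit <- with_seed(seed, runif(n, 0.1, 0.9))
  sev <- (bins - 1L + jit) / n_bins
  lapply(seq_len(n), function(i) {
    ph <- simulate_phantom(
      effort = effort_range[2] - sev[i] * diff(effort_range),
      disease_fraction = disease_range[1] + sev[i] * diff(disease_range),
      seed = seed * 10000L + i,
      case_id = sprintf("case_%03d", i), ...)
    ph$severity <- sev[i]
    ph$severity_bin <- bins[i]
    ph
  })
}

#' Write a phantom case to a directory as NIfTI + manifest
#'
#' @param ph A `jr_phantom`.
#' @param dir Output directory (created if missing).
#' @return The case directory path, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  cdir <- file.path(dir, ph$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  write_volume(ph$I_FRC, file.path(cdir, "I_FRC.nii.gz"))
  write_volume(ph$I_TLC, file.path(cdir, "I_TLC.nii.gz"))
  write_volume(ph$M_FRC, file.path(cdir, "M_FRC.nii.gz"))
  write_volume(ph$M_TLC, file.path(cdir, "M_TLC.nii.gz"))
  write_volume(ph$lobes$FRC, file.path(cdir, "lobes_FRC.nii.gz"))
  write_volume(ph$lobes$TLC, file.path(cdir, "lobes_TLC.nii.gz"))
  write_volume(ph$prm$FRC, file.path(cdir, "prm_FRC.nii.gz"))
  write_volume(ph$prm$TLC, file.path(cdir, "prm_TLC.nii.gz"))
  write_volume(ph$J_FRC$J, file.path(cdir, "J_FRC.nii.gz"))
  write_volume(ph$J_TLC$J, file.path(cdir, "J_TLC.nii.gz"))
  jsonlite::write_json(
    list(case_id = ph$case_id, effort_true = ph$effort_true,
         effort_drive = ph$effort_drive, params = ph$params),
    file.path(cdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(cdir)
}
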