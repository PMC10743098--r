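---
title: "Direct regression of lung volume-change maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct regression of lung volume-change maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deformable image registration (DIR) of paired chest CT scans — one near full
inspiration (total lung capacity, TLC) and one near passive expiration
(functional residual capacity, FRC) — yields a displacement field whose
Jacobian determinant `J` measures local volume change: `J > 1` is expansion,
`J < 1` contraction. Registration is slow and needs two scans. `jacreg`
implements the alternative: a 3D convolutional network regresses the Jacobian
map directly from the CT images, either from the pair or from a single scan,
exploiting the empirical structure–function link between local intensity,
texture and tissue distensibility.

The package covers the whole experimental loop: a synthetic paired-inflation
phantom generator with exact analytic ground truth, the preprocessing chain,
the network and its composite loss, a 2x2 multifactorial training harness
(single vs. paired input x FRC vs. TLC output space), and a
local/regional/global evaluation suite.

## Geometry and the Jacobian

All volumes are axis-aligned scalar grids; voxel `(i, j, k)` (0-based) sits at
`origin + (i, j, k) * spacing` in mm. The transformation convention follows
registration practice: `h(x)` maps fixed-frame points into the moving frame,
and the Jacobian is reported in the fixed frame. For a displacement
parameterization `h(x) = x + u(x)`,

```
J(x) = det(I + du/dx),
```

with derivatives in physical units. `jacobian_determinant()` uses central
differences in the interior and first-order one-sided differences on the
outermost voxel layer. Central differences are exact for affine fields and
carry a truncation error `A k^3 h^2 / 6` for a sinusoidal displacement of
amplitude `A` (mm), frequency `k` (rad/mm) and grid step `h` (mm); the
one-sided boundary scheme is an order lower (`A k^2 h / 2`), which is why
boundary voxels are never included in oracle comparisons. Non-positive
determinants inside the lung mask indicate folding; they set a quality flag
and warn, but never raise: DIR outputs can fold and the pipeline must record
rather than crash.

Targets are trained in the log2 encoding `Y = log2 J`, so that reciprocal
volume ratios (a region doubling on inspiration vs. halving on expiration)
have equal magnitude and opposite sign, and predictions are decoded as
`J = 2^Y`, which is positive by construction.

## The phantom generator

`simulate_phantom()` builds the study conditions the training harness and the
evaluation suite assume. The design goals, in order:

1. **Exact ground truth.** The FRC-to-TLC deformation is a composition of
   closed-form families — localized radial contraction bumps, a separable
   sinusoid, and a global affine inflation — so `J` is analytic in both
   frames and the inverse is available by fixed-point iteration (tolerance
   1e-3 mm, at most 50 iterations).
2. **Mass-conserved intensities.** FRC intensities follow a tissue-fraction
   model, `HU = -1000 * airfrac + 40 * (1 - airfrac)`; TLC intensities are
   derived on their own grid through the sponge model
   `I_TLC(h(x)) + 1000 = (I_FRC(x) + 1000) / J_FRC(x)`, sampling the analytic
   fields through the inverse deformation. No numeric registration appears
   anywhere in the simulator. Noise is added after the coupling, so the
   conservation identity holds exactly only in the noiseless limit; tests use
   noiseless cases for the identity and noisy cases for training realism.
3. **Effort unidentifiable from one image.** The latent effort (the healthy
   tissue inflation drive, with whole-lung target ratios spanning 1.2-2.2
   across severity) enters only through the affine component, which leaves
   the FRC image untouched: two cases sharing a seed but differing in effort
   have bit-identical FRC images. Lung anatomy additionally varies per case
   (overall size factor U(0.85, 1.05) with mild per-axis asymmetry), so the
   absolute lung size in a TLC image is the product of anatomy and effort
   and cannot be inverted from one image either — without this, a fixed
   anatomy would hand the single-TLC arm an effort shortcut that real
   cohorts do not offer. This is the mechanism behind the single-input
   arms' weak global-mean performance.
4. **Regional pattern visible in one image.** The air-fraction texture is
   coupled to the (effort-independent) sinusoidal heterogeneity —
   `airfrac = base + 0.35 * (1 - J_sin) + ripple` — and disease pockets are
   both darker at FRC (air fraction 0.90 for trapped/fSAD-like pockets, 0.97
   for emphysema-like ones) and less distensible (radial bumps cancel the
   local drive so pocket `J` sits near 1). Darker therefore means less
   expansion, the gas-trapping signature. The coupling strength and the
   0.008-amplitude analytic ripple (a deliberate noise floor in the
   structure-function link) were fixed at design time so that the link is
   strong but not deterministic; the residual ripple plus the dose-dependent
   HU noise (30 HU at FRC vs. 15 HU at TLC, emulating 50 vs. 200 mAs
   acquisitions) keep the single-image task nontrivial.

What the phantom does **not** emulate: airway/vessel trees, lobar sliding,
scanner/reconstruction variation, and real anatomical shape variability. A
network that excels on phantoms has learned the intended intensity-mechanics
coupling, not radiology; passing tests here validate the pipeline's
correctness and the identifiability structure, nothing more.

`simulate_cohort()` stratifies severity into bins (default up to 7); severity
maps linearly to decreasing effort and increasing disease fraction
(0 to 0.25 of lung volume), reproducing the canonical decline of whole-lung
mean Jacobian with disease severity.

## Preprocessing

`crop_mask_normalize()` reproduces the standard chain: Gaussian anti-alias
smoothing (sigma = 0.5 x downsampling ratio in voxels, skipped when
upsampling — a standard half-ratio rule), resampling to 3 mm isotropic voxels
(masks nearest-neighbor, no smoothing), cropping to the union bounding box of
the two lung masks, masking to a -1024 HU background, clamping to
[-1024, 200] HU and affine rescaling to [-1, 1]. Masking precedes clamping,
so background is indistinguishable from air after normalization. How real
unregistered FRC/TLC pairs are brought onto one grid for channel
concatenation is under-determined in general; here both volumes are resampled
to the shared target spacing and cropped with the single union box (phantom
pairs share a grid by construction), and the crop box is recorded for
provenance. Ground-truth `Y` maps are set to 0 outside the lung; the loss is
mask-restricted anyway. `pad_to_multiple()` pads symmetrically with the
normalized background (-1) to meet the network's divisibility requirement and
records the pad for exact inversion of predictions.

## Network

`build_network()` implements a multiscale residual regression network with
`L` levels (default 4). A stem convolution lifts the input (1 or 2 channels)
to `C0 = 8` channels; level `l` carries `C_l = C0 * 2^l` channels through a
residual identity block (two 3x3x3 convolutions; normalization before the
residual addition, activation after), and levels are connected by residual
down blocks (stride-2 3x3x3 main path with instance norm, stride-2 1x1x1
projection shortcut, addition, then ReLU). Each identity-block output is
upconvolved to full resolution with `C0` filters (transposed convolution,
kernel = stride = `2^l`; a 1x1x1 convolution at level 0), the `C0 * L`
channels are concatenated, and two integration convolutions — a 3x3x3 with
norm/activation and a final linear 1x1x1 — produce the single-channel
log2-Jacobian map. All convolutions use He-normal initialization; instance
normalization uses epsilon 1e-5 with affine scale/shift. Kernel sizes, the
down-block internals and the upconvolution realization are declared choices
(the architecture family under-determines them); the final linear 1x1x1
makes the zero-weight case exactly `Y = 0`, i.e. a no-volume-change prior.

There is no deep-learning framework dependency: forward and backward passes
are implemented in the package (im2col GEMM convolutions in C++ via
RcppArmadillo, layer orchestration in R), and the analytic gradients are
tested against finite differences to relative error below 1e-5.

## Loss

The training loss is `alpha * MAE + (1 - alpha) * (1 - SSIM)` with
`alpha = 0.5`, both restricted to the lung mask. SSIM uses a 7^3 Gaussian
window (sigma 1.5), dynamic range 5 on the log2-Jacobian scale, and
`K1 = 0.01`, `K2 = 0.03`, so `C1 = 0.0025`, `C2 = 0.0225`. Two
implementation decisions matter numerically:

* Window weights are renormalized where the patch is clipped by the volume
  border, so local statistics of constant images are exact everywhere and
  the filter-based map equals a brute-force per-voxel patch computation to
  1e-6 (both are tested).
* The SSIM map is computed over the full padded volume and then averaged
  over the mask; patch support near the lung edge includes background
  voxels. The loss operates on signed `Y`; the magnitude `|log2 J|` appears
  only in evaluation metrics.

Optimization is Adam with the AMSGrad variant at learning rate 1e-4 (the
reference setting; the small-scale demonstrations use 1e-3 to converge
within their compute envelope). One global seed controls simulation, split,
initialization and batch order. A validation split (10% of the training
cases) selects the checkpoint; whether the original work used one is
unstated, so this is the package's own choice. Optional axis-flip
augmentation of (input, target, mask) triples is available for the
small-cohort regime, where it markedly narrows the train/validation gap; it
is off by default and never applied to validation cases.

## The multifactorial harness

`run_factorial()` trains the four arms {single, paired} x {FRC, TLC} with a
shared 90/10 train/test split and shared seeds. Single-input arms consume
only the image matching the output space. The expected ordering — the
mechanism the phantom is built to expose — is: paired arms recover the
global mean Jacobian (effort is identifiable from the pair), single arms do
not, yet single arms retain the regional pattern, so their effort-corrected
regional volume-change percentages remain strongly correlated with ground
truth.

## Evaluation

All local/regional metrics are computed on `|log2 J|` over the mask: MAE,
Spearman correlation (average ranks), PSNR (peak fixed to the SSIM dynamic
range 5 — the natural scale bound here; the report metadata records this
choice), masked mean SSIM, and Dice overlap of quartile regions. Quartile
thresholds are each map's own 25th/75th in-mask percentiles, which
guarantees equal-sized regions; deriving both regions from the reference
thresholds is the other defensible reading, and the choice is recorded in
the report metadata. Standard deviations are population (divide by n)
throughout, also recorded.

Regional volume change follows `dV_ROI = (J_mean_ROI - 1) * V_ROI`,
expressed as a percent of the total change; because ROIs partition the mask
the percentages sum to exactly 100 (an algebraic identity the tests assert
at 1e-6). Cases with `|J_mean - 1| < 0.02` are flagged and excluded from
percentage analyses to avoid dividing by a near-zero total. PRM
classification uses the standard thresholds (-856 HU at FRC, -950 HU at
TLC: emphysema if both below, fSAD if only FRC below, else normal) and on
phantoms uses the simulator's exact correspondence; for real data the caller
must supply pre-aligned volumes, since registration itself is out of scope.
Agreement summaries are OLS regressions (slope, intercept, r^2) plus
Bland-Altman mean difference and mean +/- 1.96 population SD limits, per
group where groups are given. For PRM-partitioned volume-change fractions
the pooled regression r^2 is dominated by the order-of-magnitude size
differences between classes and is reported for completeness only;
per-class Bland-Altman limits on the raw pairs are the informative summary
there. Cohort reports can also carry ground-truth-as-prediction control
rows, which must reproduce the identity values end to end and guard the
report pipeline itself.

## Problem sizes and numerical choices

The bundled demonstrations run at 24^3 voxels x 3 mm with reduced depth
(L = 3) and width (C0 = 4-8), cohorts of a dozen to a few dozen cases, and a
few hundred optimizer steps — sizes chosen so the full factorial loop runs
in minutes on one CPU core while still exposing the qualitative ordering of
the four arms. The package scales to the reference configuration (L = 4,
C0 = 8, 32^3 cohorts of hundreds of cases) through the same functions; at
that scale the paired-FRC arm's held-out voxelwise Spearman and global-mean
r^2 rise well above the demo values (the scaling is driven by training-set
size; the train/validation gap closes roughly monotonically with cohort
size). Degenerate inputs are handled explicitly: empty masks error, constant
maps flag Spearman as undefined and quartile Dice as degenerate, folding
flags rather than raises, and infinite PSNR (identical maps) is reported as
`Inf` rather than capped.

## Known limitations

* The phantom's two-ellipsoid anatomy and four-compartment "lobes" are
  deliberately schematic; fissure sliding and airway structures are absent.
* Single-device training only; no multi-GPU data parallelism.
* The network assumes axis-aligned geometry and isotropic spacing after
  preprocessing (the math does not, but the defaults do).
* Checkpoints serialize weights as JSON text: portable and diff-able, but
  not compact; at reference scale a binary format would be preferable.
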