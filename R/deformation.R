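#' Analytic deformation families
#'
#' Closed-form transformations `h(x)` of physical space (mm) with exact
#' Jacobian determinants, used as ground-truth generators for the phantom
#' simulator and as oracles for the numeric Jacobian operator. Three
#' families are provided plus sequential composition:
#'
#' * `deform_affine()`: `h(x) = center + S (x - center)` with diagonal scale
#'   `S`; Jacobian `prod(scale)` everywhere.
#' * `deform_sinusoid()`: separable per-axis displacement
#'   `h_i(x) = x_i + a_i sin(k_i x_i + p_i)`; Jacobian is the product of the
#'   1D factors `1 + a_i k_i cos(k_i x_i + p_i)`, positive when
#'   `|a_i k_i| < 1`.
#' * `deform_radial()`: localized radial bumps
#'   `h(x) = p + lambda(r) (x - p)` with
#'   `lambda(r) = 1 + eps exp(-r^2 / (2 w^2))`; Jacobian
#'   `lambda^2 (lambda + r lambda')`.
#'
#' @param scale Length-3 positive scale factors.
#' @param center Length-3 fixed point of the map (mm).
#' @return A `jr_deform` object.
#' @export
deform_affine <- function(scale = c(1, 1, 1), center = c(0, 0, 0)) {
  scale <- rep_len(as.numeric(scale), 3L)
  if (any(scale <= 0)) stop("affine scales must be positive")
  structure(list(family = "affine", scale = scale, center = as.numeric(center)),
            class = "jr_deform")
}

#' @rdname deform_affine
#' @param amplitude,freq,phase Length-3 per-axis sinusoid parameters
#'   (mm, rad/mm, rad). Requires `|amplitude * freq| < 1` per axis.
#' @export
deform_sinusoid <- function(amplitude = c(0, 0, 0), freq = c(0.1, 0.1, 0.1),
                            phase = c(0, 0, 0)) {
  amplitude <- rep_len(as.numeric(amplitude), 3L)
  freq <- rep_len(as.numeric(freq), 3L)
  phase <- rep_len(as.numeric(phase), 3L)
  if (any(abs(amplitude * freq) >= 1))
    stop("sinusoid parameters violate positivity: need |amplitude*freq| < 1")
  structure(list(family = "sinusoid", amplitude = amplitude, freq = freq,
                 phase = phase), class = "jr_deform")
}

#' @rdname deform_affine
#' @param centers m x 3 matrix of bump centers (mm).
#' @param eps Length-m bump amplitudes (negative values contract locally).
#' @param width Length-m Gaussian widths (mm).
#' @export
deform_radial <- function(centers, eps, width) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  m <- nrow(centers)
  eps <- rep_len(as.numeric(eps), m)
  width <- rep_len(as.numeric(width), m)
  if (any(width <= 0)) stop("bump widths must be positive")
  # positivity: J(r) = lambda^2 (lambda - eps r^2/w^2 e^{-r^2/2w^2}).
  # check each bump on a fine radial grid out to 5 widths
  for (j in seq_len(m)) {
    r <- seq(0, 5 * width[j], length.out = 200)
    g <- exp(-r^2 / (2 * width[j]^2))
    lam <- 1 + eps[j] * g
    jr <- lam^2 * (lam - eps[j] * (r^2 / width[j]^2) * g)
    if (any(jr <= 0) || any(lam <= 0))
      stop("radial bump parameters violate positivity")
  }
  structure(list(family = "radial", centers = centers, eps = eps,
                 width = width), class = "jr_deform")
}

#' @rdname deform_affine
#' @param parts List of `jr_deform` objects, applied first-to-last.
#' @export
deform_composite <- function(parts) {
  stopifnot(all(vapply(parts, inherits, TRUE, "jr_deform")))
  structure(list(family = "composite", parts = parts), class = "jr_deform")
}

#' Apply a deformation to points
#'
#' @param def A `jr_deform`.
#' @param pts n x 3 matrix of physical coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
deform_apply <- function(def, pts) {
  pts <- as_pts(pts)
  switch(def$family,
    affine = sweep(sweep(pts, 2, def$center) %*% diag(def$scale), 2,
                   def$center, "+"),
    sinusoid = {
      out <- pts
      for (i in 1:3)
        out[, i] <- pts[, i] +
          def$amplitude[i] * sin(def$freq[i] * pts[, i] + def$phase[i])
      out
    },
    radial = {
      out <- pts
      for (j in seq_len(nrow(def$centers))) {
        d <- sweep(out, 2, def$centers[j, ])
        r2 <- rowSums(d^2)
        lam <- 1 + def$eps[j] * exp(-r2 / (2 * def$width[j]^2))
        out <- sweep(d * lam, 2, def$centers[j, ], "+")
      }
      out
    },
    composite = {
      out <- pts
      for (p in def$parts) out <- deform_apply(p, out)
      out
    },
    fixed_point_inverse = fp_invert_points(def$forward, pts, def$tol,
                                           def$max_iter),
    stop("unknown family")
  )
}

#' Closed-form Jacobian determinant of a deformation at points
#'
#' For composites the chain rule applies: the Jacobian is the product of the
#' component Jacobians evaluated along the composed trajectory.
#'
#' @inheritParams deform_apply
#' @return Numeric vector of determinants, one per point.
#' @export
deform_jacobian <- function(def, pts) {
  pts <- as_pts(pts)
  switch(def$family,
    affine = rep(prod(def$scale), nrow(pts)),
    sinusoid = {
      j <- rep(1, nrow(pts))
      for (i in 1:3)
        j <- j * (1 + def$amplitude[i] * def$freq[i] *
                    cos(def$freq[i] * pts[, i] + def$phase[i]))
      j
    },
    radial = {
      j <- rep(1, nrow(pts))
      cur <- pts
      for (jj in seq_len(nrow(def$centers))) {
        d <- sweep(cur, 2, def$centers[jj, ])
        r2 <- rowSums(d^2)
        g <- exp(-r2 / (2 * def$width[jj]^2))
        lam <- 1 + def$eps[jj] * g
        j <- j * lam^2 * (lam - def$eps[jj] * (r2 / def$width[jj]^2) * g)
        cur <- sweep(d * lam, 2, def$centers[jj, ], "+")
      }
      j
    },
    composite = {
      j <- rep(1, nrow(pts))
      cur <- pts
      for (p in def$parts) {
        j <- j * deform_jacobian(p, cur)
        cur <- deform_apply(p, cur)
      }
      j
    },
    fixed_point_inverse = {
      x <- deform_apply(def, pts)
      1 / deform_jacobian(def$forward, x)
    },
    stop("unknown family")
  )
}

#' Invert an analytic deformation
#'
#' Affine maps invert in closed form; all other families (and composites,
#' inverted component-by-component in reverse order) use damped fixed-point
#' iteration `x <- y - u(x)` to the stated tolerance.
#'
#' @param def A `jr_deform` (orientation-preserving).
#' @param tol Convergence tolerance in mm (default 1e-3).
#' @param max_iter Maximum fixed-point iterations (default 50).
#' @return A `jr_deform` representing the inverse.
#' @export
invert_analytic <- function(def, tol = 1e-3, max_iter = 50L) {
  switch(def$family,
    affine = deform_affine(1 / def$scale, def$center),
    composite = deform_composite(lapply(rev(def$parts), invert_analytic,
                                        tol = tol, max_iter = max_iter)),
    fixed_point_inverse = def$forward,
    structure(list(family = "fixed_point_inverse", forward = def,
                   tol = tol, max_iter = as.integer(max_iter)),
              class = "jr_deform")
  )
}

fp_invert_points <- function(fwd, y, tol, max_iter) {
  x <- y
  for (it in seq_len(max_iter)) {
    hx <- deform_apply(fwd, x)
    res <- y - hx
    x <- x + res
    if (max(abs(res)) <= tol) return(x)
  }
  if (max(abs(deform_apply(fwd, x) - y)) > tol)
    stop("fixed-point inversion did not converge within ", max_iter,
         " iterations")
  x
}

as_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  pts
}

#' Regular grid description
#'
#' @param shape Integer length-3 voxel counts.
#' @param spacing Voxel size (mm), scalar or length 3.
#' @param origin Physical position of voxel (0,0,0) (mm).
#' @return A `jr_grid` list.
#' @export
grid3d <- function(shape, spacing = 3, origin = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  structure(list(shape = shape, spacing = spacing,
                 origin = as.numeric(origin)), class = "jr_grid")
}

as_grid <- function(x) {
  if (inherits(x, "jr_grid")) return(x)
  if (inherits(x, "jr_volume"))
    return(grid3d(dim(x$data), x$spacing, x$origin))
  stop("expected a jr_grid or jr_volume")
}

# physical coordinates of all voxels, n x 3, voxel index d fastest
grid_points <- function(g) {
  g <- as_grid(x = g)
  ax <- lapply(1:3, function(i)
    g$origin[i] + (seq_len(g$shape[i]) - 1) * g$spacing[i])
  cbind(rep(ax[[1]], times = g$shape[2] * g$shape[3]),
        rep(rep(ax[[2]], each = g$shape[1]), times = g$shape[3]),
        rep(ax[[3]], each = g$shape[1] * g$shape[2]))
}

#' Sample an analytic deformation on a grid
#'
#' Returns the displacement field `u(x) = h(x) - x` sampled at every voxel
#' and the exact closed-form Jacobian map, both in the frame the grid lives
#' in (the fixed-image frame of the transformation).
#'
#' @param def A `jr_deform`.
#' @param grid A `jr_grid` or `jr_volume` defining the sampling grid.
#' @param frame Which inflation state the grid represents (`"FRC"` or
#'   `"TLC"`).
#' @return List with `field` (D x H x W x 3 array, mm), `jac`
#'   (`jr_volume` of kind `"jacobian"`), `frame`.
#' @export
evaluate_analytic <- function(def, grid, frame = "FRC") {
  g <- as_grid(grid)
  pts <- grid_points(g)
  hp <- deform_apply(def, pts)
  u <- array(hp - pts, dim = c(g$shape, 3L))
  j <- array(deform_jacobian(def, pts), dim = g$shape)
  if (any(j <= 0)) stop("deformation parameters give non-positive Jacobian")
  list(field = u,
       jac = volume3d(j, g$spacing, g$origin, kind = "jacobian"),
       frame = frame)
}

#' Numeric Jacobian determinant of a displacement field
#'
#' Computes `det(I + du/dx)` voxelwise with spatial derivatives taken in
#' physical units (mm): central differences in the interior, first-order
#' one-sided differences on the outermost voxel layer. A non-positive
#' determinant inside the mask indicates folding of the transformation; it
#' is reported via a warning and the `folded` flag, never an error.
#'
#' @param field D x H x W x 3 displacement array (mm), or the list returned
#'   by [evaluate_analytic()].
#' @param mask Optional `jr_mask` on the same grid (NULL = whole grid).
#' @param spacing Voxel spacing (mm); taken from `mask` if supplied.
#' @param frame Frame tag carried through to the result.
#' @return A `jr_jacmap`: list with `J`, `Y` (`jr_volume`s), `frame`,
#'   `folded` (logical) and `n_folded`.
#' @export
jacobian_determinant <- function(field, mask = NULL, spacing = NULL,
                                 frame = "FRC") {
  if (is.list(field) && !is.null(field$field)) field <- field$field
  d <- dim(field)
  if (length(d) != 4L || d[4] != 3L) stop("field must be D x H x W x 3")
  if (!is.null(mask)) {
    if (!identical(dim(mask$data), d[1:3])) stop("mask/field shape mismatch")
    if (is.null(spacing)) spacing <- mask$spacing
  }
  if (is.null(spacing)) stop("spacing required when no mask is given")
  spacing <- rep_len(as.numeric(spacing), 3L)

  # gradient tensor G[i,j] = d u_i / d x_j, assembled axis by axis
  G <- vector("list", 9L)
  for (i in 1:3) {
    ui <- array(field[, , , i], dim = d[1:3])
    for (j in 1:3)
      G[[(i - 1) * 3 + j]] <- axis_gradient(ui, j, spacing[j])
  }
  a <- function(i, j) G[[(i - 1) * 3 + j]] + (i == j)
  J <- a(1, 1) * (a(2, 2) * a(3, 3) - a(2, 3) * a(3, 2)) -
       a(1, 2) * (a(2, 1) * a(3, 3) - a(2, 3) * a(3, 1)) +
       a(1, 3) * (a(2, 1) * a(3, 2) - a(2, 2) * a(3, 1))

  inmask <- if (is.null(mask)) rep(TRUE, length(J)) else mask$data == 1
  n_folded <- sum(J[inmask] <= 0)
  if (n_folded > 0)
    warning(sprintf("non-positive Jacobian at %d in-mask voxel(s): %s",
                    n_folded, "transformation folds"))
  sp <- if (is.null(mask)) spacing else mask$spacing
  org <- if (is.null(mask)) c(0, 0, 0) else mask$origin
  Jv <- volume3d(J, sp, org, kind = "jacobian")
  Ypos <- pmax(J, .Machine$double.xmin)
  Yv <- volume3d(array(log2(Ypos), dim = d[1:3]), sp, org,
                 kind = "log2_jacobian")
  structure(list(J = Jv, Y = Yv, frame = frame,
                 folded = n_folded > 0, n_folded = n_folded),
            class = "jr_jacmap")
}

# per-axis derivative: central interior, first-order one-sided at the edges
axis_gradient <- function(x, axis, h) {
  d <- dim(x)
  n <- d[axis]
  g <- array(0, dim = d)
  idx <- function(k) switch(axis,
    `1` = x[k, , , drop = FALSE],
    `2` = x[, k, , drop = FALSE],
    `3` = x[, , k, drop = FALSE])
  assign_idx <- function(k, val) switch(axis,
    `1` = g[k, , ] <<- val,
    `2` = g[, k, ] <<- val,
    `3` = g[, , k] <<- val)
  if (n == 1L) return(g)
  assign_idx(1L, (idx(2L) - idx(1L)) / h)
  assign_idx(n, (idx(n) - idx(n - 1L)) / h)
  if (n > 2L) {
    ks <- 2:(n - 1L)
    assign_idx(ks, (idx(ks + 1L) - idx(ks - 1L)) / (2 * h))
  }
  g
}

#' Construct a Jacobian map from a Jacobian volume
#'
#' Bundles a positive Jacobian volume with its log2 encoding.
#' @param J `jr_volume` of kind `"jacobian"` (or plain array).
#' @param spacing,origin Grid geometry if `J` is a plain array.
#' @param frame Frame tag (`"FRC"` or `"TLC"`).
#' @param mask Optional mask; positivity is enforced in-mask only.
#' @return A `jr_jacmap`.
#' @export
jacobian_map <- function(J, spacing = NULL, origin = c(0, 0, 0),
                         frame = "FRC", mask = NULL) {
  if (!inherits(J, "jr_volume")) {
    if (is.null(spacing)) stop("spacing required for a plain array")
    J <- volume3d(J, spacing, origin, kind = "jacobian")
  }
  Y <- log2_encode(J, mask = mask)
  structure(list(J = J, Y = Y, frame = frame, folded = FALSE, n_folded = 0L),
            class = "jr_jacmap")
}

#' log2 encoding of a Jacobian volume
#'
#' `Y = log2(J)`, so that reciprocal volume ratios have equal magnitude and
#' opposite sign: expansion maps to positive values, contraction to negative.
#'
#' @param J `jr_volume` of positive values (kind `"jacobian"`).
#' @param mask Optional `jr_mask`; positivity is required in-mask and
#'   out-of-mask values are encoded as 0.
#' @return `jr_volume` of kind `"log2_jacobian"`.
#' @export
log2_encode <- function(J, mask = NULL) {
  x <- J$data
  inmask <- if (is.null(mask)) array(TRUE, dim(x)) else mask$data == 1
  if (any(x[inmask] <= 0)) stop("non-positive Jacobian in-mask")
  y <- array(0, dim(x))
  y[inmask] <- log2(x[inmask])
  volume3d(y, J$spacing, J$origin, kind = "log2_jacobian")
}

#' Decode a log2-Jacobian volume
#'
#' `J = 2^Y`, strictly positive by construction.
#' @param Y `jr_volume` of kind `"log2_jacobian"`.
#' @return `jr_volume` of kind `"jacobian"`.
#' @export
log2_decode <- function(Y) {
  if (any(!is.finite(Y$data))) stop("non-finite log2-Jacobian input")
  volume3d(2^Y$data, Y$spacing, Y$origin, kind = "jacobian")
}
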