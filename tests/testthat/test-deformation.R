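test_that("zero displacement gives unit Jacobian everywhere", {
  u <- array(0, dim = c(8, 8, 8, 3))
  jm <- jacobian_determinant(u, spacing = 3)
  expect_equal(max(abs(jm$J$data - 1)), 0)
  expect_false(jm$folded)
})

test_that("linear displacement fields are differentiated exactly", {
  g <- grid3d(10, 3)
  pts <- jacreg:::grid_points(g)
  u <- array(0, dim = c(g$shape, 3))
  u[, , , 1] <- array(0.1 * pts[, 1], dim = g$shape)
  jm <- jacobian_determinant(u, spacing = 3)
  expect_equal(max(abs(jm$J$data - 1.1)), 0, tolerance = 1e-12)
})

test_that("numeric Jacobian matches the sinusoid closed form within the truncation bound", {
  A <- 2; k <- 0.1; h <- 3
  def <- deform_sinusoid(amplitude = c(A, 0, 0), freq = c(k, k, k))
  ev <- evaluate_analytic(def, grid3d(32, h))
  jm <- jacobian_determinant(ev$field, spacing = h)
  err <- abs(jm$J$data - ev$jac$data)
  interior <- array(FALSE, dim(err))
  interior[2:31, 2:31, 2:31] <- TRUE
  bound <- A * k^3 * h^2 / 6
  expect_lte(max(err[interior]), bound * 1.001)
})

test_that("separable sinusoid Jacobian is the product of per-axis factors", {
  def <- deform_sinusoid(amplitude = c(1, 2, 0.5), freq = c(0.1, 0.05, 0.2),
                         phase = c(0.3, 1, 2))
  set.seed(4)
  pts <- matrix(runif(60, 0, 90), ncol = 3)
  j <- deform_jacobian(def, pts)
  manual <- (1 + 1 * 0.1 * cos(0.1 * pts[, 1] + 0.3)) *
    (1 + 2 * 0.05 * cos(0.05 * pts[, 2] + 1)) *
    (1 + 0.5 * 0.2 * cos(0.2 * pts[, 3] + 2))
  expect_equal(j, manual, tolerance = 1e-12)
})

test_that("affine family has constant Jacobian equal to the product of scales", {
  def <- deform_affine(c(1.2, 1.1, 0.9), center = c(10, 10, 10))
  ev <- evaluate_analytic(def, grid3d(8, 3))
  expect_equal(unique(as.vector(ev$jac$data)), 1.2 * 1.1 * 0.9,
               tolerance = 1e-12)
})

test_that("zero-amplitude radial family is the identity", {
  def <- deform_radial(matrix(c(10, 10, 10), 1), eps = 0, width = 5)
  pts <- matrix(runif(30, 0, 30), ncol = 3)
  expect_equal(deform_apply(def, pts), pts)
  expect_equal(deform_jacobian(def, pts), rep(1, 10))
})

test_that("log2 encoding maps reciprocal ratios to opposite signs", {
  J <- volume3d(array(c(1, 2, 0.5, 4), c(4, 1, 1)), 3, kind = "jacobian")
  Y <- log2_encode(J)
  expect_equal(as.vector(Y$data), c(0, 1, -1, 2))
  back <- log2_decode(Y)
  expect_equal(back$data, J$data, tolerance = 1e-12)
})

test_that("log2 encoding rejects non-positive in-mask values", {
  J <- volume3d(array(c(-1, 2), c(2, 1, 1)), 3, kind = "jacobian")
  expect_error(log2_encode(J), "non-positive")
})

test_that("affine inversion is exact and sinusoid inversion converges", {
  aff <- deform_affine(c(2, 1.5, 1.25), center = c(5, 5, 5))
  inv <- invert_analytic(aff)
  expect_equal(inv$scale, 1 / c(2, 1.5, 1.25))
  # identity inverts to identity
  idy <- invert_analytic(deform_affine(c(1, 1, 1)))
  expect_equal(idy$scale, c(1, 1, 1))

  sdef <- deform_sinusoid(amplitude = c(1, 1, 1), freq = c(0.1, 0.1, 0.1))
  sinv <- invert_analytic(sdef)
  pts <- jacreg:::grid_points(grid3d(32, 3))
  res <- deform_apply(sdef, deform_apply(sinv, pts)) - pts
  expect_lte(max(abs(res)), 1e-3)
})

test_that("forward/backward Jacobians are reciprocal along the deformation", {
  h <- deform_composite(list(
    deform_sinusoid(amplitude = c(0.8, 0.6, 0.5), freq = c(0.08, 0.1, 0.09)),
    deform_affine(c(1.15, 1.15, 1.15), center = c(45, 45, 45))))
  pts <- jacreg:::grid_points(grid3d(16, 6))
  j_fwd <- deform_jacobian(h, pts)
  hinv <- invert_analytic(h)
  hp <- deform_apply(h, pts)
  j_bwd <- deform_jacobian(hinv, hp)  # Jacobian of h^-1 at h(x)
  rel <- abs(j_fwd * j_bwd - 1)
  expect_lte(median(rel), 0.01)
})

test_that("mean Jacobian equals the deformed-to-original volume ratio", {
  ph <- clean_phantom(seed = 9, effort = 1.7, disease_fraction = 0.1)
  ratio <- sum(ph$M_TLC$data) / sum(ph$M_FRC$data)
  jmean <- mean(ph$J_FRC$J$data[ph$M_FRC$data == 1])
  expect_equal(jmean, ratio, tolerance = 0.02)
})

test_that("folding is flagged, not raised", {
  # displacement with strong gradient -> negative determinant somewhere
  g <- grid3d(8, 1)
  pts <- jacreg:::grid_points(g)
  u <- array(0, dim = c(g$shape, 3))
  u[, , , 1] <- array(-1.5 * pts[, 1], dim = g$shape)  # scale -0.5: folds
  m <- lung_mask(array(1, g$shape), 1)
  expect_warning(jm <- jacobian_determinant(u, m), "fold")
  expect_true(jm$folded)
  expect_gt(jm$n_folded, 0)
})

test_that("out-of-range parameters are rejected", {
  expect_error(deform_sinusoid(amplitude = c(11, 0, 0), freq = c(0.1, 1, 1)),
               "positivity")
  # strong expansion bumps fold the radial map (contraction bumps cannot)
  expect_error(deform_radial(matrix(0, 1, 3), eps = 3, width = 3),
               "positivity")
})
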