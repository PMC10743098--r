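test_that("output shape matches input shape and fusion width is C0*L", {
  cfg <- network_config(L = 4, base_filters = 8, in_channels = 2)
  net <- build_network(cfg, seed = 1)
  x <- array(runif(32^3 * 2, -1, 1), dim = c(32, 32, 32, 2))
  y <- net_forward(net, x)
  expect_equal(dim(y), c(32L, 32L, 32L))
  expect_equal(dim(net$int1$w)[4], 32L)  # C0*L = 8*4 fused channels
  # reduced-depth single-channel configuration
  cfg2 <- network_config(L = 2, base_filters = 4, in_channels = 1)
  net2 <- build_network(cfg2, seed = 1)
  y2 <- net_forward(net2, array(0.1, dim = c(16, 16, 16, 1)))
  expect_equal(dim(y2), c(16L, 16L, 16L))
})

test_that("parameter count equals the closed-form layer ledger", {
  for (cfg in list(network_config(L = 4, base_filters = 8, in_channels = 2),
                   network_config(L = 3, base_filters = 4, in_channels = 1))) {
    net <- build_network(cfg, seed = 2)
    expect_equal(length(net_get_params(net)),
                 jacreg:::net_param_ledger(cfg))
  }
})

test_that("inference is deterministic and rejects bad inputs", {
  cfg <- network_config(L = 2, base_filters = 4, in_channels = 1)
  net <- build_network(cfg, seed = 3)
  x <- array(runif(8^3, -1, 1), dim = c(8, 8, 8, 1))
  expect_identical(net_forward(net, x), net_forward(net, x))
  expect_error(net_forward(net, array(0, c(7, 8, 8, 1))), "divisible")
  expect_error(net_forward(net, array(0, c(8, 8, 8, 2))), "channel")
  xb <- x; xb[1] <- NA
  expect_error(net_forward(net, xb), "finite")
})

test_that("zeroing the final layer yields Y = 0 and J = 1", {
  cfg <- network_config(L = 2, base_filters = 4, in_channels = 1)
  net <- build_network(cfg, seed = 4)
  net$int2$w[] <- 0
  net$int2$b[] <- 0
  x <- array(runif(8^3, -1, 1), dim = c(8, 8, 8, 1))
  y <- net_forward(net, x)
  expect_equal(max(abs(y)), 0)
  ph <- clean_phantom(seed = 2, shape = c(16, 16, 16))
  cs <- prepare_case(ph, "FRC", paired = FALSE, multiple = 2L)
  net1 <- build_network(network_config(L = 2, base_filters = 4,
                                       in_channels = 1), seed = 5)
  net1$int2$w[] <- 0; net1$int2$b[] <- 0
  pred <- predict_jacobian(net1, cs)
  expect_equal(unique(as.vector(pred$J$data)), 1)
})

test_that("residual identity blocks pass nonnegative input through when zeroed", {
  ly_a <- jacreg:::new_conv(4, 4, 3)
  ly_b <- jacreg:::new_conv(4, 4, 3, act = FALSE)
  for (ly in list(ly_a, ly_b)) {
    ly$w[] <- 0; ly$b[] <- 0; ly$gamma[] <- 0; ly$beta[] <- 0
  }
  x <- array(abs(rnorm(6^3 * 4)), dim = c(6, 6, 6, 4))
  a <- jacreg:::layer_forward(ly_a, x)
  b <- jacreg:::layer_forward(ly_b, a)
  out <- pmax(b + x, 0)
  expect_equal(out, x)
})

test_that("feature maps halve in size and double in channels per level", {
  cfg <- network_config(L = 3, base_filters = 4, in_channels = 1)
  net <- build_network(cfg, seed = 6)
  x <- array(runif(16^3, -1, 1), dim = c(16, 16, 16, 1))
  invisible(net_forward(net, x))
  # probe the down-block outputs via the stored ReLU masks
  expect_equal(dim(net$ribA[[1]]$w)[4:5], c(4L, 4L))
  expect_equal(dim(net$ribA[[2]]$w)[4:5], c(8L, 8L))
  expect_equal(dim(net$ribA[[3]]$w)[4:5], c(16L, 16L))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(11)
  cfg <- network_config(L = 2, base_filters = 2, in_channels = 1)
  net <- build_network(cfg, seed = 7)
  x <- array(runif(8^3, -1, 1), dim = c(8, 8, 8, 1))
  tgt <- array(rnorm(8^3, 0, 0.5), dim = c(8, 8, 8))
  mask <- array(0, c(8, 8, 8)); mask[3:6, 3:6, 3:6] <- 1
  lcfg <- loss_config(alpha = 0.5)
  theta <- net_get_params(net)
  jacreg:::net_zero_grads(net)
  lg <- jacreg:::loss_total_grad(tgt, net_forward(net, x), mask, lcfg)
  jacreg:::net_backward(net, lg$grad)
  g <- jacreg:::net_get_grads(net)
  f <- function(th) {
    net_set_params(net, th)
    loss_total(tgt, net_forward(net, x), mask, lcfg)
  }
  idx <- sort(sample(length(theta), 15))
  num <- vapply(idx, function(i) {
    e <- 1e-5
    tp <- theta; tp[i] <- tp[i] + e; f1 <- f(tp)
    tp[i] <- tp[i] - 2 * e; f2 <- f(tp)
    (f1 - f2) / (2 * e)
  }, 0)
  rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-6)
  expect_lt(max(rel), 1e-5)
})

test_that("gradients flow through the skip connections to level 0", {
  ph <- clean_phantom(seed = 5, shape = c(16, 16, 16))
  cs <- prepare_case(ph, "FRC", paired = TRUE, multiple = 2L)
  net <- build_network(network_config(L = 2, base_filters = 2,
                                      in_channels = 2), seed = 9)
  jacreg:::net_zero_grads(net)
  yh <- net_forward(net, cs$x)
  lg <- jacreg:::loss_total_grad(cs$y, yh, cs$mask, loss_config())
  jacreg:::net_backward(net, lg$grad)
  expect_gt(max(abs(net$ribA[[1]]$gw)), 0)
  expect_gt(max(abs(net$stem$gw)), 0)
})

test_that("single- and paired-arm channel contracts are enforced", {
  ph <- clean_phantom(seed = 6, shape = c(16, 16, 16))
  cs2 <- prepare_case(ph, "FRC", paired = TRUE, multiple = 2L)
  cs1 <- prepare_case(ph, "FRC", paired = FALSE, multiple = 2L)
  net <- build_network(network_config(L = 2, base_filters = 2,
                                      in_channels = 1), seed = 8)
  arm1 <- study_arm("single", "FRC")
  expect_error(predict_jacobian(net, cs2, arm1), "arm/input mismatch")
  expect_s3_class(predict_jacobian(net, cs1, arm1), "jr_jacmap")
  armT <- study_arm("single", "TLC")
  expect_error(predict_jacobian(net, cs1, armT), "arm/input mismatch")
})
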