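#' Network configuration
#'
#' Configuration of the multiscale residual regression network. The network
#' has `L` resolution levels; the residual identity block at level `l`
#' carries `C_l = base_filters * 2^l` channels, so inputs must have spatial
#' extents divisible by `2^(L-1)`.
#'
#' @param L Number of levels (default 4).
#' @param base_filters Channels at level 0 (default 8).
#' @param in_channels 1 (single image) or 2 (paired images).
#' @param kernel_size Convolution kernel size (default 3).
#' @param norm_epsilon Instance-normalization epsilon.
#' @return A `jr_net_config` list.
#' @export
network_config <- function(L = 4L, base_filters = 8L, in_channels = 2L,
                           kernel_size = 3L, norm_epsilon = 1e-5) {
  stopifnot(L >= 1, in_channels %in% c(1L, 2L), base_filters >= 1)
  structure(list(L = as.integer(L), base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels),
                 kernel_size = as.integer(kernel_size),
                 norm_epsilon = norm_epsilon, output_channels = 1L),
            class = "jr_net_config")
}

# ---- layer: convolution (+ optional instance norm and ReLU) -----------------

new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                     norm = TRUE, act = TRUE, transpose = FALSE,
                     eps = 1e-5, name = "conv") {
  ly <- new.env(parent = emptyenv())
  ly$cin <- cin; ly$cout <- cout; ly$k <- as.integer(k)
  ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$norm <- norm; ly$act <- act; ly$transpose <- transpose
  ly$eps <- eps; ly$name <- name
  fan_in <- if (transpose) cin else k^3 * cin
  ly$w <- array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)),
                dim = c(k, k, k, cin, cout))
  ly$b <- numeric(cout)
  if (norm) { ly$gamma <- rep(1, cout); ly$beta <- numeric(cout) }
  class(ly) <- "jr_layer"
  ly
}

layer_forward <- function(ly, x) {
  z <- if (ly$transpose) .convt3d_fwd(x, ly$w, ly$b)
       else .conv3d_fwd(x, ly$w, ly$b, ly$stride, ly$pad)
  ly$x <- x
  if (ly$norm) {
    d <- dim(z)
    n <- prod(d[1:3])
    zm <- matrix(z, n, d[4])
    mu <- colMeans(zm)
    va <- colMeans(zm^2) - mu^2
    s <- sqrt(va + ly$eps)
    xhat <- sweep(sweep(zm, 2, mu), 2, s, "/")
    out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    ly$xhat <- xhat; ly$s <- s
    z <- array(out, dim = d)
  }
  if (ly$act) {
    ly$pos <- z > 0
    z <- z * ly$pos
  }
  z
}

layer_backward <- function(ly, gy) {
  if (ly$act) gy <- gy * ly$pos
  if (ly$norm) {
    d <- dim(gy)
    n <- prod(d[1:3])
    gm <- matrix(gy, n, d[4])
    ly$ggamma <- acc(ly$ggamma, colSums(gm * ly$xhat))
    ly$gbeta <- acc(ly$gbeta, colSums(gm))
    gg <- sweep(gm, 2, ly$gamma, "*")              # d/d xhat
    m1 <- colMeans(gg)
    m2 <- colMeans(gg * ly$xhat)
    gz <- sweep(sweep(gg, 2, m1) - sweep(ly$xhat, 2, m2, "*"), 2, ly$s, "/")
    gy <- array(gz, dim = d)
  }
  bw <- if (ly$transpose) .convt3d_bwd(ly$x, ly$w, gy)
        else .conv3d_bwd(ly$x, ly$w, gy, ly$stride, ly$pad)
  ly$gw <- acc(ly$gw, bw$gw)
  ly$gb <- acc(ly$gb, bw$gb)
  ly$x <- NULL; ly$xhat <- NULL; ly$pos <- NULL
  bw$gx
}

acc <- function(cur, add) if (is.null(cur)) add else cur + add

layer_params <- function(ly) {
  p <- list(w = ly$w, b = ly$b)
  if (ly$norm) p <- c(p, list(gamma = ly$gamma, beta = ly$beta))
  p
}

layer_grads <- function(ly) {
  g <- list(w = ly$gw, b = ly$gb)
  if (ly$norm) g <- c(g, list(gamma = ly$ggamma, beta = ly$gbeta))
  lapply(g, function(x) if (is.null(x)) 0 else x)
}

layer_zero_grads <- function(ly) {
  ly$gw <- NULL; ly$gb <- NULL; ly$ggamma <- NULL; ly$gbeta <- NULL
}

# ---- the network ------------------------------------------------------------

#' Build the multiscale residual regression network
#'
#' Architecture: a stem convolution lifts the input to `base_filters`
#' channels; each level `l = 0..L-1` applies a residual identity block
#' (channels and size preserved; normalization before the residual
#' addition, activation after) and, between levels, a residual down block
#' (stride-2 convolution doubling the channels, with a stride-2 1x1
#' projection shortcut). Each identity-block output is upconvolved back to
#' full resolution with `base_filters` filters (transposed convolution with
#' kernel and stride `2^l`), the `base_filters * L` channel multiscale stack
#' is concatenated, and two integration convolutions (the last one 1x1 and
#' linear) produce the single-channel log2-Jacobian map. All other
#' convolutions carry instance normalization and ReLU. Weights use
#' He-normal initialization.
#'
#' @param cfg A `jr_net_config`.
#' @param seed Optional seed for reproducible initialization.
#' @return A `jr_network` object.
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  build <- function() {
    L <- cfg$L; c0 <- cfg$base_filters; k <- cfg$kernel_size
    eps <- cfg$norm_epsilon
    net <- new.env(parent = emptyenv())
    net$cfg <- cfg
    net$stem <- new_conv(cfg$in_channels, c0, k, eps = eps, name = "stem")
    net$ribA <- list(); net$ribB <- list(); net$dmain <- list()
    net$dproj <- list(); net$up <- list()
    for (l in 0:(L - 1)) {
      cl <- c0 * 2^l
      net$ribA[[l + 1]] <- new_conv(cl, cl, k, eps = eps,
                                    name = sprintf("rib%d_a", l))
      net$ribB[[l + 1]] <- new_conv(cl, cl, k, act = FALSE, eps = eps,
                                    name = sprintf("rib%d_b", l))
      if (l < L - 1) {
        net$dmain[[l + 1]] <- new_conv(cl, 2 * cl, k, stride = 2L,
                                       act = FALSE, eps = eps,
                                       name = sprintf("down%d_main", l))
        net$dproj[[l + 1]] <- new_conv(cl, 2 * cl, 1L, stride = 2L, pad = 0L,
                                       norm = FALSE, act = FALSE,
                                       name = sprintf("down%d_proj", l))
      }
      net$up[[l + 1]] <- if (l == 0)
        new_conv(c0, c0, 1L, pad = 0L, eps = eps, name = "up0")
      else
        new_conv(cl, c0, 2L^l, transpose = TRUE, eps = eps,
                 name = sprintf("up%d", l))
    }
    net$int1 <- new_conv(c0 * L, c0 * L, k, eps = eps, name = "int1")
    net$int2 <- new_conv(c0 * L, 1L, 1L, pad = 0L, norm = FALSE, act = FALSE,
                         name = "int2")
    class(net) <- "jr_network"
    net
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

net_layers <- function(net) {
  c(list(net$stem), net$ribA, net$ribB, net$dmain, net$dproj, net$up,
    list(net$int1, net$int2))
}

#' @export
print.jr_network <- function(x, ...) {
  np <- length(net_get_params(x))
  cat(sprintf("<jr_network> L=%d, base=%d, in=%d, %d parameters\n",
              x$cfg$L, x$cfg$base_filters, x$cfg$in_channels, np))
  invisible(x)
}

#' Forward pass
#'
#' @param net A `jr_network`.
#' @param x Input array `(D, H, W, C)` with `C = in_channels` and spatial
#'   extents divisible by `2^(L-1)`; values expected in `[-1, 1]`.
#' @return Array `(D, H, W)`: the predicted log2-Jacobian map.
#' @export
net_forward <- function(net, x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[4] != net$cfg$in_channels)
    stop(sprintf("network expects %d input channel(s), got %d",
                 net$cfg$in_channels, d[4]))
  if (any(d[1:3] %% 2^(net$cfg$L - 1) != 0))
    stop("input extents must be divisible by 2^(L-1)")
  if (any(!is.finite(x))) stop("non-finite input")
  L <- net$cfg$L
  cur <- layer_forward(net$stem, x)
  feats <- vector("list", L)
  net$rib_pos <- vector("list", L)
  net$down_pos <- vector("list", L)
  for (l in 0:(L - 1)) {
    a <- layer_forward(net$ribA[[l + 1]], cur)
    bvl <- layer_forward(net$ribB[[l + 1]], a)
    pre <- bvl + cur
    pos <- pre > 0
    net$rib_pos[[l + 1]] <- pos
    cur <- pre * pos
    feats[[l + 1]] <- cur
    if (l < L - 1) {
      m <- layer_forward(net$dmain[[l + 1]], cur)
      p <- layer_forward(net$dproj[[l + 1]], cur)
      pre2 <- m + p
      pos2 <- pre2 > 0
      net$down_pos[[l + 1]] <- pos2
      cur <- pre2 * pos2
    }
  }
  ups <- lapply(seq_len(L), function(i)
    layer_forward(net$up[[i]], feats[[i]]))
  cat_dim <- dim(ups[[1]])
  fused <- array(0, dim = c(cat_dim[1:3], net$cfg$base_filters * L))
  off <- 0L
  for (i in seq_len(L)) {
    nc <- dim(ups[[i]])[4]
    fused[, , , off + seq_len(nc)] <- ups[[i]]
    off <- off + nc
  }
  out <- layer_forward(net$int2, layer_forward(net$int1, fused))
  array(out, dim = dim(out)[1:3])
}

# backward pass: gy is (D, H, W) gradient of the loss w.r.t. the output map
net_backward <- function(net, gy) {
  L <- net$cfg$L
  dim(gy) <- c(dim(gy), 1L)
  g <- layer_backward(net$int1, layer_backward(net$int2, gy))
  c0 <- net$cfg$base_filters
  gfeat <- vector("list", L)
  for (i in seq_len(L)) {
    gi <- g[, , , (i - 1) * c0 + seq_len(c0), drop = FALSE]
    gfeat[[i]] <- layer_backward(net$up[[i]], gi)
  }
  gcur <- NULL
  for (l in (L - 1):0) {
    gl <- gfeat[[l + 1]]
    if (l < L - 1) {
      gd <- gcur * net$down_pos[[l + 1]]
      gl <- gl + layer_backward(net$dmain[[l + 1]], gd) +
        layer_backward(net$dproj[[l + 1]], gd)
    }
    gpre <- gl * net$rib_pos[[l + 1]]
    ga <- layer_backward(net$ribB[[l + 1]], gpre)
    gcur <- layer_backward(net$ribA[[l + 1]], ga) + gpre
  }
  gx <- layer_backward(net$stem, gcur)
  net$rib_pos <- NULL; net$down_pos <- NULL
  gx
}

#' Get / set network parameters as a flat numeric vector
#'
#' @param net A `jr_network`.
#' @return For `net_get_params`, a numeric vector of all weights.
#' @export
net_get_params <- function(net) {
  unlist(lapply(net_layers(net), layer_params), use.names = FALSE)
}

#' @rdname net_get_params
#' @param theta Numeric vector as returned by `net_get_params`.
#' @export
net_set_params <- function(net, theta) {
  pos <- 0L
  for (ly in net_layers(net)) {
    for (nm in names(layer_params(ly))) {
      cur <- ly[[nm]]
      n <- length(cur)
      val <- theta[pos + seq_len(n)]
      ly[[nm]] <- if (is.array(cur)) array(val, dim = dim(cur)) else val
      pos <- pos + n
    }
  }
  stopifnot(pos == length(theta))
  invisible(net)
}

net_get_grads <- function(net) {
  unlist(lapply(net_layers(net), function(ly) {
    g <- layer_grads(ly)
    p <- layer_params(ly)
    for (nm in names(p))
      if (length(g[[nm]]) != length(p[[nm]])) g[[nm]] <- p[[nm]] * 0
    g
  }), use.names = FALSE)
}

net_zero_grads <- function(net) {
  for (ly in net_layers(net)) layer_zero_grads(ly)
  invisible(net)
}

# closed-form parameter ledger for a configuration: per layer,
# k^3*cin*cout weights + cout biases (+ 2*cout instance-norm affine terms)
net_param_ledger <- function(cfg) {
  L <- cfg$L; c0 <- cfg$base_filters; k <- cfg$kernel_size
  count <- function(k, cin, cout, norm) k^3 * cin * cout + cout +
    if (norm) 2 * cout else 0
  total <- count(k, cfg$in_channels, c0, TRUE)          # stem
  for (l in 0:(L - 1)) {
    cl <- c0 * 2^l
    total <- total + 2 * count(k, cl, cl, TRUE)         # identity block
    if (l < L - 1) {
      total <- total + count(k, cl, 2 * cl, TRUE)       # down main
      total <- total + count(1, cl, 2 * cl, FALSE)      # down projection
    }
    total <- total + count(if (l == 0) 1 else 2^l, cl, c0, TRUE)  # upconv
  }
  total + count(k, c0 * L, c0 * L, TRUE) + count(1, c0 * L, 1, FALSE)
}

#' Predict a Jacobian map for a prepared case
#'
#' Runs the network on the prepared input, removes the padding, and decodes
#' the prediction to the Jacobian scale: `J = 2^Y` inside the lung mask and
#' 1 outside (positivity by construction).
#'
#' @param net A `jr_network`.
#' @param case A prepared case from [prepare_case()].
#' @param arm Optional `jr_study_arm`; if given, the case's channel count
#'   must match the arm's input factor.
#' @return A `jr_jacmap` (frame = the case's output space) plus a `Yhat`
#'   element with the raw unpadded prediction.
#' @export
predict_jacobian <- function(net, case, arm = NULL) {
  if (!is.null(arm)) {
    want <- if (arm$input_factor == "paired") 2L else 1L
    if (dim(case$x)[4] != want)
      stop(sprintf("arm/input mismatch: %s-input arm given %d channel(s)",
                   arm$input_factor, dim(case$x)[4]))
    if (!identical(arm$output_space, case$output_space))
      stop("arm/input mismatch: case prepared for a different output space")
  }
  yhat <- net_forward(net, case$x)
  yhat <- unpad_volume(yhat, case$pad)
  mask <- unpad_volume(case$mask, case$pad)
  y <- yhat
  y[mask != 1] <- 0
  jm <- jacobian_map(volume3d(2^y, case$spacing, kind = "jacobian"),
                     frame = case$output_space)
  jm$Yhat <- yhat
  jm
}
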