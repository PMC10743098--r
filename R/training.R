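#' Study arm of the multifactorial design
#'
#' One cell of the 2x2 design: input factor (single or paired CT images)
#' crossed with output space (FRC expansion or TLC contraction). Single-input
#' arms consume only the image matching the output space.
#'
#' @param input_factor `"single"` or `"paired"`.
#' @param output_space `"FRC"` or `"TLC"`.
#' @return A `jr_study_arm`.
#' @export
study_arm <- function(input_factor = c("paired", "single"),
                      output_space = c("FRC", "TLC")) {
  structure(list(input_factor = match.arg(input_factor),
                 output_space = match.arg(output_space)),
            class = "jr_study_arm")
}

arm_id <- function(arm) paste(arm$input_factor, tolower(arm$output_space),
                              sep = "_")

#' Training configuration
#'
#' Adam with the AMSGrad variant; He-normal initialization is handled by
#' [build_network()].
#'
#' @param learning_rate Step size (default 1e-4).
#' @param batch_size Cases per optimizer step (default 4).
#' @param epochs Number of passes over the training set.
#' @param seed Seed controlling initialization and batch order.
#' @param amsgrad Use the AMSGrad second-moment maximum (default TRUE).
#' @param val_fraction Fraction of the training cases held out for
#'   checkpoint selection (default 0.1).
#' @param early_stop_frac Optional: stop once the epoch training loss falls
#'   to this fraction of the first epoch's loss (NULL = run all epochs).
#' @param augment_flips Random axis-flip augmentation of (input, target,
#'   mask) triples during training (default FALSE). Useful in small-cohort
#'   regimes; validation cases are never augmented.
#' @return A `jr_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         epochs = 10L, seed = 1L, amsgrad = TRUE,
                         val_fraction = 0.1, early_stop_frac = NULL,
                         augment_flips = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 amsgrad = amsgrad, val_fraction = val_fraction,
                 early_stop_frac = early_stop_frac,
                 augment_flips = augment_flips),
            class = "jr_train_config")
}

flip_arr <- function(x, flips) {
  d <- dim(x)
  ix <- lapply(1:3, function(ax) if (flips[ax]) d[ax]:1 else seq_len(d[ax]))
  if (length(d) == 4L) x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  else x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), vhat = numeric(n), t = 0L)
}

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, amsgrad = TRUE) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vv <- if (amsgrad) {
    state$vhat <- pmax(state$vhat, state$v)
    state$vhat
  } else state$v
  vhat <- vv / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

prepare_arm_cases <- function(arm, cohort, cfg_prep, multiple) {
  lapply(cohort, function(ph) {
    if (inherits(ph, "jr_phantom"))
      prepare_case(ph, output_space = arm$output_space,
                   paired = arm$input_factor == "paired",
                   cfg = cfg_prep, multiple = multiple)
    else ph
  })
}

#' Train one study arm
#'
#' Minimizes the composite loss over the arm's (input, log2-Jacobian)
#' pairs with Adam/AMSGrad, recording per-epoch training and validation
#' loss and retaining the weights with the best validation loss.
#' Deterministic given the config seed.
#'
#' @param arm A `jr_study_arm`.
#' @param cohort List of `jr_phantom` cases (or prepared cases from
#'   [prepare_case()] matching the arm).
#' @param net_cfg A `jr_net_config`; its `in_channels` is forced to match
#'   the arm.
#' @param loss_cfg A `jr_loss_config`.
#' @param train_cfg A `jr_train_config`.
#' @param prep_cfg A `jr_prep_config` used when `cohort` holds phantoms.
#' @return A `jr_checkpoint`: list with `net`, `arm`, `history`
#'   (data.frame epoch/train_loss/val_loss), `best_epoch`, configs.
#' @export
train_arm <- function(arm, cohort, net_cfg = network_config(),
                      loss_cfg = loss_config(),
                      train_cfg = train_config(),
                      prep_cfg = preprocess_config()) {
  net_cfg$in_channels <- if (arm$input_factor == "paired") 2L else 1L
  multiple <- 2L^(net_cfg$L - 1L)
  cases <- prepare_arm_cases(arm, cohort, prep_cfg, multiple)
  for (cs in cases) {
    if (dim(cs$x)[4] != net_cfg$in_channels)
      stop("arm/input mismatch in prepared cohort")
  }

  n <- length(cases)
  hist_tr <- numeric(0)
  hist_val <- numeric(0)
  with_seed(train_cfg$seed, {
    n_val <- if (n >= 5) max(1L, floor(train_cfg$val_fraction * n)) else 0L
    val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    net <- build_network(net_cfg)
    theta <- net_get_params(net)
    opt <- adam_init(length(theta))
    best_val <- Inf
    best_theta <- theta
    best_epoch <- 0L

    case_loss_grad <- function(cs, want_grad = TRUE) {
      if (want_grad && isTRUE(train_cfg$augment_flips)) {
        flips <- runif(3) < 0.5
        if (any(flips)) {
          cs$x <- flip_arr(cs$x, flips)
          cs$y <- flip_arr(cs$y, flips)
          cs$mask <- flip_arr(cs$mask, flips)
        }
      }
      yhat <- net_forward(net, cs$x)
      lg <- if (want_grad)
        loss_total_grad(cs$y, yhat, cs$mask, loss_cfg)
      else list(value = loss_total(cs$y, yhat, cs$mask, loss_cfg))
      if (want_grad) net_backward(net, lg$grad)
      lg$value
    }

    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + train_cfg$batch_size - 1L, length(ord))]
        net_zero_grads(net)
        bl <- vapply(cases[batch], case_loss_grad, numeric(1))
        if (any(!is.finite(bl))) {
          cond <- structure(
            class = c("jr_divergence", "error", "condition"),
            list(message = sprintf("non-finite loss at epoch %d", ep),
                 call = sys.call(-1),
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train_loss = hist_tr,
                                      val_loss = hist_val)))
          stop(cond)
        }
        grad <- net_get_grads(net) / length(batch)
        st <- adam_step(opt, theta, grad, train_cfg$learning_rate,
                        amsgrad = train_cfg$amsgrad)
        theta <- st$theta
        opt <- st$state
        net_set_params(net, theta)
        ep_losses <- c(ep_losses, mean(bl))
        i <- i + train_cfg$batch_size
      }
      tr_loss <- mean(ep_losses)
      val_loss <- if (length(val_idx) > 0)
        mean(vapply(cases[val_idx], case_loss_grad, numeric(1),
                    want_grad = FALSE))
      else tr_loss
      hist_tr <- c(hist_tr, tr_loss)
      hist_val <- c(hist_val, val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_theta <- theta
        best_epoch <- ep
      }
      if (!is.null(train_cfg$early_stop_frac) &&
          tr_loss <= train_cfg$early_stop_frac * hist_tr[1]) break
    }
    net_set_params(net, best_theta)
  })

  structure(list(net = net, arm = arm,
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train_loss = hist_tr,
                                      val_loss = hist_val),
                 best_epoch = best_epoch,
                 net_cfg = net_cfg, loss_cfg = loss_cfg,
                 train_cfg = train_cfg,
                 val_idx = val_idx, train_idx = tr_idx),
            class = "jr_checkpoint")
}

#' @export
print.jr_checkpoint <- function(x, ...) {
  cat(sprintf("<jr_checkpoint %s> %d epoch(s), best val %.4f @ epoch %d\n",
              arm_id(x$arm), nrow(x$history),
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Weights and configurations are serialized to a JSON file (text format).
#' @param ckpt A `jr_checkpoint`.
#' @param path Output file.
#' @export
save_checkpoint <- function(ckpt, path) {
  obj <- list(theta = net_get_params(ckpt$net),
              net_cfg = unclass(ckpt$net_cfg),
              arm = unclass(ckpt$arm),
              history = ckpt$history,
              best_epoch = ckpt$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$net_cfg[c("L", "base_filters",
                                               "in_channels", "kernel_size",
                                               "norm_epsilon")])
  net <- build_network(cfg, seed = 1L)
  net_set_params(net, as.numeric(obj$theta))
  structure(list(net = net,
                 arm = study_arm(obj$arm$input_factor, obj$arm$output_space),
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch, net_cfg = cfg),
            class = "jr_checkpoint")
}

#' Train all four arms of the 2x2 factorial design
#'
#' Trains {single, paired} x {FRC, TLC} with a shared train/test split
#' (default 90/10) and shared seeds, so the arms are directly comparable.
#'
#' @param cohort List of `jr_phantom` cases.
#' @param net_cfg,loss_cfg,train_cfg,prep_cfg Configurations shared by all
#'   arms.
#' @param test_fraction Held-out fraction (default 0.1).
#' @return A `jr_factorial`: list with `checkpoints` (named by arm id),
#'   `test_idx`, `train_idx`, `split_hash`, and the configs.
#' @export
run_factorial <- function(cohort, net_cfg = network_config(),
                          loss_cfg = loss_config(),
                          train_cfg = train_config(),
                          prep_cfg = preprocess_config(),
                          test_fraction = 0.1) {
  n <- length(cohort)
  stopifnot(n >= 2)
  with_seed(train_cfg$seed, {
    n_test <- max(1L, round(test_fraction * n))
    test_idx <- sort(sample(n, n_test))
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  split_hash <- paste(test_idx, collapse = "-")

  arms <- list(study_arm("single", "FRC"), study_arm("paired", "FRC"),
               study_arm("single", "TLC"), study_arm("paired", "TLC"))
  checkpoints <- list()
  for (arm in arms) {
    ck <- train_arm(arm, cohort[train_idx], net_cfg, loss_cfg, train_cfg,
                    prep_cfg)
    ck$split_hash <- split_hash
    checkpoints[[arm_id(arm)]] <- ck
  }
  structure(list(checkpoints = checkpoints, test_idx = test_idx,
                 train_idx = train_idx, split_hash = split_hash,
                 net_cfg = net_cfg, loss_cfg = loss_cfg,
                 train_cfg = train_cfg),
            class = "jr_factorial")
}
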