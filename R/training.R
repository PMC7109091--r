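## Multi-resolution supervised training, Adam, inference, and the optional
## conditional-adversarial fine-tuning stage for the denoiser.

#' Training configuration
#'
#' @param batch_size Minibatch size (defaults follow the small-batch regime
#'   typical for this architecture family).
#' @param iterations Number of minibatch updates.
#' @param learning_rate Adam step size.
#' @param branch_weights Per-output loss weights, full-resolution head
#'   first; `NULL` means equal weight 1 for every supervised output.
#' @param seed Integer seed controlling batch sampling.
#' @param eval_every Evaluate test MAE every this many iterations (the
#'   final iteration is always evaluated).
#' @param optimizer Only `"adam"` is available.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, iterations = 100L,
                         learning_rate = 1e-3, branch_weights = NULL,
                         seed = 1L, eval_every = 10L,
                         optimizer = c("adam")) {
  optimizer <- match.arg(optimizer)
  if (!is.null(branch_weights)) {
    stopifnot(all(branch_weights >= 0), any(branch_weights > 0))
  }
  structure(list(batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 branch_weights = branch_weights,
                 seed = as.integer(seed),
                 eval_every = as.integer(eval_every),
                 optimizer = optimizer),
            class = "train_config")
}

#' Multi-resolution training loss
#'
#' Weighted sum, over the supervised outputs, of the mean absolute error
#' between each output and the matching level of the target pyramid. It is
#' zero exactly when every output equals its target, and each term is a
#' metric (nonnegative, symmetric, triangle inequality).
#'
#' @param outputs List of output arrays, full resolution first (as returned
#'   by [forward_network()]).
#' @param pyramid A [build_target_pyramid()] with the same number of levels.
#' @param weights Nonnegative per-level weights; `NULL` = all 1.
#' @return Scalar loss.
#' @export
multires_loss <- function(outputs, pyramid, weights = NULL) {
  stopifnot(length(outputs) == length(pyramid))
  if (is.null(weights)) weights <- rep(1, length(outputs))
  stopifnot(length(weights) == length(outputs))
  total <- 0
  for (k in seq_along(outputs)) {
    o <- as_image_array(outputs[[k]]); t <- as_image_array(pyramid[[k]])
    if (!all(dim(o) == dim(t))) {
      stop("output ", k, " has shape ", paste(dim(o), collapse = "x"),
           " but target level has ", paste(dim(t), collapse = "x"))
    }
    total <- total + weights[k] * mean(abs(o - t))
  }
  total
}

# Per-output MAE values and loss gradients for one sample.
multires_terms <- function(outputs, pyramid, weights) {
  terms <- numeric(length(outputs))
  gouts <- vector("list", length(outputs))
  for (k in seq_along(outputs)) {
    o <- outputs[[k]]; t <- pyramid[[k]]
    terms[k] <- mean(abs(o - t))
    if (weights[k] > 0) gouts[[k]] <- weights[k] * sign(o - t) / length(o)
  }
  if (is.null(gouts[[1]])) gouts[[1]] <- array(0, dim(outputs[[1]]))
  list(terms = terms, gouts = gouts)
}

## --- Adam -----------------------------------------------------------------

adam_init <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (layer in names(grads)) {
    g <- grads[[layer]]
    if (is.null(state$m[[layer]])) {
      state$m[[layer]] <- lapply(g, function(x) x * 0)
      state$v[[layer]] <- lapply(g, function(x) x * 0)
    }
    for (nm in names(g)) {
      state$m[[layer]][[nm]] <- beta1 * state$m[[layer]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[layer]][[nm]] <- beta2 * state$v[[layer]][[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- state$m[[layer]][[nm]] / bc1
      vhat <- state$v[[layer]][[nm]] / bc2
      params[[layer]][[nm]] <- params[[layer]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (layer in names(g)) {
    if (is.null(acc[[layer]])) acc[[layer]] <- g[[layer]]
    else for (nm in names(g[[layer]])) {
      acc[[layer]][[nm]] <- acc[[layer]][[nm]] + g[[layer]][[nm]]
    }
  }
  acc
}

scale_grads <- function(g, f) {
  lapply(g, function(layer) lapply(layer, function(x) x * f))
}

## --- Training loop --------------------------------------------------------

dataset_items <- function(dataset) {
  if (inherits(dataset, "mrcnn_dataset")) dataset$items else dataset
}

#' Train a network with multi-resolution supervision
#'
#' Runs minibatch Adam on [multires_loss()]: every supervised output of the
#' network is matched against the corresponding level of the area-average
#' pyramid of its target. The full-resolution test MAE is recorded every
#' `eval_every` iterations, and the parameters achieving the best test MAE
#' are returned as the trained network. With all randomness seeded, two
#' runs produce identical histories.
#'
#' @param net An `mcnn_net` from [build_mcnn()] or [build_unet()].
#' @param dataset An `mrcnn_dataset` (or plain list of `input`/`target`
#'   pairs) whose image sides are divisible by `2^depth`.
#' @param config A [train_config()].
#' @param test_set Optional held-out dataset evaluated at full resolution.
#' @return An object of class `mcnn_train_state`: `network` (best
#'   checkpoint), `final_network`, `history` (a tibble with one row per
#'   iteration: `iteration`, `train_loss`, per-level `loss_level*`, and
#'   `test_mae` where evaluated) and `config`.
#' @export
train_network <- function(net, dataset, config = train_config(),
                          test_set = NULL) {
  items <- dataset_items(dataset)
  n_items <- length(items)
  stopifnot(n_items >= 1)
  levels <- net$spec$n_branches + 1L
  weights <- config$branch_weights %||% rep(1, levels)
  stopifnot(length(weights) == levels)

  pyramids <- lapply(items, function(it) {
    build_target_pyramid(it$target, levels)
  })
  test_items <- if (!is.null(test_set)) dataset_items(test_set)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  state <- adam_init()
  hist_iter <- integer(0); hist_loss <- numeric(0)
  hist_terms <- matrix(numeric(0), ncol = levels)
  hist_test <- numeric(0)
  best_mae <- Inf; best_params <- net$params

  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n_items, config$batch_size, replace = n_items < config$batch_size)
    acc <- NULL; batch_loss <- 0; batch_terms <- numeric(levels)
    for (i in idx) {
      fw <- forward_network(net, items[[i]]$input, cache = TRUE)
      mt <- multires_terms(fw$outputs, pyramids[[i]], weights)
      batch_terms <- batch_terms + mt$terms
      batch_loss <- batch_loss + sum(weights * mt$terms)
      acc <- add_grads(acc, backward_network(net, fw$cache, mt$gouts))
    }
    acc <- scale_grads(acc, 1 / length(idx))
    batch_loss <- batch_loss / length(idx)
    batch_terms <- batch_terms / length(idx)
    if (!is.finite(batch_loss)) {
      stop("training diverged at iteration ", it, " (non-finite loss); ",
           "reduce the learning rate")
    }
    upd <- adam_step(net$params, acc, state, config$learning_rate)
    net$params <- upd$params; state <- upd$state

    hist_iter <- c(hist_iter, it)
    hist_loss <- c(hist_loss, batch_loss)
    hist_terms <- rbind(hist_terms, batch_terms)
    tm <- NA_real_
    if (!is.null(test_items) &&
        (it %% config$eval_every == 0L || it == config$iterations)) {
      tm <- evaluate_mae(net, test_items)
      if (tm <= best_mae) {
        best_mae <- tm; best_params <- net$params
      }
    }
    hist_test <- c(hist_test, tm)
  }

  history <- tibble::tibble(iteration = hist_iter, train_loss = hist_loss)
  for (k in seq_len(levels)) history[[paste0("loss_level", k - 1L)]] <- hist_terms[, k]
  history$test_mae <- hist_test

  best_net <- net
  if (is.null(test_items)) best_params <- net$params
  best_net$params <- best_params
  structure(list(network = best_net, final_network = net, history = history,
                 config = config,
                 final_test_mae = if (length(hist_test)) utils::tail(stats::na.omit(hist_test), 1) else NA_real_,
                 best_test_mae = if (is.finite(best_mae)) best_mae else NA_real_),
            class = "mcnn_train_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean full-resolution MAE of a network over a list of items.
evaluate_mae <- function(net, items) {
  mean(vapply(items, function(it) {
    pred <- forward_network(net, it$input)[[1]]
    mean(abs(pred - as_image_array(it$target)))
  }, numeric(1)))
}

#' @export
print.mcnn_train_state <- function(x, ...) {
  cat(sprintf("<mcnn_train_state> %d iteration(s); final train loss %.4f%s\n",
              nrow(x$history), utils::tail(x$history$train_loss, 1),
              if (!is.na(x$final_test_mae))
                sprintf("; final test MAE %.4f (best %.4f)",
                        x$final_test_mae, x$best_test_mae) else ""))
  invisible(x)
}

#' Predict a full-resolution output image
#'
#' Inference entry point: runs the network and returns only the
#' full-resolution head, discarding the coarse branches. Inputs whose side
#' is not divisible by `2^depth` are reflect-padded and the output cropped
#' back.
#'
#' @param object An `mcnn_net`.
#' @param img Input matrix or H x W x C array.
#' @param ... Unused.
#' @return Output image: a matrix when `output_channels == 1`, else an
#'   array.
#' @export
predict.mcnn_net <- function(object, img, ...) {
  x <- as_image_array(img)
  n <- dim(x)[1]; m <- dim(x)[2]
  d <- 2L^object$spec$depth
  np <- as.integer(ceiling(max(n, m) / d) * d)
  if (np != n || np != m) {
    x <- pad_reflect(x, np)
  }
  out <- forward_network(object, x)[[1]]
  out <- out[seq_len(n), seq_len(m), , drop = FALSE]
  if (dim(out)[3] == 1L) out <- out[, , 1] else out
}

# Reflect-pad an H x W x C array to side `to` (bottom/right).
pad_reflect <- function(x, to) {
  n <- dim(x)[1]; m <- dim(x)[2]
  ridx <- c(seq_len(n), rev(seq_len(n)))[seq_len(to)]
  cidx <- c(seq_len(m), rev(seq_len(m)))[seq_len(to)]
  x[ridx, cidx, , drop = FALSE]
}

## --- Conditional-adversarial fine-tuning ----------------------------------

#' Adversarial fine-tuning configuration
#'
#' @param adversarial_weight Weight of the conditional-adversarial term
#'   added to the MAE generator loss; 0 reduces the stage to continued MAE
#'   training.
#' @param iterations Number of alternating generator/discriminator updates.
#' @param learning_rate Generator step size (kept tiny: this stage refines
#'   an already-trained network).
#' @param disc_learning_rate Discriminator step size.
#' @param batch_size Minibatch size.
#' @param disc_width Channel width of the patch discriminator's first
#'   stage.
#' @param seed Integer seed.
#' @param collapse_floor,collapse_window Abort when the exponential moving
#'   average of the discriminator loss stays below `collapse_floor` for
#'   `collapse_window` consecutive iterations (mode-collapse guard).
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(adversarial_weight = 0.01, iterations = 50L,
                       learning_rate = 1e-5, disc_learning_rate = 1e-4,
                       batch_size = 8L, disc_width = 16L, seed = 1L,
                       collapse_floor = 0.02, collapse_window = 20L) {
  stopifnot(adversarial_weight >= 0, learning_rate > 0)
  structure(list(adversarial_weight = adversarial_weight,
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 disc_learning_rate = disc_learning_rate,
                 batch_size = as.integer(batch_size),
                 disc_width = as.integer(disc_width),
                 seed = as.integer(seed),
                 collapse_floor = collapse_floor,
                 collapse_window = as.integer(collapse_window)),
            class = "gan_config")
}

# Patch discriminator: 2 stride-2 conv stages + linear 3x3 logit map,
# conditioned on the network input (input and candidate are concatenated).
build_discriminator <- function(in_channels, width, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  list(d1 = he_conv(3L, in_channels, width),
       d2 = he_conv(3L, width, 2L * width),
       d3 = he_conv(3L, 2L * width, 1L))
}

disc_forward <- function(dp, x) {
  z1 <- conv_fwd(x, dp$d1, 2L); h1 <- act_fwd(z1, "lrelu")
  z2 <- conv_fwd(h1, dp$d2, 2L); h2 <- act_fwd(z2, "lrelu")
  out <- conv_fwd(h2, dp$d3, 1L)
  list(out = out, x = x, z1 = z1, h1 = h1, z2 = z2, h2 = h2)
}

disc_backward <- function(dp, cache, gout) {
  g3 <- conv_bwd(cache$h2, dp$d3, gout, 1L)
  g2in <- g3$gx * act_mask(cache$z2, "lrelu")
  g2 <- conv_bwd(cache$h1, dp$d2, g2in, 2L)
  g1in <- g2$gx * act_mask(cache$z1, "lrelu")
  g1 <- conv_bwd(cache$x, dp$d1, g1in, 2L)
  list(gx = g1$gx,
       grads = list(d1 = list(W = g1$gw, b = g1$gb),
                    d2 = list(W = g2$gw, b = g2$gb),
                    d3 = list(W = g3$gw, b = g3$gb)))
}

concat_channels <- function(a, b) {
  out <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Conditional-adversarial fine-tuning
#'
#' Refines a trained network with a least-squares conditional GAN: the
#' generator (the network's full-resolution head and trunk; coarse branch
#' heads are frozen) minimises `MAE + adversarial_weight * (D(x, G(x)) -
#' 1)^2` while a patch discriminator conditioned on the input learns to
#' separate predictions from targets. Used by the denoiser to push
#' predicted intensity clusters towards atomic-like shapes.
#'
#' @param net A trained `mcnn_net`.
#' @param dataset Paired dataset as in [train_network()].
#' @param config A [gan_config()].
#' @return The fine-tuned `mcnn_net`, with the alternating-loss history
#'   attached as attribute `"gan_history"` (a tibble with `iteration`,
#'   `g_mae`, `g_adv`, `d_loss`).
#' @export
finetune_gan <- function(net, dataset, config = gan_config()) {
  items <- dataset_items(dataset)
  n_items <- length(items)
  cond_ch <- net$spec$input_channels + net$spec$output_channels
  dp <- build_discriminator(cond_ch, config$disc_width, config$seed + 1L)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  g_state <- adam_init(); d_state <- adam_init()
  ema_d <- NA_real_
  low_run <- 0L
  hist <- list()

  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n_items, config$batch_size, replace = n_items < config$batch_size)
    g_acc <- NULL; d_acc <- NULL
    g_mae <- 0; g_adv <- 0; d_loss <- 0
    for (i in idx) {
      x <- as_image_array(items[[i]]$input)
      target <- as_image_array(items[[i]]$target)
      fw <- forward_network(net, x, cache = TRUE)
      pred <- fw$outputs[[1]]
      npx <- length(pred)

      gout <- sign(pred - target) / npx
      g_mae <- g_mae + mean(abs(pred - target))
      if (config$adversarial_weight > 0) {
        dc <- disc_forward(dp, concat_channels(x, pred))
        nd <- length(dc$out)
        g_adv <- g_adv + mean((dc$out - 1)^2)
        db <- disc_backward(dp, dc, 2 * (dc$out - 1) / nd)
        gpred <- db$gx[, , net$spec$input_channels + seq_len(dim(pred)[3]), drop = FALSE]
        gout <- gout + config$adversarial_weight * gpred
      }
      gouts <- vector("list", net$spec$n_branches + 1L)
      gouts[[1]] <- gout
      gg <- backward_network(net, fw$cache, gouts)
      gg[grep("^br", names(gg))] <- NULL  # coarse heads frozen in this stage
      g_acc <- add_grads(g_acc, gg)

      if (config$adversarial_weight > 0) {
        # discriminator update terms (prediction treated as constant)
        dreal <- disc_forward(dp, concat_channels(x, target))
        dfake <- disc_forward(dp, concat_channels(x, pred))
        nd <- length(dreal$out)
        d_loss <- d_loss + mean((dreal$out - 1)^2) + mean(dfake$out^2)
        d_acc <- add_grads(d_acc, disc_backward(dp, dreal, 2 * (dreal$out - 1) / nd)$grads)
        d_acc <- add_grads(d_acc, disc_backward(dp, dfake, 2 * dfake$out / nd)$grads)
      }
    }
    nb <- length(idx)
    upd <- adam_step(net$params, scale_grads(g_acc, 1 / nb), g_state,
                     config$learning_rate)
    net$params <- upd$params; g_state <- upd$state
    if (config$adversarial_weight > 0) {
      dupd <- adam_step(dp, scale_grads(d_acc, 1 / nb), d_state,
                        config$disc_learning_rate)
      dp <- dupd$params; d_state <- dupd$state
    }
    d_loss <- d_loss / nb
    ema_d <- if (is.na(ema_d)) d_loss else 0.9 * ema_d + 0.1 * d_loss
    low_run <- if (config$adversarial_weight > 0 && ema_d < config$collapse_floor)
      low_run + 1L else 0L
    if (low_run >= config$collapse_window) {
      stop("adversarial fine-tuning aborted: discriminator loss collapsed ",
           "below ", config$collapse_floor, " for ", low_run, " iterations")
    }
    hist[[it]] <- c(iteration = it, g_mae = g_mae / nb, g_adv = g_adv / nb,
                    d_loss = d_loss)
  }
  attr(net, "gan_history") <- tibble::as_tibble(do.call(rbind, hist))
  net
}
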