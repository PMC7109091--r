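## Network construction and forward evaluation.
##
## A network is a plain list: spec (mcnn_spec), params (named list of layer
## parameter lists, each holding arrays W/b), and, when the spec asks for it,
## the sum-normalised fixed LPF kernels. All images are H x W x C arrays.

as_image_array <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

conv_fwd <- function(x, p, stride = 1L) {
  k <- dim(p$W)[1]
  .conv2d_fwd(x, as.numeric(p$W), p$b, k, dim(p$W)[4], as.integer(stride),
              (k - 1L) %/% 2L)
}

conv_bwd <- function(x, p, gout, stride = 1L) {
  k <- dim(p$W)[1]
  g <- .conv2d_bwd(x, as.numeric(p$W), gout, k, as.integer(stride),
                   (k - 1L) %/% 2L)
  g$gw <- array(g$gw, dim(p$W))
  g$gb <- as.numeric(g$gb)
  g
}

tconv_fwd <- function(x, p) .tconv2_fwd(x, as.numeric(p$W), p$b, dim(p$W)[4])

tconv_bwd <- function(x, p, gout) {
  g <- .tconv2_bwd(x, as.numeric(p$W), gout)
  g$gw <- array(g$gw, dim(p$W))
  g$gb <- as.numeric(g$gb)
  g
}

act_fwd <- function(z, activation) {
  if (activation == "lrelu") z * (0.2 + 0.8 * (z > 0)) else z * (z > 0)
}

act_mask <- function(z, activation) {
  if (activation == "lrelu") 0.2 + 0.8 * (z > 0) else (z > 0) * 1
}

stage_widths <- function(spec) pmin(spec$base_width * 2L^(seq_len(spec$depth) - 1L), 512L)

# decoder stage output channels, indexed by stage s = 1..depth
decoder_widths <- function(spec) {
  w <- stage_widths(spec)
  c(spec$base_width, w[seq_len(spec$depth - 1L)])
}

effective_in_channels <- function(spec) {
  spec$input_channels * (1L + if (spec$use_lpf_layer) 4L else 0L)
}

he_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

he_tconv <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = array(stats::rnorm(4 * cin * cout, sd = sd), c(2, 2, cin, cout)),
       b = numeric(cout))
}

bottleneck_init <- function(ch) {
  r <- max(ch %/% 2L, 4L)
  c1 <- he_conv(1L, ch, r); c2 <- he_conv(3L, r, r); c3 <- he_conv(1L, r, ch)
  list(W1 = c1$W, b1 = c1$b, W2 = c2$W, b2 = c2$b, W3 = c3$W, b3 = c3$b)
}

#' Build a multi-resolution network (or its U-Net baseline)
#'
#' `build_mcnn()` constructs the network described by an [mcnn_spec()]:
#' an encoder of `depth` stride-2 convolution stages, a mirrored decoder of
#' stride-2 up-convolutions with skip connections, a full-resolution output
#' head, and one extra 3x3 convolution head per coarse branch attached to
#' the decoder feature of matching resolution. `build_unet()` forces
#' `n_branches = 0`, yielding the plain single-output U-Net used as the
#' comparison baseline; with the same `seed`, all layers shared between the
#' two networks are initialised bit-identically.
#'
#' @param spec An [mcnn_spec()].
#' @return An object of class `mcnn_net` with elements `spec`, `params`
#'   (named list of weight arrays) and `parameter_count`.
#' @examples
#' net <- build_mcnn(mcnn_spec(depth = 3, n_branches = 2, base_width = 4))
#' out <- forward_network(net, matrix(0, 32, 32))
#' sapply(out, function(o) dim(o)[1])  # 32 16 8
#' @export
build_mcnn <- function(spec) {
  validate_mcnn_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  w <- stage_widths(spec)
  v <- decoder_widths(spec)
  c0 <- effective_in_channels(spec)
  D <- spec$depth
  params <- list()

  cin <- c0
  for (s in seq_len(D)) {
    params[[paste0("enc", s)]] <- he_conv(3L, cin, w[s])
    if (spec$cell == "bottleneck") params[[paste0("encb", s)]] <- bottleneck_init(w[s])
    cin <- w[s]
  }
  for (s in rev(seq_len(D))) {
    cin_up <- if (s == D) w[D] else v[s + 1L]
    skip_ch <- if (s >= 2L) w[s - 1L] else c0
    params[[paste0("up", s)]] <- he_tconv(cin_up, v[s])
    params[[paste0("dec", s)]] <- he_conv(3L, v[s] + skip_ch, v[s])
    if (spec$cell == "bottleneck") params[[paste0("decb", s)]] <- bottleneck_init(v[s])
  }
  params[["head0"]] <- he_conv(3L, v[1L], spec$output_channels)
  if (spec$n_branches > 0L) {
    for (k in seq_len(spec$n_branches)) {
      # decoder feature at side n / 2^k has v[k + 1] channels
      params[[paste0("br", k)]] <- he_conv(3L, v[k + 1L], spec$output_channels)
    }
  }

  net <- list(spec = spec, params = params,
              lpf = if (spec$use_lpf_layer) lpf_bank_normalized() else NULL)
  class(net) <- "mcnn_net"
  net$parameter_count <- count_parameters(net)
  net
}

#' @rdname build_mcnn
#' @export
build_unet <- function(spec) {
  spec$n_branches <- 0L
  build_mcnn(spec)
}

#' Count trainable parameters
#'
#' Sums all trainable scalar weights of a network. The fixed low-pass
#' kernels of the LPF input layer are not trainable and are excluded, so a
#' network with and without the LPF layer differs in input-channel fan-in
#' of the first stage but the kernels themselves add nothing.
#'
#' @param net An `mcnn_net`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, function(p) sum(lengths(p)), numeric(1)))
}

#' @export
print.mcnn_net <- function(x, ...) {
  cat(sprintf("<mcnn_net> %s cells, depth %d, %d supervised output(s), %s trainable parameters\n",
              x$spec$cell, x$spec$depth, x$spec$n_branches + 1L,
              format(x$parameter_count, big.mark = ",")))
  invisible(x)
}

apply_lpf_layer <- function(x, kernels) {
  chans <- list(x)
  cin <- dim(x)[3]
  for (f in kernels) {
    k <- nrow(f)
    p <- list(W = array(f, c(k, k, 1L, 1L)), b = 0)
    filt <- array(0, dim(x))
    for (ci in seq_len(cin)) {
      filt[, , ci] <- conv_fwd(x[, , ci, drop = FALSE], p, 1L)
    }
    chans[[length(chans) + 1L]] <- filt
  }
  xs <- array(0, c(dim(x)[1:2], cin * length(chans)))
  for (i in seq_along(chans)) {
    xs[, , ((i - 1L) * cin + 1L):(i * cin)] <- chans[[i]]
  }
  xs
}

bottleneck_fwd <- function(a, p, activation) {
  z1 <- conv_fwd(a, list(W = p$W1, b = p$b1), 1L); h1 <- act_fwd(z1, activation)
  z2 <- conv_fwd(h1, list(W = p$W2, b = p$b2), 1L); h2 <- act_fwd(z2, activation)
  h3 <- conv_fwd(h2, list(W = p$W3, b = p$b3), 1L)
  zs <- a + h3
  list(out = act_fwd(zs, activation), a = a, z1 = z1, h1 = h1, z2 = z2,
       h2 = h2, zs = zs)
}

bottleneck_bwd <- function(g, cache, p, activation) {
  gs <- g * act_mask(cache$zs, activation)
  g3 <- conv_bwd(cache$h2, list(W = p$W3, b = p$b3), gs, 1L)
  g2in <- g3$gx * act_mask(cache$z2, activation)
  g2 <- conv_bwd(cache$h1, list(W = p$W2, b = p$b2), g2in, 1L)
  g1in <- g2$gx * act_mask(cache$z1, activation)
  g1 <- conv_bwd(cache$a, list(W = p$W1, b = p$b1), g1in, 1L)
  list(gx = gs + g1$gx,
       grads = list(W1 = g1$gw, b1 = g1$gb, W2 = g2$gw, b2 = g2$gb,
                    W3 = g3$gw, b3 = g3$gb))
}

#' Evaluate a network on one image
#'
#' Runs a forward pass and returns every supervised output: element 1 is
#' the full-resolution prediction (side n), element k + 1 the k-th coarse
#' output (side n / 2^k). Inference-time prediction that discards the
#' coarse heads is available via [predict.mcnn_net()].
#'
#' @param net An `mcnn_net`.
#' @param x Input image: an H x W matrix or H x W x C array with C equal to
#'   the spec's `input_channels`; H and W must be divisible by `2^depth`.
#' @param cache Keep intermediate activations (used by the training loop).
#' @return A list of `n_branches + 1` output arrays (with `cache = TRUE`, a
#'   list with elements `outputs` and `cache`).
#' @export
forward_network <- function(net, x, cache = FALSE) {
  spec <- net$spec
  x <- as_image_array(x)
  if (dim(x)[3] != spec$input_channels) {
    stop("input has ", dim(x)[3], " channel(s); spec expects ", spec$input_channels)
  }
  n <- dim(x)[1]
  if (dim(x)[2] != n || n %% (2L^spec$depth) != 0L) {
    stop("input side must be square and divisible by 2^depth = ", 2L^spec$depth)
  }
  act <- spec$activation
  D <- spec$depth
  P <- net$params

  x0 <- if (spec$use_lpf_layer) apply_lpf_layer(x, net$lpf) else x
  enc <- vector("list", D)       # stage outputs
  enc_z <- vector("list", D)     # pre-activations
  enc_in <- vector("list", D)
  enc_bc <- vector("list", D)
  f <- x0
  for (s in seq_len(D)) {
    enc_in[[s]] <- f
    z <- conv_fwd(f, P[[paste0("enc", s)]], 2L)
    enc_z[[s]] <- z
    a <- act_fwd(z, act)
    if (spec$cell == "bottleneck") {
      bc <- bottleneck_fwd(a, P[[paste0("encb", s)]], act)
      enc_bc[[s]] <- bc
      a <- bc$out
    }
    enc[[s]] <- a
    f <- a
  }

  dec <- vector("list", D)       # decoder stage outputs, index s -> side n/2^(s-1)
  up_z <- vector("list", D); up_in <- vector("list", D)
  cat_in <- vector("list", D); dec_z <- vector("list", D); dec_bc <- vector("list", D)
  for (s in rev(seq_len(D))) {
    up_in[[s]] <- f
    zu <- tconv_fwd(f, P[[paste0("up", s)]])
    up_z[[s]] <- zu
    u <- act_fwd(zu, act)
    skip <- if (s >= 2L) enc[[s - 1L]] else x0
    cc <- array(0, c(dim(u)[1:2], dim(u)[3] + dim(skip)[3]))
    cc[, , seq_len(dim(u)[3])] <- u
    cc[, , dim(u)[3] + seq_len(dim(skip)[3])] <- skip
    cat_in[[s]] <- cc
    zd <- conv_fwd(cc, P[[paste0("dec", s)]], 1L)
    dec_z[[s]] <- zd
    a <- act_fwd(zd, act)
    if (spec$cell == "bottleneck") {
      bc <- bottleneck_fwd(a, P[[paste0("decb", s)]], act)
      dec_bc[[s]] <- bc
      a <- bc$out
    }
    dec[[s]] <- a
    f <- a
  }

  outputs <- vector("list", spec$n_branches + 1L)
  outputs[[1L]] <- conv_fwd(dec[[1L]], P[["head0"]], 1L)
  if (spec$n_branches > 0L) {
    for (k in seq_len(spec$n_branches)) {
      outputs[[k + 1L]] <- conv_fwd(dec[[k + 1L]], P[[paste0("br", k)]], 1L)
    }
  }
  if (!cache) return(outputs)
  list(outputs = outputs,
       cache = list(x0 = x0, enc = enc, enc_z = enc_z, enc_in = enc_in,
                    enc_bc = enc_bc, dec = dec, up_z = up_z, up_in = up_in,
                    cat_in = cat_in, dec_z = dec_z, dec_bc = dec_bc))
}

# Backward pass. gouts: list of gradients w.r.t. each supervised output
# (same ordering as forward_network outputs; NULL entries are skipped).
# Returns a list of gradients with the same structure as net$params.
backward_network <- function(net, cache, gouts) {
  spec <- net$spec
  act <- spec$activation
  D <- spec$depth
  P <- net$params
  grads <- list()

  gdec <- vector("list", D)  # gradient w.r.t. each decoder stage output
  gh <- conv_bwd(cache$dec[[1L]], P[["head0"]], gouts[[1L]], 1L)
  grads[["head0"]] <- list(W = gh$gw, b = gh$gb)
  gdec[[1L]] <- gh$gx
  if (spec$n_branches > 0L) {
    for (k in seq_len(spec$n_branches)) {
      if (is.null(gouts[[k + 1L]])) next
      gb <- conv_bwd(cache$dec[[k + 1L]], P[[paste0("br", k)]], gouts[[k + 1L]], 1L)
      grads[[paste0("br", k)]] <- list(W = gb$gw, b = gb$gb)
      gdec[[k + 1L]] <- gb$gx
    }
  }

  genc <- vector("list", D)  # gradient w.r.t. encoder stage outputs
  for (s in seq_len(D)) {
    g <- gdec[[s]]
    if (is.null(g)) g <- array(0, dim(cache$dec[[s]]))
    if (spec$cell == "bottleneck") {
      bb <- bottleneck_bwd(g, cache$dec_bc[[s]], P[[paste0("decb", s)]], act)
      grads[[paste0("decb", s)]] <- bb$grads
      g <- bb$gx
    }
    g <- g * act_mask(cache$dec_z[[s]], act)
    gd <- conv_bwd(cache$cat_in[[s]], P[[paste0("dec", s)]], g, 1L)
    grads[[paste0("dec", s)]] <- list(W = gd$gw, b = gd$gb)
    cu <- dim(cache$up_z[[s]])[3]
    gu <- gd$gx[, , seq_len(cu), drop = FALSE]
    gskip <- gd$gx[, , -seq_len(cu), drop = FALSE]
    if (s >= 2L) {
      genc[[s - 1L]] <- if (is.null(genc[[s - 1L]])) gskip else genc[[s - 1L]] + gskip
    }
    gu <- gu * act_mask(cache$up_z[[s]], act)
    gt <- tconv_bwd(cache$up_in[[s]], P[[paste0("up", s)]], gu)
    grads[[paste0("up", s)]] <- list(W = gt$gw, b = gt$gb)
    if (s == D) {
      genc[[D]] <- if (is.null(genc[[D]])) gt$gx else genc[[D]] + gt$gx
    } else {
      gdec[[s + 1L]] <- if (is.null(gdec[[s + 1L]])) gt$gx else gdec[[s + 1L]] + gt$gx
    }
  }

  for (s in rev(seq_len(D))) {
    g <- genc[[s]]
    if (spec$cell == "bottleneck") {
      bb <- bottleneck_bwd(g, cache$enc_bc[[s]], P[[paste0("encb", s)]], act)
      grads[[paste0("encb", s)]] <- bb$grads
      g <- bb$gx
    }
    g <- g * act_mask(cache$enc_z[[s]], act)
    ge <- conv_bwd(cache$enc_in[[s]], P[[paste0("enc", s)]], g, 2L)
    grads[[paste0("enc", s)]] <- list(W = ge$gw, b = ge$gb)
    if (s >= 2L) {
      genc[[s - 1L]] <- if (is.null(genc[[s - 1L]])) ge$gx else genc[[s - 1L]] + ge$gx
    }
  }
  grads
}
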