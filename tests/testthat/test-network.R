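test_that("the output ladder halves exactly at each coarse branch", {
  net <- build_mcnn(mcnn_spec(depth = 3, n_branches = 2, base_width = 4, seed = 1))
  out <- forward_network(net, matrix(0.5, 64, 64))
  expect_length(out, 3L)
  # independent walk of the layer graph: sides n / 2^k
  expect_equal(sapply(out, function(o) dim(o)[1]), 64 / 2^(0:2))
  expect_equal(sapply(out, function(o) dim(o)[2]), 64 / 2^(0:2))
})

test_that("input sides not divisible by 2^depth are rejected at forward time", {
  net <- build_mcnn(mcnn_spec(depth = 3, n_branches = 0, base_width = 2, seed = 1))
  expect_error(forward_network(net, matrix(0, 20, 20)), "divisible")
  expect_error(forward_network(net, matrix(0, 16, 24)), "divisible")
})

test_that("spec invariants are enforced", {
  expect_error(mcnn_spec(depth = 0), "depth")
  expect_error(mcnn_spec(depth = 3, n_branches = 3), "n_branches")
  expect_silent(mcnn_spec(depth = 8, n_branches = 7, base_width = 1))
})

test_that("a zero-branch network is exactly the U-Net baseline", {
  spec <- mcnn_spec(depth = 2, n_branches = 0, base_width = 4, seed = 11)
  a <- build_mcnn(spec)
  b <- build_unet(mcnn_spec(depth = 2, n_branches = 1, base_width = 4, seed = 11))
  expect_identical(a$params, b$params)
  expect_identical(count_parameters(a), count_parameters(b))
  x <- seeded_image(16, seed = 3)
  expect_identical(forward_network(a, x), forward_network(b, x))
  expect_length(forward_network(b, x), 1L)
})

test_that("shared layers of MCNN and U-Net are bit-identical under a shared seed", {
  spec <- mcnn_spec(depth = 3, n_branches = 2, base_width = 4, seed = 5)
  mcnn <- build_mcnn(spec)
  unet <- build_unet(spec)
  shared <- names(unet$params)
  expect_identical(mcnn$params[shared], unet$params)
  expect_gt(count_parameters(mcnn), count_parameters(unet))
})

test_that("parameter counting equals an exhaustive traversal of the weight tensors", {
  for (cell in c("plain", "bottleneck")) {
    net <- build_mcnn(mcnn_spec(depth = 2, n_branches = 1, base_width = 3,
                                cell = cell, seed = 2))
    expect_equal(count_parameters(net), length(unlist(net$params)))
  }
  # hand count for one 3x3 conv, 1 -> 1 channels with bias: 9 + 1
  expect_equal(sum(lengths(mrcnn_ns$he_conv(3L, 1L, 1L))), 10)
})

test_that("the fixed LPF kernels are not trainable", {
  spec_lpf <- mcnn_spec(depth = 2, n_branches = 0, base_width = 4,
                        use_lpf_layer = TRUE, seed = 1)
  net <- build_mcnn(spec_lpf)
  # the four kernels never appear among the trainable arrays; the only
  # difference against the LPF-free twin is the first-stage fan-in
  expect_false(any(grepl("lpf", names(net$params))))
  plain <- build_mcnn(mcnn_spec(depth = 2, n_branches = 0, base_width = 4, seed = 1))
  extra <- count_parameters(net) - count_parameters(plain)
  # 4 extra input channels feed enc1 and the full-resolution skip into dec1;
  # the kernels themselves contribute nothing
  expect_equal(extra, 2 * (3 * 3 * 4 * 4))
})

test_that("forward pass is deterministic and the LPF layer preserves intensity range", {
  net <- build_mcnn(mcnn_spec(depth = 2, n_branches = 1, base_width = 4,
                              use_lpf_layer = TRUE, seed = 9))
  x <- seeded_image(16, seed = 4)
  expect_identical(forward_network(net, x), forward_network(net, x))
  xs <- mrcnn_ns$apply_lpf_layer(mrcnn_ns$as_image_array(x), net$lpf)
  expect_equal(dim(xs)[3], 5L)
  expect_lte(max(xs), max(x) + 1e-12)
  expect_gte(min(xs), 0 - 1e-12)
})

test_that("backpropagation matches finite differences on a tiny network", {
  for (cell in c("plain", "bottleneck")) {
    spec <- mcnn_spec(depth = 2, n_branches = 1, base_width = 3, cell = cell,
                      use_lpf_layer = (cell == "plain"), seed = 7)
    net <- build_mcnn(spec)
    set.seed(42)
    x <- array(runif(64), c(8, 8, 1))
    pyr <- build_target_pyramid(matrix(runif(64), 8, 8), 2)
    w <- c(1, 0.5)
    fw <- forward_network(net, x, cache = TRUE)
    mt <- mrcnn_ns$multires_terms(fw$outputs, pyr, w)
    grads <- mrcnn_ns$backward_network(net, fw$cache, mt$gouts)
    loss_at <- function(net) multires_loss(forward_network(net, x), pyr, w)
    eps <- 1e-6
    for (layer in c("enc1", "up2", "dec1", "head0", "br1")) {
      g <- grads[[layer]]
      for (nm in names(g)) {
        i <- sample(length(g[[nm]]), 1)
        np <- net
        np$params[[layer]][[nm]][i] <- np$params[[layer]][[nm]][i] + eps
        lp <- loss_at(np)
        np$params[[layer]][[nm]][i] <- np$params[[layer]][[nm]][i] - 2 * eps
        lm <- loss_at(np)
        expect_equal(g[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-3)
      }
    }
  }
})

test_that("architecture specs round-trip through plain-text config files", {
  spec <- mcnn_spec(depth = 3, n_branches = 2, base_width = 8, cell = "bottleneck",
                    use_lpf_layer = TRUE, seed = 123)
  path <- tempfile(fileext = ".yml")
  write_mcnn_spec(spec, path)
  expect_identical(read_mcnn_spec(path), spec)
})
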