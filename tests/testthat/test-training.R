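toy_dataset <- function(n, side = 16, seed = 1) {
  sample_training_set("laplacian", n, seed = seed, side = side)
}

test_that("multires_loss equals an independently re-summed weighted MAE", {
  set.seed(3)
  pyr <- build_target_pyramid(matrix(runif(256), 16, 16), 3)
  outputs <- lapply(pyr, function(t) t + array(rnorm(length(t), sd = 0.3), dim(t)))
  w <- c(2, 1, 0.5)
  oracle <- 0
  for (k in 1:3) oracle <- oracle + w[k] * mean(abs(outputs[[k]] - pyr[[k]]))
  expect_equal(multires_loss(outputs, pyr, w), oracle)

  expect_equal(multires_loss(pyr, pyr, w), 0)
  # single level, constant offset
  one <- build_target_pyramid(matrix(0.2, 8, 8), 1)
  expect_equal(multires_loss(list(one[[1]] + 0.3), one, 2), 0.3 * 2)
  expect_error(multires_loss(list(matrix(0, 4, 4)), one), "shape|4x4")
})

test_that("a zero learning rate leaves the loss history constant", {
  ds <- toy_dataset(4)
  net <- build_mcnn(mcnn_spec(depth = 2, n_branches = 1, base_width = 4, seed = 2))
  st <- train_network(net, ds, train_config(batch_size = 4, iterations = 5,
                                            learning_rate = 0, seed = 1))
  expect_equal(length(unique(round(st$history$train_loss, 12))), 1L)
})

test_that("training is reproducible given a fixed seed", {
  ds <- toy_dataset(6)
  spec <- mcnn_spec(depth = 2, n_branches = 1, base_width = 4, seed = 3)
  cfg <- train_config(batch_size = 2, iterations = 8, learning_rate = 1e-3,
                      seed = 5, eval_every = 4)
  s1 <- train_network(build_mcnn(spec), ds, cfg, test_set = toy_dataset(2, seed = 9))
  s2 <- train_network(build_mcnn(spec), ds, cfg, test_set = toy_dataset(2, seed = 9))
  expect_identical(s1$history, s2$history)
  expect_identical(s1$network$params, s2$network$params)
})

test_that("zeroing the coarse-branch weights reproduces plain U-Net training", {
  ds <- toy_dataset(6, seed = 2)
  te <- toy_dataset(3, seed = 8)
  spec <- mcnn_spec(depth = 2, n_branches = 1, base_width = 4, seed = 4)
  cfg_m <- train_config(batch_size = 2, iterations = 10, learning_rate = 1e-3,
                        seed = 6, eval_every = 5, branch_weights = c(1, 0))
  cfg_u <- train_config(batch_size = 2, iterations = 10, learning_rate = 1e-3,
                        seed = 6, eval_every = 5)
  sm <- train_network(build_mcnn(spec), ds, cfg_m, test_set = te)
  su <- train_network(build_unet(spec), ds, cfg_u, test_set = te)
  # identical update trajectory on every shared layer
  shared <- names(su$final_network$params)
  expect_equal(sm$final_network$params[shared], su$final_network$params,
               tolerance = 1e-12)
  expect_equal(sm$history$test_mae, su$history$test_mae, tolerance = 1e-12)
  # the untouched branch head keeps its initial weights
  init <- build_mcnn(spec)
  expect_identical(sm$final_network$params$br1, init$params$br1)
})

test_that("training reduces the loss on the toy task and records per-branch terms", {
  ds <- toy_dataset(12, seed = 3)
  net <- build_mcnn(mcnn_spec(depth = 2, n_branches = 1, base_width = 8, seed = 1))
  st <- train_network(net, ds, train_config(batch_size = 4, iterations = 40,
                                            learning_rate = 1e-3, seed = 2))
  h <- st$history
  expect_named(h, c("iteration", "train_loss", "loss_level0", "loss_level1",
                    "test_mae"))
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
  # smoothed loss decreases across the run for default settings
  ema <- stats::filter(h$train_loss, rep(1 / 10, 10), sides = 1)
  ema <- ema[!is.na(ema)]
  expect_lt(tail(ema, 1), head(ema, 1))
})

test_that("divergence aborts with a diagnostic", {
  ds <- toy_dataset(4)
  net <- build_mcnn(mcnn_spec(depth = 2, n_branches = 1, base_width = 4, seed = 2))
  net$params$head0$W[] <- 1e300
  net$params$head0$b[] <- 1e300
  expect_error(
    train_network(net, ds, train_config(batch_size = 2, iterations = 5,
                                        learning_rate = 1e10, seed = 1)),
    "diverged")
})

test_that("prediction keeps only the full-resolution head and handles odd sizes", {
  net <- build_mcnn(mcnn_spec(depth = 2, n_branches = 1, base_width = 4, seed = 6))
  img <- seeded_image(16, seed = 12)
  p <- predict(net, img)
  expect_equal(dim(p), c(16L, 16L))
  expect_equal(p, forward_network(net, img)[[1]][, , 1])
  # reproducible and deterministic
  expect_identical(predict(net, img), p)
  # side not divisible by 2^depth: reflect-pad then crop back
  odd <- seeded_image(15, seed = 13)
  expect_equal(dim(predict(net, odd)), c(15L, 15L))
})

test_that("tidy, glance and autoplot expose the training history", {
  ds <- toy_dataset(4)
  net <- build_unet(mcnn_spec(depth = 2, base_width = 4, n_branches = 0, seed = 2))
  st <- train_network(net, ds, train_config(batch_size = 2, iterations = 6,
                                            learning_rate = 1e-3, seed = 3),
                      test_set = toy_dataset(2, seed = 5))
  td <- tidy(st)
  expect_true(all(c("iteration", "metric", "value") %in% names(td)))
  gl <- glance(st)
  expect_equal(gl$iterations, 6L)
  expect_true(is.finite(gl$final_test_mae))
  expect_s3_class(autoplot(st), "ggplot")
})
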