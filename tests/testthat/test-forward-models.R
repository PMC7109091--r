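make_wave <- function(side = 32, seed = 1) {
  set.seed(seed)
  amp <- matrix(runif(side^2, 0.5, 1), side, side)
  ph <- matrix(rnorm(side^2, sd = 0.5), side, side)
  wave_field(amp, ph, pixel_size = 1, wavelength = 0.5)
}

test_that("propagation is the identity at z = 0 and leaves a plane wave unchanged", {
  w <- make_wave()
  expect_identical(propagate(w, 0), w)
  plane <- wave_field(matrix(1, 16, 16), matrix(0.3, 16, 16))
  out <- propagate(plane, 25)
  expect_equal(out$amplitude, plane$amplitude, tolerance = 1e-10)
})

test_that("propagation conserves total intensity and composes over distances", {
  w <- make_wave(side = 32, seed = 2)
  for (z in c(-40, 7.5, 31)) {
    out <- propagate(w, z)
    # Parseval oracle: energy computed independently in the frequency domain
    spec_energy <- sum(Mod(stats::fft(mrcnn_ns$wave_complex(w)))^2) / 32^2
    expect_equal(sum(out$amplitude^2), spec_energy, tolerance = 1e-6)
    expect_equal(sum(out$amplitude^2), sum(w$amplitude^2), tolerance = 1e-6)
  }
  one_hop <- propagate(w, 12)
  two_hop <- propagate(propagate(w, 4.5), 7.5)
  expect_equal(mrcnn_ns$wave_complex(two_hop), mrcnn_ns$wave_complex(one_hop),
               tolerance = 1e-5)
})

test_that("defocus beyond the alias-free range raises a warning", {
  w <- make_wave(16)
  expect_warning(propagate(w, 1e5), "alias")
})

test_that("an in-focus pure phase object is invisible and defocus pairs mirror its contrast", {
  side <- 32
  set.seed(3)
  ph <- 0.4 * random_texture(side)
  w <- wave_field(matrix(1, side, side), ph, pixel_size = 1, wavelength = 0.5)
  optics <- optics_params(c(-5, 0, 5), wavelength = 0.5, pixel_size = 1)
  stack <- simulate_defocus_series(w, optics, noise = NULL)
  # z = 0: featureless unit contrast
  expect_equal(stack[, , 2], matrix(1, side, side), tolerance = 1e-10)
  # transport-of-intensity oracle: the antisymmetric part of a +/-z pair is
  # proportional to minus the phase Laplacian
  diff_pair <- stack[, , 3] - stack[, , 1]
  lap <- mrcnn_ns$laplacian5(ph)
  expect_gt(cor(as.vector(diff_pair), as.vector(-lap)), 0.9)
})

test_that("flat-amplitude zero-phase series reproduces the squared amplitude at every plane", {
  side <- 16
  w <- wave_field(matrix(2, side, side), matrix(0, side, side))
  optics <- optics_params(c(-3, 1, 8))
  stack <- simulate_defocus_series(w, optics, noise = NULL)
  for (k in 1:3) expect_equal(stack[, , k], matrix(4, side, side), tolerance = 1e-9)
})

test_that("the exponential defocus geometry spans the requested symmetric range", {
  z <- exponential_defocus_planes(51, z_max = 500, z_min = 1)
  expect_length(z, 51)
  expect_equal(min(z), -500)
  expect_equal(max(z), 500)
  expect_true(0 %in% z)
  expect_equal(z, -rev(z))

  # a through-focus acquisition over these planes yields a 51-image stack
  w <- wave_field(matrix(1, 16, 16), 0.2 * seeded_image(16, seed = 2),
                  pixel_size = 4, wavelength = 0.5e-3)
  stack <- simulate_defocus_series(w, optics_params(z, wavelength = 0.5e-3,
                                                    pixel_size = 4),
                                   noise = NULL)
  expect_equal(dim(stack), c(16L, 16L, 51L))
})

test_that("atomic images match a brute-force convolution of the pulse map", {
  side <- 32
  set.seed(8)
  pos <- cbind(sample(5:28, 6), sample(5:28, 6))  # integer positions
  inten <- runif(6, 0.4, 1)
  scene <- atom_scene(pos, peak_sigma = 2, intensities = inten, canvas_side = side)
  img <- simulate_adf(scene)

  # oracle: pulse image convolved (brute force, full loops) with the kernel
  pulse <- matrix(0, side, side)
  for (a in seq_len(nrow(pos))) pulse[pos[a, 1], pos[a, 2]] <- pulse[pos[a, 1], pos[a, 2]] + inten[a]
  ref <- matrix(0, side, side)
  for (r in 1:side) for (c in 1:side) {
    acc <- 0
    for (rr in 1:side) for (cc in 1:side) {
      acc <- acc + pulse[rr, cc] * exp(-((r - rr)^2 + (c - cc)^2) / (2 * 2^2))
    }
    ref[r, c] <- acc
  }
  ref <- ref / max(ref)
  expect_equal(img, ref, tolerance = 1e-12)
})

test_that("atomic rendering is linear in scene intensities and peaks where atoms sit", {
  one <- atom_scene(cbind(17, 17), peak_sigma = 2, canvas_side = 33)
  img <- simulate_adf(one)
  expect_equal(which(img == max(img)), which(matrix(seq_len(33^2), 33) == 17 + 16 * 33))
  two <- atom_scene(rbind(c(8, 8), c(25, 25)), peak_sigma = 1.5, canvas_side = 32)
  img2 <- simulate_adf(two)
  expect_equal(img2[8, 8], img2[25, 25], tolerance = 1e-6)
  # doubling all intensities leaves the peak-normalised image unchanged
  twice <- atom_scene(rbind(c(8, 8), c(25, 25)), peak_sigma = 1.5,
                      intensities = 2, canvas_side = 32)
  expect_equal(simulate_adf(twice), img2, tolerance = 1e-12)
  empty <- atom_scene(matrix(numeric(0), ncol = 2), canvas_side = 8)
  expect_equal(simulate_adf(empty), matrix(0, 8, 8))
})

test_that("the noise injector is reproducible, mean-preserving and has a noiseless limit", {
  img <- matrix(0.7, 64, 64)
  p <- noise_params(dose = 50, gaussian_sigma = 0.05, white_amplitude = 0.02,
                    clip_low = 0, clip_high = 4, seed = 99)
  expect_identical(apply_noise(img, p), apply_noise(img, p))

  # noiseless limit: huge dose, no additive stages, wide clip bounds
  p0 <- noise_params(dose = 1e12, gaussian_sigma = 0, white_amplitude = 0,
                     clip_low = -1e6, clip_high = 1e6, seed = 1)
  expect_equal(apply_noise(img, p0), img * 0 + 0.7, tolerance = 1e-4)

  # law of large numbers at 512 x 512: sample mean within 3 standard errors
  s <- 0.4
  big <- matrix(s, 512, 512)
  pd <- noise_params(dose = 25, gaussian_sigma = 0, white_amplitude = 0,
                     clip_low = 0, clip_high = 1e6, seed = 7)
  noisy <- apply_noise(big, pd)
  se <- sqrt(s / 25) / 512
  expect_lt(abs(mean(noisy) - s), 3 * se)

  expect_error(apply_noise(matrix(-1, 2, 2), p), "nonnegative")
  expect_error(noise_params(dose = -5), "dose")
})

test_that("laplacian pairs have the advertised analytic structure", {
  # constant phase: identically zero input channel before rescale
  expect_true(all(mrcnn_ns$laplacian5(matrix(3, 10, 10)) == 0))

  # phase x^2 + y^2: interior Laplacian is exactly 4
  g <- outer((1:20)^2, (1:20)^2, `+`)
  lap <- mrcnn_ns$laplacian5(g)
  expect_true(all(abs(lap[2:19, 2:19] - 4) < 1e-9))

  # spectral oracle: periodic frequency-domain Laplacian agrees exactly on
  # interior pixels (the 5-point stencil only sees the boundary rows there)
  set.seed(5)
  ph <- random_texture(32)
  f <- mrcnn_ns$fft_freq(32)
  mult <- outer(2 * cos(2 * pi * f) - 2, 2 * cos(2 * pi * f) - 2, `+`)
  lap_fft <- Re(stats::fft(stats::fft(ph) * mult, inverse = TRUE)) / 32^2
  lap_dir <- mrcnn_ns$laplacian5(ph)
  expect_equal(lap_dir[3:30, 3:30], lap_fft[3:30, 3:30], tolerance = 1e-10)

  pair <- make_laplacian_pair(ph)
  expect_true(all(pair$input >= 0 & pair$input <= 1))
  expect_true(all(pair$target >= 0 & pair$target <= 1))
  # recorded affine parameters invert the rescaling
  expect_equal(pair$target * pair$scaling$target["gain"] + pair$scaling$target["offset"],
               ph, ignore_attr = TRUE)
})

test_that("target pyramids take exact block means and conserve the global mean", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16), 4, 4)
  pyr <- build_target_pyramid(m, 2)
  expect_equal(pyr[[2]][, , 1], matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                                         mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2, 2))
  cst <- build_target_pyramid(matrix(0.37, 16, 16), 4)
  for (lvl in cst) expect_true(all(lvl == 0.37))

  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- build_target_pyramid(img, 5)
  for (lvl in pyr) expect_equal(mean(lvl), mean(img), tolerance = 1e-12)
  expect_error(build_target_pyramid(matrix(0, 6, 6), 3), "divisible")
})

test_that("training-set sampling is deterministic and shape-correct for every kind", {
  a <- sample_training_set("laplacian", 3, seed = 21, side = 32)
  b <- sample_training_set("laplacian", 3, seed = 21, side = 32)
  expect_identical(a, b)

  adf <- sample_training_set("adf", 8, seed = 4, side = 32)
  expect_length(adf$items, 8)
  for (it in adf$items) {
    expect_equal(dim(it$input), c(32L, 32L, 1L))
    expect_equal(dim(it$target), c(32L, 32L, 1L))
    expect_true(all(it$target >= 0 & it$target <= 1))
  }

  ph <- sample_training_set("phase", 2, seed = 3, side = 32,
                            optics = optics_params(c(-10, 10)))
  expect_equal(dim(ph$items[[1]]$input), c(32L, 32L, 2L))
  expect_error(sample_training_set("unknown", 2), "arg")
})

test_that("the sampler scales to the full training-set size of the phase regime", {
  ds <- sample_training_set("laplacian", 2048, seed = 1, side = 16)
  expect_equal(ds$n, 2048L)
  expect_length(ds$items, 2048)
})
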