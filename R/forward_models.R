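## Synthetic forward models: Fresnel defocus propagation, ADF atomic-image
## synthesis, compound noise, inverse-Laplacian toy pairs, target pyramids
## and the seeded training-set sampler.

#' Complex optical wave field
#'
#' Container for a monochromatic complex wave sampled on a square grid:
#' nonnegative amplitude and unwrapped phase (radians), with the pixel size
#' and wavelength (both in micrometres) needed by the propagator.
#'
#' @param amplitude Nonnegative matrix.
#' @param phase Matrix of phases in radians, same shape as `amplitude`.
#' @param pixel_size Physical side of one pixel (micrometres).
#' @param wavelength Wavelength (micrometres).
#' @return An object of class `wave_field`.
#' @export
wave_field <- function(amplitude, phase = matrix(0, nrow(amplitude), ncol(amplitude)),
                       pixel_size = 1, wavelength = 0.5) {
  stopifnot(is.matrix(amplitude), all(dim(amplitude) == dim(phase)),
            all(amplitude >= 0), pixel_size > 0, wavelength > 0)
  structure(list(amplitude = amplitude, phase = phase,
                 pixel_size = pixel_size, wavelength = wavelength),
            class = "wave_field")
}

wave_complex <- function(w) w$amplitude * exp(1i * w$phase)

#' Fresnel free-space propagation of a wave field
#'
#' Propagates a [wave_field()] by a signed defocus distance `z` with the
#' paraxial (Fresnel) transfer function: the spatial-frequency spectrum is
#' multiplied by `exp(-i * pi * lambda * z * (u^2 + v^2))` and transformed
#' back. The transfer function has unit modulus, so the total intensity
#' (sum of squared amplitude) is conserved to numerical precision.
#'
#' A warning is raised when `|z|` exceeds `n * pixel_size^2 / lambda`, the
#' distance beyond which the sampled chirp aliases at the Nyquist band.
#'
#' @param wave A [wave_field()] on a square grid.
#' @param z Signed defocus distance in micrometres (negative = underfocus).
#' @return The propagated `wave_field` (same grid and metadata).
#' @export
propagate <- function(wave, z) {
  stopifnot(inherits(wave, "wave_field"))
  n <- nrow(wave$amplitude)
  if (ncol(wave$amplitude) != n) stop("propagation requires a square raster")
  if (z == 0) return(wave)
  z_max <- n * wave$pixel_size^2 / wave$wavelength
  if (abs(z) > z_max) {
    warning(sprintf(
      "defocus |z| = %g exceeds the alias-free range %g for this sampling",
      abs(z), z_max))
  }
  f <- fft_freq(n, wave$pixel_size)
  f2 <- outer(f^2, f^2, `+`)
  H <- exp(-1i * pi * wave$wavelength * z * f2)
  psi <- stats::fft(stats::fft(wave_complex(wave)) * H, inverse = TRUE) / n^2
  wave_field(Mod(psi), Arg(psi), wave$pixel_size, wave$wavelength)
}

# FFT sample frequencies (cycles per unit length), standard wrap order.
fft_freq <- function(n, d = 1) {
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

#' Compound noise model parameters
#'
#' Describes the detector noise pipeline applied to a clean image: scale by
#' `dose` (expected counts per pixel at unit signal), Poisson draw, additive
#' Gaussian noise, additive uniform ("white") noise, clipping to the
#' detector range, and rescale back to signal units. `gaussian_sigma`,
#' `white_amplitude`, `clip_low` and `clip_high` are all expressed on the
#' signal (unit) scale.
#'
#' @param dose Expected counts per pixel at unit signal; must be positive.
#' @param gaussian_sigma Standard deviation of the additive Gaussian stage.
#' @param white_amplitude Half-width of the additive uniform stage.
#' @param clip_low,clip_high Detector clipping range (signal scale).
#' @param seed Optional integer; when given, [apply_noise()] is
#'   deterministic.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(dose = 1000, gaussian_sigma = 0.01,
                         white_amplitude = 0.01, clip_low = 0, clip_high = 2,
                         seed = NULL) {
  stopifnot(dose > 0, gaussian_sigma >= 0, white_amplitude >= 0,
            clip_low < clip_high)
  structure(list(dose = dose, gaussian_sigma = gaussian_sigma,
                 white_amplitude = white_amplitude, clip_low = clip_low,
                 clip_high = clip_high, seed = seed),
            class = "noise_params")
}

#' Corrupt an image with compound detector noise
#'
#' Applies the pipeline described by [noise_params()]. For very large doses
#' (above 1e7 expected counts) the Poisson stage uses its Gaussian
#' approximation, so the noiseless limit `dose -> Inf` recovers the input.
#'
#' @param img Nonnegative matrix or array (required by the Poisson stage).
#' @param p A [noise_params()].
#' @return Noisy image, same shape, in signal units.
#' @export
apply_noise <- function(img, p) {
  stopifnot(inherits(p, "noise_params"))
  if (any(img < 0)) stop("apply_noise requires a nonnegative image")
  if (!is.null(p$seed)) set.seed(p$seed)
  lam <- img * p$dose
  counts <- if (p$dose > 1e7) {
    stats::rnorm(length(lam), mean = lam, sd = sqrt(lam))
  } else {
    stats::rpois(length(lam), lam)
  }
  y <- counts / p$dose
  if (p$gaussian_sigma > 0) y <- y + stats::rnorm(length(y), sd = p$gaussian_sigma)
  if (p$white_amplitude > 0) {
    y <- y + stats::runif(length(y), -p$white_amplitude, p$white_amplitude)
  }
  y <- pmin(pmax(y, p$clip_low), p$clip_high)
  array(y, dim(img))
}

#' Optics parameters for a defocus series
#'
#' @param defocus_distances Nonempty vector of signed defocus distances
#'   (micrometres); negative values are underfocus.
#' @param wavelength,pixel_size As in [wave_field()].
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(defocus_distances, wavelength = 0.5, pixel_size = 1) {
  stopifnot(length(defocus_distances) >= 1, wavelength > 0, pixel_size > 0)
  structure(list(defocus_distances = as.numeric(defocus_distances),
                 wavelength = wavelength, pixel_size = pixel_size),
            class = "optics_params")
}

#' Exponentially spaced symmetric defocus planes
#'
#' Builds a symmetric set of defocus distances whose magnitudes are
#' geometrically spaced up to `z_max`, the plane geometry used for
#' through-focus acquisition: `n` planes covering `[-z_max, z_max]`
#' including the in-focus plane when `n` is odd.
#'
#' @param n Number of planes.
#' @param z_max Largest absolute defocus (micrometres).
#' @param z_min Smallest nonzero absolute defocus.
#' @return Sorted numeric vector of length `n`.
#' @export
exponential_defocus_planes <- function(n = 51, z_max = 500, z_min = 1) {
  stopifnot(n >= 1, z_max > z_min, z_min > 0)
  half <- n %/% 2
  mags <- exp(seq(log(z_min), log(z_max), length.out = half))
  if (n %% 2 == 1) sort(c(-mags, 0, mags)) else sort(c(-mags, mags))
}

#' Simulate a noisy defocus intensity series
#'
#' Propagates a wave to each requested focal plane, records the intensity
#' `|psi|^2`, and corrupts each plane with the compound noise model.
#'
#' @param wave A [wave_field()].
#' @param optics An [optics_params()]; its wavelength/pixel size override
#'   the wave's metadata for the propagation.
#' @param noise A [noise_params()], or `NULL` for noise-free intensities.
#' @return An H x W x n_planes array ordered as `optics$defocus_distances`.
#' @export
simulate_defocus_series <- function(wave, optics, noise = noise_params()) {
  stopifnot(inherits(optics, "optics_params"))
  w <- wave_field(wave$amplitude, wave$phase, optics$pixel_size, optics$wavelength)
  n <- nrow(w$amplitude)
  if (!is.null(noise) && !is.null(noise$seed)) set.seed(noise$seed)
  noise_once <- if (is.null(noise)) NULL else {
    ns <- noise; ns$seed <- NULL; ns
  }
  stack <- array(0, c(dim(w$amplitude), length(optics$defocus_distances)))
  for (i in seq_along(optics$defocus_distances)) {
    intens <- propagate(w, optics$defocus_distances[i])$amplitude^2
    if (!is.null(noise_once)) intens <- apply_noise(intens, noise_once)
    stack[, , i] <- intens
  }
  stack
}

#' Scene description for a simulated ADF-STEM image
#'
#' @param positions Two-column matrix of continuous (row, col) atom
#'   coordinates, 1-based, within the canvas.
#' @param peak_sigma Gaussian width of one atomic peak, in pixels.
#' @param intensities Positive per-atom weights (recycled to the number of
#'   atoms).
#' @param canvas_side Image side in pixels.
#' @return An object of class `atom_scene`.
#' @export
atom_scene <- function(positions, peak_sigma = 2.5, intensities = 1,
                       canvas_side = 64L) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  intensities <- rep_len(as.numeric(intensities), nrow(positions))
  stopifnot(peak_sigma > 0, canvas_side >= 1,
            nrow(positions) == 0 ||
              (all(positions >= 0.5) & all(positions <= canvas_side + 0.5)),
            all(intensities > 0))
  structure(list(positions = positions, peak_sigma = peak_sigma,
                 intensities = intensities, canvas_side = as.integer(canvas_side)),
            class = "atom_scene")
}

#' Render a clean ADF-STEM image from an atom scene
#'
#' Atoms appear as 2D Gaussian peaks: the image is the sum over atoms of
#' `intensity * exp(-((dr)^2 + (dc)^2) / (2 * peak_sigma^2))`, which for
#' integer positions equals the convolution of a pulse map with a Gaussian
#' kernel. The result is normalised to peak 1 (an empty scene yields an
#' all-zero image).
#'
#' @param scene An [atom_scene()].
#' @return A `canvas_side` x `canvas_side` matrix in `[0, 1]`.
#' @export
simulate_adf <- function(scene) {
  stopifnot(inherits(scene, "atom_scene"))
  n <- scene$canvas_side
  img <- matrix(0, n, n)
  if (nrow(scene$positions) == 0) return(img)
  rows <- seq_len(n)
  s2 <- 2 * scene$peak_sigma^2
  for (a in seq_len(nrow(scene$positions))) {
    gr <- exp(-(rows - scene$positions[a, 1])^2 / s2)
    gc <- exp(-(rows - scene$positions[a, 2])^2 / s2)
    img <- img + scene$intensities[a] * outer(gr, gc)
  }
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}

#' Inverse-Laplacian training pair
#'
#' Builds the toy pair used to probe convergence: the network input is the
#' discrete 5-point Laplacian of a phase image (second-order central
#' differences, replicate boundary) and the target is the phase itself.
#' Both are affinely rescaled to `[0, 1]`; the affine parameters are
#' recorded in the result so physical units can be restored.
#'
#' @param phase Finite numeric matrix.
#' @return A list with `input`, `target` (both matrices in `[0, 1]`) and
#'   `scaling` (offset/gain per channel).
#' @export
make_laplacian_pair <- function(phase) {
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  lap <- laplacian5(phase)
  rs <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) list(img = array(0, dim(x)), offset = lo, gain = 1)
    else list(img = (x - lo) / (hi - lo), offset = lo, gain = hi - lo)
  }
  ri <- rs(lap); rt <- rs(phase)
  list(input = ri$img, target = rt$img,
       scaling = list(input = c(offset = ri$offset, gain = ri$gain),
                      target = c(offset = rt$offset, gain = rt$gain)))
}

# 5-point discrete Laplacian with replicate boundary.
laplacian5 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  up <- x[c(1, seq_len(n - 1)), , drop = FALSE]
  dn <- x[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  lf <- x[, c(1, seq_len(m - 1)), drop = FALSE]
  rt <- x[, c(seq_len(m - 1) + 1, m), drop = FALSE]
  up + dn + lf + rt - 4 * x
}

#' Multi-resolution target pyramid
#'
#' Produces the coarse supervision targets: level 1 is the target itself,
#' each further level a 2x2 area average of the previous one. Area
#' averaging makes the global mean identical at every level, which is the
#' property the coarse branches are supervised to reproduce.
#'
#' @param target Matrix (or H x W x C array) whose side is divisible by
#'   `2^(levels - 1)`.
#' @param levels Total number of levels (full resolution included).
#' @return A list of `levels` arrays of halving side, class
#'   `target_pyramid`.
#' @export
build_target_pyramid <- function(target, levels) {
  target <- as_image_array(target)
  n <- dim(target)[1]
  stopifnot(levels >= 1)
  if (n %% (2^(levels - 1)) != 0) {
    stop("target side ", n, " is not divisible by 2^(levels - 1) = ",
         2^(levels - 1))
  }
  out <- vector("list", levels)
  out[[1]] <- target
  for (k in seq_len(levels - 1)) {
    out[[k + 1]] <- halve_image(out[[k]])
  }
  structure(out, class = "target_pyramid")
}

# 2x2 area average of an H x W x C array.
halve_image <- function(x) {
  n <- dim(x)[1]; m <- dim(x)[2]; ch <- dim(x)[3]
  y <- array(0, c(n / 2, m / 2, ch))
  for (ci in seq_len(ch)) {
    xi <- x[, , ci]
    y[, , ci] <- (xi[seq(1, n, 2), seq(1, m, 2)] + xi[seq(2, n, 2), seq(1, m, 2)] +
                  xi[seq(1, n, 2), seq(2, m, 2)] + xi[seq(2, n, 2), seq(2, m, 2)]) / 4
  }
  y
}

#' Gaussian random-field texture
#'
#' Seedable stand-in for natural-image content: filtered white noise with a
#' power-law amplitude spectrum `(|f| + f0)^(-beta/2)` (power exponent
#' `beta`), rescaled to `[0, 1]`. `beta = 2` mimics the roughly `1/f^2`
#' power spectrum of natural scenes.
#'
#' @param side Image side in pixels.
#' @param beta Power-spectrum exponent.
#' @param f0 Low-frequency knee (cycles/pixel), keeps the DC finite; the
#'   default `1/side` places the knee at the largest observable scale.
#' @return A `side` x `side` matrix in `[0, 1]`.
#' @export
random_texture <- function(side, beta = 2, f0 = 1 / side) {
  f <- fft_freq(side)
  fr <- sqrt(outer(f^2, f^2, `+`))
  ampl <- (fr + f0)^(-beta / 2)
  wn <- stats::fft(matrix(stats::rnorm(side^2), side, side))
  img <- Re(stats::fft(wn * ampl, inverse = TRUE)) / side^2
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(matrix(0.5, side, side))
  (img - lo) / (hi - lo)
}

random_atom_scene <- function(side, n_atoms = NULL, peak_sigma = NULL) {
  if (is.null(n_atoms)) n_atoms <- sample(5:15, 1)
  if (is.null(peak_sigma)) peak_sigma <- stats::runif(1, 2, 3.5)
  atom_scene(
    positions = cbind(stats::runif(n_atoms, 0.5, side + 0.5),
                      stats::runif(n_atoms, 0.5, side + 0.5)),
    peak_sigma = peak_sigma,
    intensities = stats::runif(n_atoms, 0.3, 1),
    canvas_side = side
  )
}

#' Default compound-noise settings for low-dose ADF frames
#'
#' The corruption used for denoiser training and validation: ten expected
#' counts per pixel at unit signal plus a Gaussian and uniform noise floor,
#' which places simulated frames in the below-minus-ten-decibel SNR regime
#' characteristic of low-dose acquisition.
#'
#' @param dose Expected counts per pixel at unit signal.
#' @return A [noise_params()] object (without a seed).
#' @export
adf_noise_params <- function(dose = 10) {
  noise_params(dose = dose, gaussian_sigma = 0.65, white_amplitude = 0.2,
               clip_low = 0, clip_high = 2)
}

#' Generate a seeded synthetic training set
#'
#' Produces `n` input/target pairs for one of the built-in tasks:
#' \describe{
#'   \item{`laplacian`}{input = discrete Laplacian of a random texture,
#'     target = the texture (both rescaled to `[0, 1]`).}
#'   \item{`phase`}{input = noisy defocused intensity planes of a pure
#'     phase object whose phase is a random texture; target = the phase
#'     rescaled to `[0, 1]`.}
#'   \item{`adf`}{input = a simulated atomic image corrupted by
#'     [adf_noise_params()]; target = the clean image.}
#' }
#'
#' @param kind One of `"laplacian"`, `"phase"`, `"adf"`.
#' @param n Number of pairs.
#' @param seed Integer seed; the same seed yields a bit-identical dataset.
#' @param side Image side in pixels (divisible by the network's `2^depth`).
#' @param optics For `kind = "phase"`: an [optics_params()] giving the
#'   recorded planes (default: a single plane at z = 20 in grid units).
#' @param noise Noise settings for `phase`/`adf` inputs; defaults are
#'   "slight" noise for phase stacks and [adf_noise_params()] for ADF.
#' @param phase_range Peak-to-peak phase modulation (radians) for `phase`.
#' @return An object of class `mrcnn_dataset`: a list with `kind`, `side`,
#'   `seed` and `items`, each item a list with `input` (H x W x C array)
#'   and `target` (H x W x 1 array).
#' @export
sample_training_set <- function(kind = c("laplacian", "phase", "adf"),
                                n, seed = 1L, side = 64L,
                                optics = NULL, noise = NULL,
                                phase_range = pi) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (kind == "phase" && is.null(optics)) {
    optics <- optics_params(defocus_distances = 20, wavelength = 0.5, pixel_size = 1)
  }
  if (is.null(noise)) {
    noise <- if (kind == "adf") adf_noise_params() else noise_params()
  }
  items <- vector("list", n)
  for (i in seq_len(n)) {
    if (kind == "laplacian") {
      pair <- make_laplacian_pair(random_texture(side))
      items[[i]] <- list(input = as_image_array(pair$input),
                         target = as_image_array(pair$target))
    } else if (kind == "phase") {
      tex <- random_texture(side)
      w <- wave_field(matrix(1, side, side), phase_range * tex,
                      optics$pixel_size, optics$wavelength)
      stack <- simulate_defocus_series(w, optics, noise)
      items[[i]] <- list(input = stack, target = as_image_array(tex))
    } else {
      clean <- simulate_adf(random_atom_scene(side))
      noisy <- apply_noise(clean, noise)
      items[[i]] <- list(input = as_image_array(matrix(noisy, side, side)),
                         target = as_image_array(clean))
    }
  }
  structure(list(kind = kind, side = as.integer(side), seed = as.integer(seed),
                 n = as.integer(n), items = items),
            class = "mrcnn_dataset")
}

#' @export
print.mrcnn_dataset <- function(x, ...) {
  cat(sprintf("<mrcnn_dataset> kind '%s', %d pair(s) of %dx%d images (seed %d)\n",
              x$kind, x$n, x$side, x$side, x$seed))
  invisible(x)
}
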