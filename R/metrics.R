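## Evaluation metrics: MAE, SNR in decibels, Fourier ring correlation.

#' Mean absolute error between two images
#'
#' @param a,b Numeric matrices or arrays of identical shape.
#' @return Scalar mean over pixels of `|a - b|`.
#' @export
mae <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mae: shape mismatch")
  mean(abs(a - b))
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(sum(reference^2) / sum((reference - estimate)^2))`: the
#' power of the reference over the power of the residual, so 0 dB means
#' equal signal and noise power. An identical pair (zero residual) returns
#' the declared cap instead of infinity.
#'
#' @param reference Ground-truth image; must not be identically zero.
#' @param estimate Image under evaluation, same shape.
#' @param cap Upper bound returned for a vanishing residual (default 100).
#' @return SNR in dB.
#' @export
snr_db <- function(reference, estimate, cap = 100) {
  if (!all(dim(reference) == dim(estimate))) stop("snr_db: shape mismatch")
  ps <- sum(reference^2)
  if (ps == 0) stop("snr_db: reference is identically zero")
  pn <- sum((reference - estimate)^2)
  min(10 * log10(ps / pn), cap)
}

#' Fourier ring correlation between two images
#'
#' Correlates the Fourier transforms of two same-sized square images over
#' rings of constant spatial frequency: for each ring, the real part of
#' the cross-power sum normalised by the geometric mean of the two ring
#' powers. Identical (or globally rescaled) images give 1 at every ring;
#' independent noise hovers around 0. Images are mean-subtracted by
#' default so the zero-frequency term does not dominate the first ring.
#'
#' @param a,b Square numeric matrices of the same size.
#' @param ring_width Ring width in cycles/pixel; the default `1/n` is one
#'   frequency sample.
#' @param mean_subtract Subtract each image's mean first (default `TRUE`).
#' @return A tibble of class `frc_curve` with columns `radius` (ring
#'   centre, cycles/pixel, strictly increasing, bounded by the Nyquist
#'   frequency 0.5), `correlation` and `n_samples`; rings with no samples
#'   are dropped.
#' @export
frc <- function(a, b, ring_width = NULL, mean_subtract = TRUE) {
  if (!is.matrix(a) || !all(dim(a) == dim(b)) || nrow(a) != ncol(a)) {
    stop("frc requires two square matrices of identical size")
  }
  n <- nrow(a)
  if (is.null(ring_width)) ring_width <- 1 / n
  if (mean_subtract) {
    a <- a - mean(a); b <- b - mean(b)
  }
  fa <- stats::fft(a); fb <- stats::fft(b)
  f <- fft_freq(n)
  fr <- sqrt(outer(f^2, f^2, `+`))
  keep <- fr <= 0.5 & fr > 0
  ring <- floor(fr[keep] / ring_width)
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  num <- tapply(cross, ring, sum)
  da <- tapply(pa, ring, sum)
  db <- tapply(pb, ring, sum)
  cnt <- tapply(rep(1, length(ring)), ring, sum)
  idx <- sort(unique(ring))
  corr <- as.numeric(num / sqrt(da * db))
  corr[!is.finite(corr)] <- 0
  out <- tibble::tibble(
    radius = pmin((idx + 0.5) * ring_width, 0.5),
    correlation = corr,
    n_samples = as.integer(cnt)
  )
  class(out) <- c("frc_curve", class(out))
  out
}

#' Write an FRC curve as a two-column CSV
#'
#' @param curve An `frc_curve` from [frc()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frc_csv <- function(curve, path) {
  utils::write.csv(curve[, c("radius", "correlation")], path, row.names = FALSE)
  invisible(path)
}

#' Metric report for a prediction against ground truth
#'
#' @param reference Ground-truth image (matrix).
#' @param estimate Predicted image, same shape.
#' @return A one-row tibble with `mae`, `snr_db` and `frc_mean` (the mean
#'   ring correlation up to Nyquist).
#' @export
metric_report <- function(reference, estimate) {
  reference <- drop_to_matrix(reference)
  estimate <- drop_to_matrix(estimate)
  curve <- frc(reference, estimate)
  tibble::tibble(
    mae = mae(reference, estimate),
    snr_db = snr_db(reference, estimate),
    frc_mean = mean(curve$correlation)
  )
}

drop_to_matrix <- function(x) {
  if (!is.matrix(x)) x <- x[, , 1]
  x
}
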