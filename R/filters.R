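#' Hand-crafted low-pass filter bank
#'
#' Returns the four fixed low-pass kernels used as the non-trainable first
#' layer of the denoising network: two box filters (5x5 and 7x7, constant 1
#' over their support) and two broad Gaussians (15x15, centred at row/column
#' 8 in 1-based indexing, peak value 1). For an index pair `(r, c)` the
#' Gaussian kernels are `exp(-((r - 8)^2 + (c - 8)^2) / sqrt(s))` with
#' `s = 20` and `s = 30`.
#'
#' The kernels are returned exactly as defined, without normalisation.
#' When installed in a network (see [build_mcnn()]) each kernel is divided
#' by its sum so that the filtered channels have unit DC gain and stay in
#' the intensity range of the input.
#'
#' @return An object of class `lpf_bank`: a list of four matrices named
#'   `f1`..`f4`, with sizes 5x5, 7x7, 15x15 and 15x15.
#' @examples
#' bank <- build_lpf_bank()
#' sapply(bank, dim)
#' bank$f3[8, 8]  # centre value is exactly 1
#' @export
build_lpf_bank <- function() {
  box <- function(k) matrix(1, k, k)
  gauss15 <- function(s) {
    rc <- 1:15
    d2 <- outer((rc - 8)^2, (rc - 8)^2, `+`)
    exp(-d2 / sqrt(s))
  }
  structure(
    list(f1 = box(5), f2 = box(7), f3 = gauss15(20), f4 = gauss15(30)),
    class = "lpf_bank"
  )
}

# Sum-normalised copies used as fixed convolution kernels inside a network.
lpf_bank_normalized <- function(bank = build_lpf_bank()) {
  lapply(unclass(bank), function(f) f / sum(f))
}
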