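#' Describe a multi-resolution network architecture
#'
#' An `mcnn_spec` fully describes an encoder-decoder network: a U-Net of
#' `depth` down/up-sampling stages whose decoder additionally emits
#' `n_branches` coarse outputs, each supervised against a downsampled copy
#' of the target. With `n_branches = 0` the spec describes a plain U-Net.
#'
#' @param input_channels Number of channels of the network input (e.g. the
#'   number of defocus planes in a phase-retrieval stack).
#' @param output_channels Number of channels of each output.
#' @param depth Number of stride-2 downsampling stages (and matching
#'   upsampling stages). Input sides must be divisible by `2^depth`.
#' @param base_width Channel width after the first encoder stage; widths
#'   double per stage and are capped at 512.
#' @param cell Stage cell type: `"plain"` (a single stride-2 convolution per
#'   encoder stage, mirrored in the decoder) or `"bottleneck"` (each stage
#'   additionally carries a 1x1 reduce / 3x3 / 1x1 expand residual block).
#' @param n_branches Number of coarse output branches hanging off the
#'   decoder; at most `depth - 1` (the decoder exposes features at sides
#'   n/2 .. n/2^(depth-1)). Total supervised outputs = `n_branches + 1`.
#' @param use_lpf_layer If `TRUE`, the four fixed low-pass kernels of
#'   [build_lpf_bank()] are applied to every input channel and the filtered
#'   copies are appended as extra channels before the first trainable layer.
#' @param activation Hidden activation, `"lrelu"` (leaky rectifier, slope
#'   0.2; the default) or `"relu"`.
#' @param seed Integer seed for weight initialisation. Two networks built
#'   from specs that differ only in `n_branches` share bit-identical weights
#'   on all common layers.
#' @return An object of class `mcnn_spec`.
#' @seealso [build_mcnn()], [build_unet()]
#' @export
mcnn_spec <- function(input_channels = 1L, output_channels = 1L,
                      depth = 4L, base_width = 32L,
                      cell = c("plain", "bottleneck"),
                      n_branches = 3L, use_lpf_layer = FALSE,
                      activation = c("lrelu", "relu"), seed = 1L) {
  cell <- match.arg(cell)
  activation <- match.arg(activation)
  spec <- list(
    input_channels = as.integer(input_channels),
    output_channels = as.integer(output_channels),
    depth = as.integer(depth),
    base_width = as.integer(base_width),
    cell = cell,
    n_branches = as.integer(n_branches),
    use_lpf_layer = isTRUE(use_lpf_layer),
    activation = activation,
    seed = as.integer(seed)
  )
  class(spec) <- "mcnn_spec"
  validate_mcnn_spec(spec)
  spec
}

validate_mcnn_spec <- function(spec) {
  stopifnot(
    spec$depth >= 1L,
    spec$input_channels >= 1L,
    spec$output_channels >= 1L,
    spec$base_width >= 1L,
    spec$n_branches >= 0L
  )
  if (spec$n_branches > spec$depth - 1L) {
    stop("n_branches must be at most depth - 1 (one coarse head per ",
         "decoder stage below full resolution)", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.mcnn_spec <- function(x, ...) {
  cat(sprintf(
    "<mcnn_spec> %d -> %d channels, depth %d, base width %d, %s cells, %d coarse branch(es)%s, seed %d\n",
    x$input_channels, x$output_channels, x$depth, x$base_width, x$cell,
    x$n_branches, if (x$use_lpf_layer) ", LPF input layer" else "", x$seed
  ))
  invisible(x)
}

#' Write or read an architecture spec as a plain-text config
#'
#' @param spec An `mcnn_spec`.
#' @param path File path for the YAML-style `key: value` text file.
#' @return `read_mcnn_spec()` returns an `mcnn_spec`; `write_mcnn_spec()`
#'   returns `path` invisibly.
#' @export
write_mcnn_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_mcnn_spec
#' @export
read_mcnn_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(mcnn_spec, vals)
}
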