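## Checkpoints, TIFF dataset I/O and experiment configuration files.

#' Save or load a network checkpoint
#'
#' A checkpoint is a single file holding the architecture spec and every
#' weight array; loading reconstructs the network state-identically.
#' [save_checkpoint()] also accepts an `mcnn_train_state`, in which case
#' the best-checkpoint network is saved.
#'
#' @param net An `mcnn_net` or `mcnn_train_state`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()` returns an `mcnn_net`; `save_checkpoint()`
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(net, path) {
  if (inherits(net, "mcnn_train_state")) net <- net$network
  stopifnot(inherits(net, "mcnn_net"))
  saveRDS(list(spec = unclass(net$spec), params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- readRDS(path)
  spec <- do.call(mcnn_spec, raw$spec)
  net <- list(spec = spec, params = raw$params,
              lpf = if (spec$use_lpf_layer) lpf_bank_normalized() else NULL)
  class(net) <- "mcnn_net"
  net$parameter_count <- count_parameters(net)
  net
}

# Scientific rasters are stored as 32-bit float TIFF so counts-per-pixel
# data are never quantised to 8 bits.
write_raster_tiff <- function(img, path) {
  img <- as_image_array(img)
  pages <- lapply(seq_len(dim(img)[3]), function(ci) img[, , ci])
  # 32-bit float pages store values outside [0, 1] faithfully; the library's
  # out-of-range caution concerns integer depths only
  withCallingHandlers(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE),
    warning = function(w) {
      if (grepl("outside the [0, 1] range", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

read_raster_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) out[, , i] <- pages[[i]]
  out
}

#' Write or read a paired-image dataset as TIFF directories
#'
#' Inputs and targets are written as 32-bit float TIFF files
#' (`input_0001.tif`, `target_0001.tif`, ...; multi-channel inputs become
#' multi-page files) together with a `manifest.yml` recording the
#' generator parameters and seed, so a run is reconstructible from its
#' output directory alone.
#'
#' @param dataset An `mrcnn_dataset` from [sample_training_set()].
#' @param dir Output directory (created if needed).
#' @return `read_dataset_tiff()` returns an `mrcnn_dataset`;
#'   `write_dataset_tiff()` returns `dir` invisibly.
#' @export
write_dataset_tiff <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mrcnn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$items)) {
    write_raster_tiff(dataset$items[[i]]$input,
                      file.path(dir, sprintf("input_%04d.tif", i)))
    write_raster_tiff(dataset$items[[i]]$target,
                      file.path(dir, sprintf("target_%04d.tif", i)))
  }
  yaml::write_yaml(list(kind = dataset$kind, n = dataset$n,
                        side = dataset$side, seed = dataset$seed),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_dataset_tiff
#' @export
read_dataset_tiff <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  items <- lapply(seq_len(man$n), function(i) {
    list(input = read_raster_tiff(file.path(dir, sprintf("input_%04d.tif", i))),
         target = read_raster_tiff(file.path(dir, sprintf("target_%04d.tif", i))))
  })
  structure(list(kind = man$kind, side = as.integer(man$side),
                 seed = as.integer(man$seed), n = as.integer(man$n),
                 items = items),
            class = "mrcnn_dataset")
}

#' Experiment configuration
#'
#' Builds a fully resolved experiment configuration (defaults expanded)
#' for the run functions ([run_generate()], [run_train()],
#' [run_predict()]). Configurations round-trip through YAML text files;
#' every run writes its resolved configuration alongside its outputs.
#'
#' @param task One of `"laplacian_toy"`, `"phase_from_defocus"`,
#'   `"adf_denoise"`, `"generic_pairs"`.
#' @param out_dir Output directory.
#' @param data List: `n_train`, `n_test`, `side`, `seed`.
#' @param spec List of [mcnn_spec()] overrides.
#' @param train List of [train_config()] overrides.
#' @param noise,optics Optional [noise_params()]/[optics_params()]
#'   overrides for the generator.
#' @return An object of class `experiment_config` (a named list).
#' @export
experiment_config <- function(task = c("laplacian_toy", "phase_from_defocus",
                                       "adf_denoise", "generic_pairs"),
                              out_dir = "mrcnn-run",
                              data = list(), spec = list(), train = list(),
                              noise = NULL, optics = NULL) {
  task <- match.arg(task)
  data <- utils::modifyList(
    list(n_train = 256L, n_test = 64L, side = 64L, seed = 1L), data)
  spec_defaults <- list(depth = 4L, n_branches = 3L, base_width = 16L,
                        cell = "plain", seed = data$seed,
                        input_channels = 1L, output_channels = 1L,
                        use_lpf_layer = (task == "adf_denoise"))
  spec <- utils::modifyList(spec_defaults, spec)
  train <- utils::modifyList(
    list(batch_size = 4L, iterations = 200L, learning_rate = 1e-3,
         seed = data$seed, eval_every = 10L), train)
  structure(list(task = task, out_dir = out_dir, data = data, spec = spec,
                 train = train, noise = noise, optics = optics),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @param config An `experiment_config` (for writing).
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals[intersect(names(vals),
    c("task", "out_dir", "data", "spec", "train", "noise", "optics"))])
}

config_task_kind <- function(config) {
  switch(config$task,
         laplacian_toy = "laplacian",
         phase_from_defocus = "phase",
         adf_denoise = "adf",
         generic_pairs = "laplacian")
}
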