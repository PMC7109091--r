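## Reproducible experiment runners: thin orchestration over the generator,
## the trainer and the metrics. These functions back the command-line
## interface in inst/cli/mrcnn.R.

#' Generate a dataset described by an experiment configuration
#'
#' Samples the training and test sets for the configured task and writes
#' them as TIFF directories (`data/train`, `data/test`) under the
#' configured output directory, together with the resolved configuration.
#'
#' @param config An [experiment_config()] or path to its YAML file.
#' @return Invisibly, a list with the two dataset objects and their
#'   directories.
#' @export
run_generate <- function(config) {
  config <- resolve_config(config)
  kind <- config_task_kind(config)
  noise <- build_noise(config)
  optics <- build_optics(config)
  tr <- sample_training_set(kind, config$data$n_train, seed = config$data$seed,
                            side = config$data$side, noise = noise,
                            optics = optics)
  te <- sample_training_set(kind, config$data$n_test,
                            seed = config$data$seed + 1L,
                            side = config$data$side, noise = noise,
                            optics = optics)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset_tiff(tr, file.path(config$out_dir, "data", "train"))
  write_dataset_tiff(te, file.path(config$out_dir, "data", "test"))
  write_experiment_config(config, file.path(config$out_dir, "config.yml"))
  invisible(list(train = tr, test = te,
                 train_dir = file.path(config$out_dir, "data", "train"),
                 test_dir = file.path(config$out_dir, "data", "test")))
}

#' Train the configured network on a generated dataset
#'
#' Reads the datasets written by [run_generate()] (generating them
#' in-memory when absent), builds the configured network (or the
#' zero-branch baseline when `baseline = TRUE`, with the identical seed),
#' trains it, and writes `checkpoint.rds`, `history.csv` and the resolved
#' configuration under the output directory.
#'
#' @param config An [experiment_config()] or path to its YAML file.
#' @param baseline Train the plain U-Net baseline instead of the
#'   multi-branch network.
#' @return The `mcnn_train_state`, invisibly.
#' @export
run_train <- function(config, baseline = FALSE) {
  config <- resolve_config(config)
  tr_dir <- file.path(config$out_dir, "data", "train")
  if (dir.exists(tr_dir)) {
    tr <- read_dataset_tiff(tr_dir)
    te <- read_dataset_tiff(file.path(config$out_dir, "data", "test"))
  } else {
    gen <- run_generate(config)
    tr <- gen$train; te <- gen$test
  }
  spec <- do.call(mcnn_spec, config_spec_args(config, tr))
  net <- if (baseline) build_unet(spec) else build_mcnn(spec)
  cfg <- do.call(train_config, config$train)
  state <- train_network(net, tr, cfg, test_set = te)
  tag <- if (baseline) "unet" else "mcnn"
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(state, file.path(config$out_dir, paste0("checkpoint_", tag, ".rds")))
  utils::write.csv(state$history,
                   file.path(config$out_dir, paste0("history_", tag, ".csv")),
                   row.names = FALSE)
  write_experiment_config(config, file.path(config$out_dir, "config.yml"))
  invisible(state)
}

#' Predict images with a trained checkpoint
#'
#' Applies a checkpointed network frame-by-frame to every `input_*.tif`
#' in a directory (or a single TIFF file), writes the predictions, and —
#' when matching `target_*.tif` ground truth is present — a JSON metric
#' report (per-frame MAE and SNR) plus per-frame FRC curves as CSV.
#'
#' @param checkpoint Path to a checkpoint from [save_checkpoint()].
#' @param inputs Directory containing `input_*.tif`, or one TIFF path.
#' @param out_dir Output directory.
#' @return Invisibly, the metric tibble (empty when no ground truth).
#' @export
run_predict <- function(checkpoint, inputs, out_dir) {
  net <- load_checkpoint(checkpoint)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- if (dir.exists(inputs)) {
    sort(list.files(inputs, pattern = "^input_.*\\.tif$", full.names = TRUE))
  } else inputs
  rows <- list()
  for (f in files) {
    img <- read_raster_tiff(f)
    pred <- predict(net, img)
    base <- sub("^input_", "pred_", basename(f))
    write_raster_tiff(pred, file.path(out_dir, base))
    truth_f <- file.path(dirname(f), sub("^input_", "target_", basename(f)))
    if (file.exists(truth_f)) {
      truth <- read_raster_tiff(truth_f)[, , 1]
      rep <- metric_report(truth, pred)
      rep$frame <- basename(f)
      write_frc_csv(frc(truth, drop_to_matrix(as_image_array(pred))),
                    file.path(out_dir, sub("\\.tif$", "_frc.csv", base)))
      rows[[length(rows) + 1L]] <- rep
    }
  }
  metrics <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  if (nrow(metrics)) {
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(metrics)
}

#' Convergence comparison between the multi-branch network and its U-Net
#' baseline
#'
#' The package's headline experiment: generate the seeded
#' inverse-Laplacian toy dataset, train a multi-branch network and an
#' identically seeded zero-branch U-Net with the same optimizer and
#' iteration budget, and report both full histories and final test MAE.
#'
#' @param seed Integer seed driving texture generation, initialisation and
#'   batch order.
#' @param n_train,n_test,side Dataset dimensions.
#' @param depth,n_branches,base_width Architecture knobs.
#' @param iterations,batch_size,learning_rate Optimisation knobs.
#' @param eval_every Test MAE evaluation cadence (iterations).
#' @return A list of class `mcnn_convergence`: `mcnn` and `unet` train
#'   states, and `summary` (tibble with one row per model: final and best
#'   test MAE).
#' @export
run_convergence_experiment <- function(seed = 1L, n_train = 256L, n_test = 64L,
                                       side = 64L, depth = 4L, n_branches = 3L,
                                       base_width = 16L, iterations = 300L,
                                       batch_size = 4L, learning_rate = 3e-3,
                                       eval_every = 10L) {
  tr <- sample_training_set("laplacian", n_train, seed = seed, side = side)
  te <- sample_training_set("laplacian", n_test, seed = seed + 1L, side = side)
  spec <- mcnn_spec(depth = depth, n_branches = n_branches,
                    base_width = base_width, seed = seed)
  cfg <- train_config(batch_size = batch_size, iterations = iterations,
                      learning_rate = learning_rate, seed = seed,
                      eval_every = eval_every)
  mcnn_state <- train_network(build_mcnn(spec), tr, cfg, test_set = te)
  unet_state <- train_network(build_unet(spec), tr, cfg, test_set = te)
  summary <- tibble::tibble(
    model = c("mcnn", "unet"),
    final_test_mae = c(mcnn_state$final_test_mae, unet_state$final_test_mae),
    best_test_mae = c(mcnn_state$best_test_mae, unet_state$best_test_mae)
  )
  structure(list(mcnn = mcnn_state, unet = unet_state, summary = summary,
                 seed = seed),
            class = "mcnn_convergence")
}

#' @export
print.mcnn_convergence <- function(x, ...) {
  cat("<mcnn_convergence>\n")
  print(x$summary)
  invisible(x)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  config
}

config_spec_args <- function(config, dataset) {
  args <- config$spec
  args$input_channels <- dim(dataset$items[[1]]$input)[3]
  args
}

build_noise <- function(config) {
  if (is.null(config$noise)) return(NULL)
  do.call(noise_params, config$noise)
}

build_optics <- function(config) {
  if (is.null(config$optics)) return(NULL)
  do.call(optics_params, config$optics)
}
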