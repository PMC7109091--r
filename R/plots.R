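## ggplot2 and broom-style surfaces for fitted objects and curves.

#' Tidy a training history
#'
#' @param x An `mcnn_train_state`.
#' @param ... Unused.
#' @return A tibble with one row per iteration and metric: `iteration`,
#'   `metric`, `value` (long form; evaluation gaps are dropped).
#' @method tidy mcnn_train_state
#' @export
tidy.mcnn_train_state <- function(x, ...) {
  long <- tidyr_pivot(x$history)
  long[!is.na(long$value), ]
}

# minimal long-form pivot (iteration column kept, others stacked)
tidyr_pivot <- function(df) {
  metrics <- setdiff(names(df), "iteration")
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(iteration = df$iteration, metric = m, value = df[[m]])
  })
}

#' Summarise a training run in one row
#'
#' @param x An `mcnn_train_state`.
#' @param ... Unused.
#' @return A one-row tibble: iterations run, final train loss, final and
#'   best test MAE, trainable parameter count.
#' @method glance mcnn_train_state
#' @export
glance.mcnn_train_state <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$history),
    final_train_loss = utils::tail(x$history$train_loss, 1),
    final_test_mae = x$final_test_mae,
    best_test_mae = x$best_test_mae,
    parameters = x$network$parameter_count
  )
}

#' Plot a training history
#'
#' Train loss and (where evaluated) test MAE against iteration, on a log
#' scale.
#'
#' @param object An `mcnn_train_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcnn_train_state
#' @export
autoplot.mcnn_train_state <- function(object, ...) {
  df <- tidy.mcnn_train_state(object)
  df <- df[df$metric %in% c("train_loss", "test_mae"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "loss / MAE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a convergence comparison
#'
#' Test MAE curves of the multi-branch network and the U-Net baseline on
#' shared axes.
#'
#' @param object An `mcnn_convergence` from [run_convergence_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcnn_convergence
#' @export
autoplot.mcnn_convergence <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$mcnn$history, model = "mcnn"),
    dplyr::mutate(object$unet$history, model = "unet")
  )
  df <- df[!is.na(df$test_mae), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$test_mae,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "test MAE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Fourier ring correlation curve
#'
#' @param object An `frc_curve` from [frc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frc_curve
#' @export
autoplot.frc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.2, 1)) +
    ggplot2::labs(x = "spatial frequency (cycles/pixel)",
                  y = "ring correlation") +
    ggplot2::theme_minimal()
}
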