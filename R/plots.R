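#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a confusion matrix
#'
#' Heatmap of the cross-validated confusion counts of a decoding result.
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_result <- function(object, ...) {
  cm <- as.data.frame.table(object$confusion, responseName = "count")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Mean accuracy %.3f (chance %.3f)",
                                  object$mean_accuracy, object$chance),
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot a group permutation null distribution
#'
#' Histogram of the permutation-derived group-mean null with the observed
#' group accuracy marked.
#'
#' @param object A `group_permutation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_permutation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_group_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_group_mean,
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(
      title = sprintf("Observed %.3f, P = %.3g (d = %.2f)",
                      object$observed_group_mean, object$p_value,
                      object$cohens_d),
      x = "null group-mean accuracy", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Plot per-task group accuracies of an experiment
#'
#' Bar panel of observed group accuracies with chance levels, mirroring the
#' per-task result summary of the pipeline report.
#'
#' @param object An `experiment_report` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- object$report[!is.na(object$report$observed), , drop = FALSE]
  df$task <- factor(df$task, levels = df$task)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$observed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$chance,
                                        ymax = .data$chance),
                           linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")),
      vjust = -0.4, size = 6) +
    ggplot2::labs(x = NULL, y = "group mean accuracy",
                  title = "Decoding accuracy by task (dashed = chance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an axial slice of a searchlight accuracy map
#'
#' @param accuracy Vector of per-voxel accuracies over `which(mask)`.
#' @param mask 3-dimensional logical array.
#' @param slice_z Which z-slice to show (default: middle slice).
#' @return A ggplot object.
#' @export
plot_searchlight_slice <- function(accuracy, mask, slice_z = NULL) {
  dims <- dim(mask)
  if (is.null(slice_z)) slice_z <- ceiling(dims[3] / 2)
  vol <- array(NA_real_, dims)
  vol[which(mask)] <- accuracy
  sl <- vol[, , slice_z]
  df <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$accuracy <- as.vector(sl)
  ggplot2::ggplot(df[!is.na(df$accuracy), ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Searchlight accuracy, z = %d", slice_z)) +
    ggplot2::theme_minimal()
}
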