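# ggplot2 displays for experiment results.

#' @export
autoplot.pep_shuffle_experiment <- function(object, metrics = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(x = "shuffling ratio", y = "metric value",
                  title = "Performance under training-sequence shuffling") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pep_ablation <- function(object, metrics = NULL, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$metric))
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$value,
                                   fill = .data$variant)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(ggplot2::vars(.data$metric),
                        ggplot2::vars(.data$family), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = "Count vs. binary fingerprint variants") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pep_motif_test <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "metric value", fill = NULL,
                  title = "Charged-motif task: fingerprints vs. n-gram baseline") +
    ggplot2::theme_minimal()
}
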