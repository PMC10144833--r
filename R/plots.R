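# ggplot2 displays for selection curves, ensemble training and DE results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the recursive-feature-elimination validation curve
#'
#' Validation AUC and F1 against the number of surviving features.
#'
#' @param object A `csf_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csf_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("f1", "auc"),
                              names_to = "metric", values_to = "score")
  n_sel <- length(object$selected_columns)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_features, y = .data$score,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = n_sel, linetype = "dashed") +
    ggplot2::labs(x = "surviving features", y = "validation score",
                  title = "Recursive feature elimination",
                  subtitle = paste(n_sel, "features selected")) +
    ggplot2::theme_minimal()
}

#' Plot per-member training loss of a PU ensemble
#'
#' @param object A `pu_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pu_ensemble <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$models), function(t) {
    loss <- attr(object$models[[t]], "loss")
    tibble::tibble(model = factor(t), epoch = seq_along(loss), loss = loss)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   group = .data$model)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "epoch", y = "training cross-entropy",
                  title = "PU bagging ensemble training") +
    ggplot2::theme_minimal()
}

#' Volcano-style display of a differential-expression table
#'
#' log2 fold change against -log10 q-value, colored by status.
#'
#' @param de Tibble from [de_analysis()].
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  df <- dplyr::filter(de, is.finite(.data$fc) & .data$fc > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fc),
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value",
                  title = "Differential expression") +
    ggplot2::theme_minimal()
}
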