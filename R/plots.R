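# ggplot2 views of tuning results and candidate score distributions.

#' Plot the threshold-grid F1 surface
#'
#' Tile plot of training-set F1 over the (phonetic, string) grid, with the
#' accepted path and the selected threshold pair marked.
#'
#' @param object A `threshold_fit` from [tune_thresholds()].
#' @param set Which F1 surface to draw, `"train"` (default) or `"valid"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_fit <- function(object, set = c("train", "valid"), ...) {
  set <- match.arg(set)
  fill <- if (set == "train") "f1_train" else "f1_valid"
  sel <- tibble::as_tibble(object$thresholds)
  ggplot2::ggplot(object$grid_eval,
                  ggplot2::aes(.data$string, .data$phonetic)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::geom_point(data = dplyr::filter(object$grid_eval,
                                             .data$accepted),
                        shape = 20, size = 0.8, colour = "white") +
    ggplot2::geom_point(data = sel, shape = 4, size = 3, stroke = 1.2,
                        colour = "red") +
    ggplot2::scale_fill_viridis_c(name = paste0("F1 (", set, ")"),
                                  na.value = "grey90") +
    ggplot2::labs(x = "string similarity threshold",
                  y = "phonetic similarity threshold") +
    ggplot2::theme_minimal()
}

#' @export
plot.threshold_fit <- function(x, ...) print(autoplot(x, ...))

#' Scatter plot of candidate-pair similarity scores
#'
#' Phonetic against string similarity for labelled candidate pairs, with
#' optional threshold lines; the visual counterpart of the joint-threshold
#' decision rule.
#'
#' @param pairs A candidate-pair tibble with `string_sim`, `phonetic_sim`
#'   and `label`.
#' @param thresholds Optional threshold pair (see [is_match()]) drawn as
#'   dashed lines.
#' @return A ggplot object.
#' @export
plot_candidate_scores <- function(pairs, thresholds = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(.data$string_sim,
                                           .data$phonetic_sim,
                                           colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "string similarity", y = "phonetic similarity") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    thr <- as_threshold_pair(thresholds)
    p <- p +
      ggplot2::geom_vline(xintercept = thr$string, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = thr$phonetic, linetype = "dashed")
  }
  p
}
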