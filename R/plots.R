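#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   scale_fill_viridis_c labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a comodulogram
#'
#' Heat map of the dominant-coupling-mode probability distribution: diagonal =
#' within-frequency, off-diagonal = modulating (row) by modulated (column)
#' cross-frequency couplings.
#'
#' @param object A `comodulogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comodulogram <- function(object, ...) {
  df <- tidy.comodulogram(object)
  nm <- rownames(object)
  df$modulating <- factor(df$modulating, levels = nm)
  df$modulated <- factor(df$modulated, levels = rev(nm))
  ggplot(df, aes(x = .data$modulating, y = .data$modulated,
                 fill = .data$probability)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, max(df$probability, 1e-9))) +
    labs(x = "modulating band", y = "modulated band", fill = "probability") +
    theme_minimal()
}

#' Plot a similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy.similarity_matrix(object)
  ggplot(df, aes(x = .data$test, y = .data$train, fill = .data$sum_loglik)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "test subject", y = "training model", fill = "sum log-lik") +
    theme_minimal()
}

#' Plot a step-wise selection accuracy curve
#'
#' @param object A `stepwise_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stepwise_selection <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$step, y = 100 * .data$accuracy)) +
    geom_line() + geom_point() +
    labs(x = "edges retained", y = "identification accuracy (%)") +
    theme_minimal()
}

#' Plot a flexibility-index matrix
#'
#' @param object A `flexibility`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flexibility <- function(object, ...) {
  df <- tidy.flexibility(object)
  ggplot(df, aes(x = .data$roi_j, y = .data$roi_i, fill = .data$fi)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "ROI", y = "ROI", fill = "FI") +
    theme_minimal()
}

#' Plot a window-parameter repeatability surface
#'
#' @param object A `window_opt`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_opt <- function(object, ...) {
  ggplot(object$surface, aes(x = factor(.data$width), y = factor(.data$step),
                             fill = .data$repeatability)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "window width (s)", y = "step (s)", fill = "repeatability") +
    theme_minimal()
}
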