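#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result`.
#' @param alpha Adjusted-p significance cut used for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df <- df[df$tested, ]
  df$significant <- !is.na(df$p_adjust) & df$p_adjust <= alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fold_change,
                                   -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("padj <= %g", alpha),
                  title = paste(attr(object, "contrast"), collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' CSA distribution of segmented fibers
#'
#' @param object A `fiber_regions` tibble from [segment_fibers()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object (accepted fibers only).
#' @export
autoplot.fiber_regions <- function(object, bins = 30, ...) {
  acc <- object[object$status == "accepted", ]
  ggplot2::ggplot(acc, ggplot2::aes(.data$area_px)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "fiber CSA (px)", y = "fibers",
                  title = sprintf("%d accepted fibers", nrow(acc))) +
    ggplot2::theme_minimal()
}

#' Trend-cluster center profiles
#'
#' @param object An `fcm_fit`.
#' @param ... Unused.
#' @return A ggplot object showing each cluster center across timepoints.
#' @export
autoplot.fcm_fit <- function(object, ...) {
  ctr <- object$centers
  df <- tibble::as_tibble(ctr)
  names(df) <- colnames(ctr) %||% paste0("t", seq_len(ncol(ctr)))
  df$cluster <- rownames(ctr)
  df <- tidyr::pivot_longer(df, -"cluster", names_to = "stage",
                            values_to = "center")
  df$stage <- factor(df$stage, levels = unique(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$center,
                                   group = .data$cluster,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stage", y = "standardized expression",
                  title = "fuzzy c-means trend centers") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation bars
#'
#' @param object A `coexpression_fit` built with a trait.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_fit <- function(object, ...) {
  abort_if(is.null(object$trait_cor),
           "fit has no trait correlations; rebuild with `trait`")
  df <- object$trait_cor
  ggplot2::ggplot(df, ggplot2::aes(.data$module, .data$r, fill = .data$module)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = "eigengene-trait Pearson r",
                  title = "module-trait correlation") +
    ggplot2::theme_minimal()
}

#' Bias-call composition per stage
#'
#' @param object A `bias_calls` object.
#' @param ... Unused.
#' @return A ggplot object (stacked bars of calls by stage).
#' @export
autoplot.bias_calls <- function(object, ...) {
  df <- object$by_stage
  df$stage <- factor(df$stage, levels = unique(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, fill = .data$call)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(y = "genes", title = "crossbred expression-bias calls") +
    ggplot2::theme_minimal()
}
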