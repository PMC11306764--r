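# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of a fitted shape PCA
#'
#' @param object A `shape_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_pca <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$evr), evr = object$evr,
                       cumulative = cumsum(object$evr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$evr), fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "red") +
    ggplot2::labs(x = "Principal component",
                  y = "Explained variance (bars) / cumulative (line)") +
    ggplot2::theme_minimal()
}

#' Train/test LMD comparison of reduction methods
#'
#' @param object A `reduction_cv` from [crossval_reduction()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reduction_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, c("train_lmd", "test_lmd"),
                            names_to = "split", values_to = "lmd")
  df$split <- sub("_lmd", "", df$split)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$lmd,
                                   fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Mean LMD error (mm)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Per-part LMD distribution of the LOOCV evaluation
#'
#' @param object A `loocv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loocv_result <- function(object, ...) {
  if (!nrow(object$per_part)) {
    stop("LOOCV result has no per-part table (no partition supplied)",
         call. = FALSE)
  }
  ggplot2::ggplot(object$per_part,
                  ggplot2::aes(x = .data$part, y = .data$lmd)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = NULL, y = "LMD error (mm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Width profile of a border pair with detected junctions
#'
#' @param widths Width series tibble from [width_series()].
#' @param junctions Optional integer vector of junction indices to mark.
#' @return A ggplot.
#' @export
plot_width_series <- function(widths, junctions = NULL) {
  p <- ggplot2::ggplot(widths, ggplot2::aes(x = .data$ordinal,
                                            y = .data$width)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Semilandmark ordinal", y = "Width (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(junctions)) {
    p <- p + ggplot2::geom_vline(xintercept = junctions, colour = "red",
                                 linetype = 2)
  }
  p
}

#' Top view of percentile morphologies
#'
#' @param object A `percentile_shapes`.
#' @param ... Unused.
#' @return A ggplot (X-Y projection, coloured by percentile).
#' @export
autoplot.percentile_shapes <- function(object, ...) {
  ggplot2::ggplot(object$shapes,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = factor(.data$percentile),
                               group = interaction(.data$percentile,
                                                   .data$border))) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "Percentile") +
    ggplot2::theme_minimal()
}
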