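# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted shape PCA
#'
#' @param x A `shape_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `sdev`, `evr`, `cumulative`.
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), sdev = x$sdev, evr = x$evr,
                 cumulative = cumsum(x$evr))
}

#' @rdname tidy.shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), p = ncol(x$basis), k = x$k,
                 variance_captured = sum(x$evr))
}

#' Tidy a regression shape model
#'
#' @param x A `shape_regression`.
#' @param ... Unused.
#' @return Long coefficient tibble (`pc`, `term`, `estimate`).
#' @export
tidy.shape_regression <- function(x, ...) {
  terms <- colnames(x$features$F)
  purrr::map_dfr(seq_len(nrow(x$coef)), function(j) {
    tibble::tibble(pc = j, term = terms, estimate = x$coef[j, ])
  })
}

#' @rdname tidy.shape_regression
#' @export
glance.shape_regression <- function(x, ...) {
  resid <- x$pca$scores - x$fitted_scores
  tibble::tibble(k = nrow(x$coef), n_features = ncol(x$coef),
                 condition = x$condition,
                 score_rss = sum(resid^2),
                 score_r_squared = 1 - sum(resid^2) / sum(x$pca$scores^2))
}

#' Tidy the reduction cross-validation table
#'
#' @param x A `reduction_cv`.
#' @param ... Unused.
#' @return The per-method summary tibble.
#' @export
tidy.reduction_cv <- function(x, ...) x$table

#' Tidy / summarise a LOOCV evaluation
#'
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @return `tidy`: per-subject LMD tibble. `glance`: one-row summary with the
#'   overall mean LMD and fold failures.
#' @export
tidy.loocv_result <- function(x, ...) x$per_subject

#' @rdname tidy.loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$per_subject),
                 mean_lmd = mean(x$per_subject$lmd),
                 max_lmd = max(x$per_subject$lmd),
                 failed = length(x$failed))
}
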