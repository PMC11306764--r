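# Linear regression of component scores on morphometric covariates, LOOCV
# evaluation, covariate significance, and percentile-shape generation.

canonical_features <- c(L = "cranial_length", W = "cranial_width",
                        C = "cranial_circumference", S = "total_surface_area",
                        SI = "average_si")

resolve_feature_cols <- function(records, features) {
  vapply(features, function(f) {
    col <- if (f %in% names(canonical_features)) canonical_features[[f]]
           else f
    if (!col %in% names(records)) {
      stop("missing covariate column: ", col, call. = FALSE)
    }
    col
  }, character(1))
}

#' Build a standardized feature matrix from morphometric records
#'
#' Selects the covariates (canonical short names `L`, `W`, `C`, `S`, `SI` map
#' to cranial length/width/circumference, total surface area and average
#' sinuosity index; any other name is used as a column name directly),
#' standardizes each column, and prepends an intercept column when requested.
#'
#' @param records Morphometric tibble (one row per subject).
#' @param features Character vector of covariates.
#' @param intercept Include a leading intercept column? Default `TRUE`.
#' @return Object of class `feature_matrix`: `F` (N x q), `feature_names`,
#'   `center`, `scale`, `ranges` (raw min/max per feature), `intercept`.
#' @export
build_features <- function(records, features = c("L", "W", "C", "S", "SI"),
                           intercept = TRUE) {
  cols <- resolve_feature_cols(records, features)
  raw <- as.matrix(records[, cols, drop = FALSE])
  if (anyNA(raw) || !all(is.finite(raw))) {
    bad <- records$subject_id[!stats::complete.cases(raw)]
    stop("missing covariate value for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  center <- colMeans(raw)
  scale_ <- sqrt(colMeans(sweep(raw, 2, center)^2))
  if (any(scale_ < 1e-12)) {
    stop("degenerate covariate: ",
         paste(features[scale_ < 1e-12], collapse = ", "), call. = FALSE)
  }
  Fm <- sweep(sweep(raw, 2, center), 2, scale_, "/")
  colnames(Fm) <- features
  if (intercept) Fm <- cbind(`(Intercept)` = 1, Fm)
  structure(
    list(F = Fm, feature_names = features, center = center, scale = scale_,
         ranges = apply(raw, 2, range), intercept = intercept),
    class = "feature_matrix"
  )
}

feature_row <- function(fm, covariates) {
  covariates <- as.list(covariates)
  cols <- resolve_feature_cols(
    tibble::as_tibble(covariates[vapply(covariates, is.numeric,
                                        logical(1))]),
    fm$feature_names)
  raw <- vapply(cols, function(cl) as.numeric(covariates[[cl]]), numeric(1))
  outside <- raw < fm$ranges[1, ] | raw > fm$ranges[2, ]
  if (any(outside)) {
    warning("covariate(s) outside training range: ",
            paste(fm$feature_names[outside], collapse = ", "),
            "; prediction is an extrapolation", call. = FALSE)
  }
  f <- (raw - fm$center) / fm$scale
  if (fm$intercept) f <- c(1, f)
  f
}

#' Fit the score-on-covariates regression shape model
#'
#' Least-squares coefficient matrix `C` mapping the standardized feature
#' matrix to component scores via the Moore-Penrose pseudoinverse:
#' `C = t(F^+ %*% Sk)`, minimizing the Frobenius norm of `Sk - F %*% t(C)`
#' over all coefficient matrices (rank-deficient feature matrices are handled
#' by the pseudoinverse; the condition number is recorded).
#'
#' @param model A fitted `shape_pca` (supplies the scores and the geometry
#'   reconstruction path).
#' @param records Morphometric tibble aligned with the model's subjects.
#' @param features Covariate names (see [build_features()]).
#' @param intercept Include an intercept? Default `TRUE`.
#' @return Object of class `shape_regression`: `coef` (k x q), `features`
#'   (the `feature_matrix`), `pca`, `fitted_scores`, `condition`.
#' @export
fit_shape_regression <- function(model, records,
                                 features = c("L", "W", "C", "S", "SI"),
                                 intercept = TRUE) {
  stopifnot(inherits(model, "shape_reduction"))
  fm <- if (inherits(records, "feature_matrix")) records
        else build_features(records, features, intercept)
  Sk <- model$scores
  if (nrow(fm$F) != nrow(Sk)) {
    stop("feature rows (", nrow(fm$F), ") != score rows (", nrow(Sk), ")",
         call. = FALSE)
  }
  C <- t(MASS::ginv(fm$F) %*% Sk)
  sv <- svd(fm$F, nu = 0, nv = 0)$d
  structure(
    list(coef = C, features = fm, pca = model,
         fitted_scores = fm$F %*% t(C),
         condition = sv[1] / max(sv[length(sv)], 1e-300)),
    class = "shape_regression"
  )
}

#' Predict a suture/fontanelle geometry from covariates
#'
#' Scores are the linear map `C %*% f` of the standardized covariate vector;
#' geometry follows via [reconstruct_subject()]. The map is affine, so
#' midpoint covariates give the midpoint shape. Covariates outside the
#' training range trigger an extrapolation warning.
#'
#' @param model A `shape_regression`.
#' @param covariates Named list / one-row tibble of raw covariate values.
#' @return Geometry tibble (`border`, `ordinal`, `x`, `y`, `z`).
#' @export
predict_shape <- function(model, covariates) {
  f <- feature_row(model$features, covariates)
  scores <- as.numeric(model$coef %*% f)
  reconstruct_subject(model$pca, scores)
}

sl_row_index <- function(topology, partition, part) {
  ranges <- partition$parts[partition$parts$part == part, ]
  unique(unlist(lapply(seq_len(nrow(ranges)), function(i) {
    which(topology$border == ranges$border[i] &
            topology$ordinal >= ranges$start[i] &
            topology$ordinal <= ranges$end[i])
  })))
}

#' Leave-one-out cross-validation of the regression shape model
#'
#' For every subject: standardize, fit the PCA and the regression on the
#' remaining N - 1 subjects, predict the held-out geometry from its own
#' measured covariates, and record the overall LMD, the per-part LMD (nine
#' parts), and the predicted vs. measured suture length/width/SI. A fold
#' failure is recorded and the run continues.
#'
#' @param sl Multi-subject semilandmark tibble (superimposed).
#' @param records Morphometric records for the same subjects.
#' @param features Covariates (see [build_features()]).
#' @param k Number of components (capped at N - 2 per fold).
#' @param partition Template `suture_partition` used for the per-part LMD and
#'   the predicted suture measures (optional).
#' @param intercept Include an intercept? Default `TRUE`.
#' @return Object of class `loocv_result`: `per_subject`, `per_part`,
#'   `measures` (predicted vs. measured), `failed` subject ids.
#' @export
loocv_shape_model <- function(sl, records,
                              features = c("L", "W", "C", "S", "SI"),
                              k = 10L, partition = NULL, intercept = TRUE) {
  G0 <- geometry_matrix(sl)
  topo <- attr(G0, "topology")
  ids <- rownames(G0)
  if (length(ids) < 3) stop("LOOCV needs at least 3 subjects", call. = FALSE)
  records <- records[match(ids, records$subject_id), ]
  per_subject <- list(); per_part <- list(); measures <- list()
  failed <- character(0)
  for (i in seq_along(ids)) {
    res <- tryCatch({
      Gtrain <- G0[-i, , drop = FALSE]
      attr(Gtrain, "topology") <- topo
      sm <- standardize_shapes(Gtrain)
      ki <- min(k, nrow(sm$G) - 1L)
      pca <- fit_shape_pca(sm, ki)
      reg <- fit_shape_regression(pca, records[-i, ], features, intercept)
      pred <- suppressWarnings(predict_shape(reg, records[i, ]))
      truth <- rows_to_points(G0[i, ])
      pred_pts <- as.matrix(pred[, c("x", "y", "z")])
      out <- list(subject = tibble::tibble(subject_id = ids[i],
                                           lmd = lmd(pred_pts, truth)))
      if (!is.null(partition)) {
        out$part <- purrr::map_dfr(part_names, function(p) {
          rows <- sl_row_index(topo, partition, p)
          tibble::tibble(subject_id = ids[i], part = p,
                         lmd = lmd(pred_pts[rows, , drop = FALSE],
                                   truth[rows, , drop = FALSE]))
        })
        pred_sl <- dplyr::mutate(pred, subject_id = ids[i], .before = 1)
        out$meas <- purrr::map_dfr(suture_parts, function(p) {
          tibble::tibble(
            subject_id = ids[i], suture = p,
            predicted_length = suture_length(pred_sl, partition, p),
            measured_length = records[[paste0(p, "_length")]][i],
            predicted_width = suture_width(pred_sl, partition, p),
            measured_width = records[[paste0(p, "_width")]][i],
            predicted_si = sinuosity_index(pred_sl, partition, p),
            measured_si = records[[paste0(p, "_si")]][i])
        })
      }
      out
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- c(failed, ids[i])
      next
    }
    per_subject[[length(per_subject) + 1]] <- res$subject
    if (!is.null(res$part)) per_part[[length(per_part) + 1]] <- res$part
    if (!is.null(res$meas)) measures[[length(measures) + 1]] <- res$meas
  }
  structure(
    list(per_subject = dplyr::bind_rows(per_subject),
         per_part = dplyr::bind_rows(per_part),
         measures = dplyr::bind_rows(measures), failed = failed),
    class = "loocv_result"
  )
}

#' Per-component covariate significance table
#'
#' For each component and each covariate set (the five single covariates plus
#' `ALL`), fits an ordinary least-squares regression of the component's scores
#' on the covariate(s) and reports R-squared and the F-test p-value, starred at
#' p < 0.001 (`**`) and p < 0.0001 (`***`). Raw p-values by default; an
#' optional Bonferroni correction multiplies by the number of table cells.
#'
#' @param scores N x k score matrix (or a `shape_reduction`).
#' @param records Morphometric records for the same subjects.
#' @param features Single covariates to test; `ALL` (their combination) is
#'   always appended.
#' @param bonferroni Apply Bonferroni correction? Default `FALSE`.
#' @return Tibble with `pc`, `covariate`, `r_squared`, `p_value`, `stars`.
#' @export
covariate_significance <- function(scores, records,
                                   features = c("L", "W", "C", "S", "SI"),
                                   bonferroni = FALSE) {
  if (inherits(scores, "shape_reduction")) scores <- scores$scores
  scores <- as.matrix(scores)
  sets <- c(stats::setNames(as.list(features), features),
            list(ALL = features))
  n_cells <- ncol(scores) * length(sets)
  out <- purrr::map_dfr(seq_len(ncol(scores)), function(j) {
    purrr::map_dfr(names(sets), function(nm) {
      fm <- build_features(records, sets[[nm]], intercept = FALSE)
      fit <- stats::lm(scores[, j] ~ fm$F)
      sm_ <- summary(fit)
      fstat <- sm_$fstatistic
      p <- if (is.null(fstat)) NA_real_ else {
        stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
      }
      if (bonferroni && is.finite(p)) p <- min(1, p * n_cells)
      tibble::tibble(pc = j, covariate = nm, r_squared = sm_$r.squared,
                     p_value = as.numeric(p),
                     stars = dplyr::case_when(p < 1e-4 ~ "***",
                                              p < 1e-3 ~ "**",
                                              TRUE ~ ""))
    })
  })
  out
}

#' Generate percentile morphologies from the fitted model
#'
#' A "percentile infant" is defined by the elementwise (marginal) empirical
#' percentile of each covariate over the training records; its geometry is
#' predicted with [predict_shape()]. Suture lengths and widths of the
#' predicted shapes are measured against the template partition, and the size
#' table is normalized by the 5th-percentile (first requested percentile) row.
#'
#' @param model A `shape_regression`.
#' @param records Training morphometric records.
#' @param percentiles Percentiles in (0, 100); default `c(5, 25, 50, 75, 95)`.
#' @param partition Template `suture_partition` for measuring the predicted
#'   shapes (optional).
#' @return Object of class `percentile_shapes`: `shapes` (tibble with
#'   `percentile` column), `covariates`, `sizes`, `normalized_sizes`.
#' @export
percentile_shapes <- function(model, records,
                              percentiles = c(5, 25, 50, 75, 95),
                              partition = NULL) {
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie in (0, 100)", call. = FALSE)
  }
  fm <- model$features
  cols <- resolve_feature_cols(records, fm$feature_names)
  covs <- purrr::map_dfr(percentiles, function(p) {
    row <- lapply(cols, function(cl) {
      as.numeric(stats::quantile(records[[cl]], p / 100, names = FALSE))
    })
    names(row) <- cols
    tibble::as_tibble(c(list(percentile = p), row))
  })
  shapes <- purrr::map_dfr(seq_along(percentiles), function(i) {
    g <- suppressWarnings(predict_shape(model, covs[i, -1]))
    dplyr::mutate(g, percentile = percentiles[i], .before = 1)
  })
  sizes <- NULL; normalized <- NULL
  if (!is.null(partition)) {
    sizes <- purrr::map_dfr(seq_along(percentiles), function(i) {
      g <- shapes[shapes$percentile == percentiles[i], ]
      g$subject_id <- paste0("p", percentiles[i])
      row <- tibble::tibble(percentile = percentiles[i])
      for (p in suture_parts) {
        row[[paste0(p, "_length")]] <- suture_length(g, partition, p)
        row[[paste0(p, "_width")]] <- suture_width(g, partition, p)
      }
      row
    })
    normalized <- sizes
    for (cl in names(sizes)[-1]) {
      normalized[[cl]] <- sizes[[cl]] / sizes[[cl]][1]
    }
  }
  structure(list(shapes = shapes, covariates = covs, sizes = sizes,
                 normalized_sizes = normalized, percentiles = percentiles),
            class = "percentile_shapes")
}
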