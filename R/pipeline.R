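# End-to-end orchestration of the full analysis.

#' Pipeline configuration
#'
#' Every framework constant is surfaced as a named option; the defaults are the
#' reference values (semilandmark counts 100/100/200/200/50/50/100, junction
#' thresholds k = 0.15/0.18 and m = 0.4, mesh edge 0.3 mm, 10 folds, 95%
#' variance threshold, covariates L/W/C/S/SI, percentiles 5/25/50/75/95).
#'
#' @param input Either a [synthetic_config()] (the pipeline simulates its
#'   subjects) or a list with file paths `curves` and `landmarks` (CSV; see
#'   [read_border_curves()]) and optionally `contours`.
#' @param output_dir Directory for all result files.
#' @param counts Semilandmark counts per border.
#' @param junction A [junction_config()].
#' @param target_edge Surface mesh edge target (mm).
#' @param slide_iterations Semilandmark sliding iterations (0 disables).
#' @param components Number of PCA components, or `NULL` to pick the smallest
#'   count reaching `variance_threshold`.
#' @param variance_threshold Cumulative explained-variance target.
#' @param features Regression covariates.
#' @param percentiles Percentile morphologies to generate.
#' @param folds Cross-validation folds for the reduction comparison.
#' @param cv_methods Reduction methods compared (VAE variants opt-in).
#' @param run_loocv Run the leave-one-out evaluation?
#' @param seed Seed for every random element.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = synthetic_config(),
                            output_dir = tempfile("suturemorph_run_"),
                            counts = default_counts(),
                            junction = junction_config(),
                            target_edge = 0.3,
                            slide_iterations = 3L,
                            components = NULL,
                            variance_threshold = 0.95,
                            features = c("L", "W", "C", "S", "SI"),
                            percentiles = c(5, 25, 50, 75, 95),
                            folds = 10L,
                            cv_methods = c("classic_pca", "kpca_linear",
                                           "kpca_cosine", "kpca_rbf",
                                           "kpca_sigmoid", "kpca_laplacian"),
                            run_loocv = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_pipeline_subjects <- function(cfg) {
  if (inherits(cfg$input, "synthetic_config")) {
    pop <- generate_population(cfg$input, representation = "curves")
    return(pop$subjects)
  }
  for (p in c(cfg$input$curves, cfg$input$landmarks)) {
    if (!file.exists(p)) stop("missing input path: ", p, call. = FALSE)
  }
  curves <- read_border_curves(cfg$input$curves, format = "csv")
  lms <- readr::read_csv(cfg$input$landmarks, show_col_types = FALSE)
  contours <- if (!is.null(cfg$input$contours)) {
    readr::read_csv(cfg$input$contours, show_col_types = FALSE)
  }
  lapply(unique(curves$subject_id), function(sid) {
    list(curves = curves[curves$subject_id == sid, ],
         landmarks = list(
           points = lms[lms$subject_id == sid, ],
           axial_contour = if (!is.null(contours)) {
             contours[contours$subject_id == sid, c("x", "y", "z")]
           }))
  })
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or simulate subjects; (2) three-point rigid alignment to
#' the first subject; (3) semilandmark resampling; (4) junction detection and
#' partitioning; (5) morphometrics including TPS surface areas; (6) form-space
#' GPA and bending-energy sliding; (7) PCA; (8) cross-validated reduction
#' comparison; (9) score regression with significance table; (10) LOOCV;
#' (11) percentile shapes. Every intermediate is written under
#' `config$output_dir`; the run is deterministic given the seed. A stage
#' failure stops with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` (invisible): `records`,
#'   `partitions`, `gpa`, `pca`, `cv`, `regression`, `significance`, `loocv`,
#'   `percentiles`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  subjects <- stage("load", load_pipeline_subjects(config))
  note("loaded ", length(subjects), " subjects")

  reference <- subjects[[1]]$landmarks
  subjects <- stage("align", lapply(subjects, align_three_point,
                                    reference = reference))
  note("three-point alignment done")

  sls <- stage("semilandmarks", lapply(subjects, function(s) {
    assemble_semilandmarks(s$curves, config$counts)
  }))
  partitions <- stage("junctions", lapply(sls, partition_sutures,
                                          cfg = config$junction))
  template_partition <- partitions[[1]]
  dir.create(out("partitions"), showWarnings = FALSE)
  for (i in seq_along(partitions)) {
    write_partition(partitions[[i]],
                    out("partitions",
                        paste0(sls[[i]]$subject_id[1], ".json")))
  }
  note("partitions written")

  records <- stage("morphometrics", purrr::map_dfr(seq_along(sls), function(i) {
    measure_subject(sls[[i]], partitions[[i]], subjects[[i]]$landmarks,
                    surface_area = TRUE, target_edge = config$target_edge)
  }))
  write_morphometrics(records, out("morphometrics.csv"))
  note("morphometrics written")

  sl_all <- dplyr::bind_rows(sls)
  gpa <- stage("gpa", gpa_align(sl_all))
  slid <- if (config$slide_iterations > 0) {
    stage("sliding", slide_semilandmarks(gpa, anchors = template_partition,
                                         iterations =
                                           config$slide_iterations))
  } else {
    gpa
  }
  note("superimposition done")

  sm <- standardize_shapes(slid$aligned)
  k <- config$components %||%
    components_for_variance(sm, config$variance_threshold)
  k <- min(k, nrow(sm$G) - 1L)
  pca <- stage("pca", fit_shape_pca(sm, k))
  note("pca with ", k, " components (evr ",
       sprintf("%.4f", sum(pca$evr)), ")")

  cv <- NULL
  if (!is.null(config$folds) && config$folds >= 2 &&
      length(subjects) >= config$folds) {
    cv <- stage("crossval", crossval_reduction(
      slid$aligned, methods = config$cv_methods, k = k,
      folds = config$folds, seed = config$seed))
    readr::write_csv(cv$table, out("cv_table.csv"))
    note("reduction cross-validation written")
  }

  reg <- stage("regression", fit_shape_regression(pca, records,
                                                  config$features))
  sig <- stage("significance", covariate_significance(pca, records,
                                                      config$features))
  readr::write_csv(sig, out("significance.csv"))
  bundle <- list(k = k, features = config$features,
                 coef = reg$coef, feature_center = reg$features$center,
                 feature_scale = reg$features$scale,
                 standardize_center = sm$center, standardize_scale = sm$scale,
                 basis = pca$basis, evr = pca$evr)
  jsonlite::write_json(bundle, out("model.json"), digits = NA)
  note("regression model written")

  loocv <- NULL
  if (isTRUE(config$run_loocv)) {
    loocv <- stage("loocv", loocv_shape_model(
      slid$aligned, records, config$features, k = k,
      partition = template_partition))
    readr::write_csv(loocv$per_subject, out("loocv_subjects.csv"))
    readr::write_csv(loocv$per_part, out("loocv_parts.csv"))
    readr::write_csv(loocv$measures, out("loocv_measures.csv"))
    note("loocv written")
  }

  pct <- stage("percentiles", percentile_shapes(
    reg, records, config$percentiles, partition = template_partition))
  readr::write_csv(pct$shapes, out("percentile_shapes.csv"))
  if (!is.null(pct$normalized_sizes)) {
    readr::write_csv(pct$sizes, out("percentile_sizes.csv"))
    readr::write_csv(pct$normalized_sizes,
                     out("percentile_sizes_normalized.csv"))
  }
  note("percentile shapes written")
  writeLines(log_lines, out("run.log"))

  invisible(structure(
    list(records = records, partitions = partitions, gpa = gpa, slid = slid,
         pca = pca, cv = cv, regression = reg, significance = sig,
         loocv = loocv, percentiles = pct, config = config,
         files = list.files(config$output_dir, recursive = TRUE)),
    class = "pipeline_result"
  ))
}
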