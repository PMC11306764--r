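# The synthetic generator: validity, determinism, ground-truth consistency.

test_that("generated subjects pass all input validators", {
  subj <- default_subject()
  expect_silent(validate_border_curves(subj$curves))
  expect_silent(validate_landmarks(subj$landmarks))
  expect_silent(validate_semilandmarks(subj$sl))
})

test_that("a fixed seed reproduces the population bitwise", {
  cfg <- synthetic_config(seed = 23, n_subjects = 3)
  p1 <- generate_population(cfg, "curves")
  p2 <- generate_population(cfg, "curves")
  expect_identical(p1$latents, p2$latents)
  expect_identical(p1$subjects[[2]]$curves, p2$subjects[[2]]$curves)
  s1 <- generate_population(cfg, "semilandmarks")
  s2 <- generate_population(cfg, "semilandmarks")
  expect_identical(s1$sl, s2$sl)
})

test_that("zero interdigitation gives ground-truth SI of 1 (flat vault)", {
  # on a curved vault even a straight template suture has arc > chord, so the
  # SI-of-1 identity is checked on a near-flat fixture
  cfg <- synthetic_config(seed = 2, az = 2, noise_sd = 0,
                          amplitudes = c(metopic = 0, sagittal = 0,
                                         coronal = 0, squamosal = 0,
                                         lambdoid = 0))
  subj <- generate_subject(cfg, subject_seed = 1, subject_id = "s",
                           latents = list(size = 1, area = 1, si = 1))
  tm <- subj$truth$measures
  expect_equal(tm$si[tm$suture == "sagittal"], 1, tolerance = 1e-3)
  expect_equal(tm$si[tm$suture == "metopic"], 1, tolerance = 1e-3)
  expect_true(all(tm$si >= 1 - 1e-9))
  # curved-course sutures (squamosal arch, coronal/lambdoid bends) retain
  # their path sinuosity even without interdigitation
  expect_true(all(tm$si < 1.06))

  # curved default vault: SIs stay modest without interdigitation
  cfg2 <- synthetic_config(seed = 2, noise_sd = 0,
                           amplitudes = c(metopic = 0, sagittal = 0,
                                          coronal = 0, squamosal = 0,
                                          lambdoid = 0))
  subj2 <- generate_subject(cfg2, subject_seed = 1, subject_id = "s",
                            latents = list(size = 1, area = 1, si = 1))
  expect_true(all(subj2$truth$measures$si < 1.06))
})

test_that("default cranial dimensions follow the configured population", {
  cfg <- synthetic_config(seed = 5, n_subjects = 25)
  pop <- generate_population(cfg, "curves")
  L <- vapply(pop$subjects, function(s) s$truth$cranial$cranial_length,
              numeric(1))
  expect_lt(abs(mean(L) - 125.44), 4 * 125.44 * 0.0607 / sqrt(25))
  expect_gt(stats::sd(L), 2)
  C <- vapply(pop$subjects, function(s) s$truth$cranial$cranial_circumference,
              numeric(1))
  expect_true(all(C > 300 & C < 430))
})

test_that("noiseless semilandmark population has rank <= 3 and a dominant
           size axis", {
  pop <- linear_population(n = 30)
  G0 <- geometry_matrix(pop$sl)
  sv <- svd(scale(G0, scale = FALSE), nu = 0, nv = 0)$d
  expect_lte(sum(sv > 1e-8 * sv[1]), 3)
  pca <- fit_shape_pca(standardize_shapes(G0), 3)
  expect_gt(abs(stats::cor(pca$scores[, 1], pop$latents$size)), 0.99)
})

test_that("geometrically inconsistent configurations are rejected", {
  expect_error(synthetic_config(seed = 1, af_diagonals = c(30, 80)),
               "fontanelle wider than vault")
  expect_error(synthetic_config(seed = 1, n_subjects = 0))
})

test_that("ground-truth junctions are detectable within one ordinal at the
           default thresholds", {
  for (sd_ in c(5, 23)) {
    subj <- if (sd_ == 5) default_subject() else {
      cfg <- synthetic_config(seed = 7)
      s <- generate_subject(cfg, subject_seed = sd_, subject_id = "S")
      s$sl <- assemble_semilandmarks(s$curves)
      s$partition <- suppressWarnings(partition_sutures(s$sl))
      s
    }
    lab <- c("JP3", "JP9", "JP10", "JP7", paste0("JP", 13:18), "JP25", "JP26",
             paste0("JP", 29:32))
    det <- subj$partition$junctions
    dd <- det$ordinal[match(lab, det$jp)]
    expect_lte(max(abs(dd - subj$truth$junctions$ordinal)), 1)
  }
})

test_that("subjects without fontanelle widening cannot be partitioned", {
  flat <- flat_parallel_curves()
  counts <- stats::setNames(as.integer(c(100, 100, 200, 200, 50, 50, 100)),
                            as.character(1:7))
  sl <- assemble_semilandmarks(flat, counts)
  expect_error(partition_sutures(sl), "partition failure: JP3")
})

test_that("curves-mode subjects carry usable landmarks and contours", {
  subj <- default_subject()
  cm <- cranial_measurements(subj$landmarks)
  expect_equal(cm$cranial_length, subj$truth$cranial$cranial_length,
               tolerance = 1e-9)
  expect_equal(cm$cranial_circumference,
               subj$truth$cranial$cranial_circumference, tolerance = 1e-9)
})
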