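# Suture and cranial measurements against analytic and quadrature oracles.

# a minimal two-edge "suture" partition on borders 1 and 2
toy_partition <- function(n) {
  suturemorph:::new_suture_partition(
    junctions = tibble::tibble(jp = character(0), border = integer(0),
                               ordinal = integer(0)),
    parts = tibble::tibble(part = "metopic", border = c(1L, 2L),
                           start = 1L, end = as.integer(n),
                           edge = c(1L, 2L), side = c("L", "R"))
  )
}

toy_sl <- function(xy1, xy2) {
  n <- nrow(xy1)
  dplyr::bind_rows(
    tibble::tibble(subject_id = "t", border = 1L, ordinal = seq_len(n),
                   x = xy1[, 1], y = xy1[, 2], z = 0),
    tibble::tibble(subject_id = "t", border = 2L, ordinal = seq_len(n),
                   x = xy2[, 1], y = xy2[, 2], z = 0)
  )
}

test_that("suture length is the mean of the two edge arc lengths", {
  a <- cbind(seq(0, 60, length.out = 50), 0)
  b <- cbind(seq(0, 40, length.out = 50), 2)
  sl <- toy_sl(a, b)
  part <- toy_partition(50)
  expect_equal(suture_length(sl, part, "metopic"), 50)
})

test_that("widths: parallel edges, brute-force nearest, and fused sutures", {
  a <- cbind(seq(0, 50, length.out = 40), 0)
  b <- cbind(seq(0, 50, length.out = 40), 2)
  sl <- toy_sl(a, b)
  part <- toy_partition(40)
  expect_equal(suture_width(sl, part, "metopic", mode = "paired"), 2)
  expect_equal(suture_width(sl, part, "metopic", mode = "nearest"), 2,
               tolerance = 1e-9)

  # nearest mode equals the exhaustive pairwise minimum average
  set.seed(4)
  b2 <- cbind(seq(0, 50, length.out = 40),
              2 + 0.5 * sin(seq(0, 50, length.out = 40)))
  sl2 <- toy_sl(a, b2)
  A <- as.matrix(sl2[sl2$border == 1, c("x", "y", "z")])
  B <- as.matrix(sl2[sl2$border == 2, c("x", "y", "z")])
  brute <- mean(apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2)))))
  expect_equal(suture_width(sl2, part, "metopic", mode = "nearest"), brute)

  # paired >= nearest, pointwise minimum dominates
  expect_gte(suture_width(sl2, part, "metopic", mode = "paired"),
             suture_width(sl2, part, "metopic", mode = "nearest"))

  # zero-width (fused) suture is accepted
  slz <- toy_sl(a, cbind(a[, 1], a[, 2] + 1e-12))
  expect_equal(suture_width(slz, part, "metopic"), 0, tolerance = 1e-9)

  # paired mode on a non-midline part falls back with a warning
  part_cor <- part
  part_cor$parts$part <- "coronal"
  expect_warning(w <- suture_width(sl, part_cor, "coronal", mode = "paired"),
                 "falling back")
  expect_equal(w, 2, tolerance = 1e-9)
})

test_that("sinuosity index: straight, semicircular and sinusoidal sutures", {
  a <- cbind(seq(0, 50, length.out = 100), 0)
  sl <- toy_sl(a, cbind(a[, 1], a[, 2] + 2))
  part <- toy_partition(100)
  expect_equal(sinuosity_index(sl, part, "metopic"), 1, tolerance = 1e-9)

  th <- seq(0, pi, length.out = 100)
  semi <- cbind(5 * cos(th), 5 * sin(th))
  sl2 <- toy_sl(semi, cbind(semi[, 1], semi[, 2] + 2))
  si <- sinuosity_index(sl2, part, "metopic")
  expect_equal(si, pi / 2, tolerance = 0.002 * pi / 2)

  # sinusoid: SI equals numerically integrated arc length / span
  lam <- 10; A_ <- 2
  xs <- seq(0, 50, length.out = 5000)
  dense <- cbind(xs, A_ * sin(2 * pi * xs / lam))
  arc <- suturemorph:::polyline_length(cbind(dense, 0))
  expected <- arc / 50
  xs2 <- seq(0, 50, length.out = 400)
  sin2 <- cbind(xs2, A_ * sin(2 * pi * xs2 / lam))
  sl3 <- toy_sl(sin2, cbind(sin2[, 1], sin2[, 2] + 30))
  expect_equal(sinuosity_index(sl3, toy_partition(400), "metopic"), expected,
               tolerance = 1e-3)

  closed <- toy_sl(rbind(a, a[rev(seq_len(nrow(a))), ]),
                   rbind(a, a[rev(seq_len(nrow(a))), ]) + 2)
  expect_error(sinuosity_index(closed, toy_partition(200), "metopic"),
               "undefined SI")
})

test_that("cranial measurements: distances and contour quadrature", {
  mk_lm <- function(contour) {
    list(points = tibble::tibble(
      landmark = c("rhinion", "fmoR", "fmoL", "glabella", "opisthocranion",
                   "eurionL", "eurionR"),
      x = c(0, 20, -20, 0, 0, -53.5, 53.5),
      y = c(60, 55, 55, 62.7, -62.7, 0, 0),
      z = c(-3, -2, -2, 0, 0, 0, 0)),
      axial_contour = contour)
  }
  th <- seq(0, 2 * pi, length.out = 2001)
  r <- 58.4
  # circle must pass through glabella/opisthocranion: centre offset on y
  circ <- tibble::tibble(x = r * cos(th), y = r * sin(th) + (62.7 - r), z = 0)
  lm <- mk_lm(circ)
  out <- suppressWarnings(cranial_measurements(lm))
  expect_equal(out$cranial_length, 125.4)
  expect_equal(out$cranial_width, 107)
  expect_equal(out$cranial_circumference, 2 * pi * r,
               tolerance = 0.001)

  # ellipse circumference within 0.1% of the elliptic-integral value
  a_ <- 62.7; b_ <- 53.5
  ell <- tibble::tibble(x = b_ * sin(th), y = a_ * cos(th), z = 0)
  exact <- 4 * a_ * stats::integrate(function(t) {
    sqrt(1 - (1 - (b_ / a_)^2) * sin(t)^2)
  }, 0, pi / 2, rel.tol = 1e-12)$value
  out2 <- cranial_measurements(mk_lm(ell))
  expect_equal(out2$cranial_circumference, exact, tolerance = 1e-3)

  # missing contour: C reported missing, never extrapolated
  out3 <- cranial_measurements(mk_lm(NULL))
  expect_true(is.na(out3$cranial_circumference))

  # contour far from glabella warns
  far <- tibble::tibble(x = 10 * cos(th), y = 10 * sin(th), z = 0)
  expect_warning(cranial_measurements(mk_lm(far)), "mm from glabella")
})

test_that("all morphometrics are rigid-invariant and SI >= 1", {
  subj <- default_subject()
  set.seed(8)
  tf <- list(rotation = suturemorph:::random_rotation(),
             translation = stats::rnorm(3, 0, 30))
  sl2 <- transform_points(subj$sl, tf)
  part <- subj$partition
  for (p in c("metopic", "sagittal", "coronal")) {
    expect_equal(suture_length(sl2, part, p), suture_length(subj$sl, part, p),
                 tolerance = 1e-9)
    expect_equal(suture_width(sl2, part, p), suture_width(subj$sl, part, p),
                 tolerance = 1e-9)
    si <- sinuosity_index(sl2, part, p)
    expect_equal(si, sinuosity_index(subj$sl, part, p), tolerance = 1e-9)
    expect_gte(si, 1 - 1e-9)
  }
})

test_that("measured suture morphology matches generator ground truth", {
  subj <- default_subject()
  truth <- subj$truth$measures
  for (p in truth$suture) {
    expect_equal(suture_length(subj$sl, subj$partition, p),
                 truth$length[truth$suture == p], tolerance = 0.03)
    expect_equal(suture_width(subj$sl, subj$partition, p),
                 truth$width[truth$suture == p], tolerance = 0.03)
    expect_equal(sinuosity_index(subj$sl, subj$partition, p),
                 truth$si[truth$suture == p], tolerance = 0.01)
  }
})
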