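# Thin-plate splines, triangulation and Heron areas against analytic oracles.

test_that("TPS reproduces an affine height field exactly", {
  set.seed(2)
  uv <- cbind(runif(30, -5, 5), runif(30, -5, 5))
  h <- 2 * uv[, 1] + 3 * uv[, 2] + 1
  f <- fit_tps(uv, h)
  expect_lt(max(abs(f$weights)), 1e-8)
  grid <- cbind(runif(50, -5, 5), runif(50, -5, 5))
  expect_lt(max(abs(predict(f, grid) - (2 * grid[, 1] + 3 * grid[, 2] + 1))),
            1e-8)
})

test_that("interpolating TPS has zero residual at its inputs", {
  set.seed(3)
  uv <- cbind(runif(40), runif(40))
  h <- sin(3 * uv[, 1]) * cos(2 * uv[, 2])
  f <- fit_tps(uv, h)
  expect_lt(max(abs(predict(f, uv) - h)), 1e-9)
})

test_that("held-out TPS residual decreases with sampling density", {
  set.seed(4)
  test_pts <- cbind(runif(200, 0.1, 2.9), runif(200, 0.1, 2.9))
  truth <- sin(test_pts[, 1]) * cos(test_pts[, 2])
  res <- vapply(c(5, 9, 17), function(m) {
    g <- as.matrix(expand.grid(seq(0, 3, length.out = m),
                               seq(0, 3, length.out = m)))
    f <- fit_tps(g, sin(g[, 1]) * cos(g[, 2]))
    sqrt(mean((predict(f, test_pts) - truth)^2))
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("duplicate projections merge; conflicting heights and collinear
           points are errors", {
  uv <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(1, 1))
  f <- fit_tps(uv, c(0, 1, 1, 2, 2 + 1e-8))
  expect_equal(length(f$weights), 4)
  expect_error(fit_tps(uv, c(0, 1, 1, 2, 5)), "conflicting heights")
  line_pts <- cbind(seq(0, 1, length.out = 6), seq(0, 2, length.out = 6))
  expect_error(fit_tps(line_pts, rnorm(6)), "collinear")
})

test_that("Heron area: right triangle and unit square", {
  tri <- suturemorph:::new_triangulated_surface(
    rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)), matrix(c(1, 2, 3), 1))
  expect_identical(as.numeric(surface_area_heron(tri)), 6)
  sq <- suturemorph:::new_triangulated_surface(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(as.numeric(surface_area_heron(sq)), 1)
})

test_that("degenerate triangles are excluded with a warning and counted", {
  surf <- suturemorph:::new_triangulated_surface(
    rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0), c(6, 0, 0)),
    rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_warning(a <- surface_area_heron(surf), "degenerate")
  expect_equal(as.numeric(a), 6)
  expect_equal(attr(a, "degenerate"), 1)
})

test_that("triangulated planar rhombus area is within 1% of d1*d2/2", {
  rh <- rbind(c(10, 0), c(0, 7), c(-10, 0), c(0, -7))
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  support <- cbind(rbind(rh, cbind(12 * cos(th), 12 * sin(th))), 0)
  patch <- fit_tps_patch(support, "XY")
  surf <- triangulate_patch(patch, list(boundary = rh), target_edge = 0.3)
  expect_equal(as.numeric(surface_area_heron(surf)), 20 * 14 / 2,
               tolerance = 0.01)
  # planar region: all lifted triangles coplanar
  expect_lt(max(abs(surf$vertices[, 3])), 1e-9)
})

test_that("mesh density follows the target edge", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  patch <- fit_tps_patch(cbind(rbind(sq, c(0.5, 0.5)), 0), "XY")
  surf <- triangulate_patch(patch, list(boundary = sq), target_edge = 0.1)
  me <- mean_edge_length(surf)
  expect_gte(me, 0.05)
  expect_lte(me, 0.15)
})

test_that("spherical cap area is within 1% of 2*pi*R*h at 0.3 mm edges", {
  R <- 10; h <- 2
  a <- sqrt(h * (2 * R - h))
  g <- expand.grid(u = seq(-a, a, by = 0.35), v = seq(-a, a, by = 0.35))
  g <- g[g$u^2 + g$v^2 <= a^2, ]
  patch <- fit_tps_patch(
    cbind(g$u, g$v, sqrt(R^2 - g$u^2 - g$v^2) - (R - h)), "XY")
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  surf <- triangulate_patch(patch, list(boundary = cbind(a * cos(th),
                                                         a * sin(th))),
                            target_edge = 0.3)
  expect_equal(as.numeric(surface_area_heron(surf)), 2 * pi * R * h,
               tolerance = 0.01)
})

test_that("total area: 5 patches, scaling law, and refinement convergence", {
  subj <- default_subject()
  res <- suppressWarnings(total_suture_area(subj$sl, subj$partition,
                                            target_edge = 0.6))
  expect_equal(nrow(res$patches), 5)
  expect_setequal(res$patches$patch,
                  c("superior", "lateral_L", "lateral_R", "anterior",
                    "posterior"))
  expect_false(res$partial)
  expect_equal(sum(res$patches$area), res$total)

  # similarity scaling multiplies areas by c^2
  sl2 <- subj$sl
  sl2[, c("x", "y", "z")] <- sl2[, c("x", "y", "z")] * 1.3
  res2 <- suppressWarnings(total_suture_area(sl2, subj$partition,
                                             target_edge = 0.6 * 1.3))
  expect_equal(res2$total, res$total * 1.3^2, tolerance = 0.01)

  # refining the edge gives Cauchy-shrinking increments
  areas <- vapply(c(1.2, 0.6, 0.3), function(e) {
    suppressWarnings(total_suture_area(subj$sl, subj$partition,
                                       target_edge = e))$total
  }, numeric(1))
  expect_lt(abs(areas[3] - areas[2]), abs(areas[2] - areas[1]) + 1e-9)
})

test_that("near-flat cranium total area matches the 2D footprint oracle", {
  cfg <- synthetic_config(seed = 13, az = 2, noise_sd = 0, displace = FALSE,
                          amplitudes = c(metopic = 0, sagittal = 0,
                                         coronal = 0, squamosal = 0,
                                         lambdoid = 0))
  subj <- generate_subject(cfg, subject_seed = 2, subject_id = "flat")
  sl <- assemble_semilandmarks(subj$curves)
  part <- suppressWarnings(partition_sutures(sl))
  res <- suppressWarnings(total_suture_area(sl, part, target_edge = 0.3))

  shoelace <- function(p) {
    n <- nrow(p)
    abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
  }
  tr <- subj$truth
  # left fontanelles counted twice (mirror symmetry)
  expected <- shoelace(tr$footprints$anterior_fontanelle) +
    shoelace(tr$footprints$posterior_fontanelle) +
    2 * shoelace(tr$footprints$sphenoidal_fontanelle_L) +
    2 * shoelace(tr$footprints$mastoid_fontanelle_L) +
    sum(vapply(names(tr$strips), function(nm) {
      st <- tr$strips[[nm]]
      quad <- rbind(st$a, st$b[rev(seq_len(nrow(st$b))), ])
      (if (grepl("_L$", nm)) 2 else 1) * shoelace(quad)
    }, numeric(1)))
  expect_equal(res$total, expected, tolerance = 0.02)
})
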