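# Synthetic infant-cranium border-curve generator with analytic ground truth.
#
# The vault is a half-ellipsoid; the seven borders are laid out in a 2D
# template plane (top view) following the tracing topology of partition.R,
# then lifted onto the ellipsoid. The anterior/posterior fontanelles are
# rhombi on the midline; the sphenoidal/mastoid fontanelles are circles at the
# lateral rim; sutures are parallel-edge strips. Interdigitation is an
# in-phase sinusoid on both edges of a suture (so the suture width stays
# constant, as for a real interdigitated suture whose two edges track each
# other), windowed to vanish smoothly at the junctions. Ground truth
# (junction arc-length fractions, suture length/width/SI by dense quadrature,
# cranial measures, 2D footprint polygons) is recorded before measurement
# noise is added.

#' Synthetic population configuration
#'
#' Defaults emulate a 2-4 month infant population: half-axes give cranial
#' length 125.4 mm, width 107.0 mm and circumference about 366 mm; suture base
#' widths are 1.54/5.45/1.88/2.24/2.62 mm (metopic/sagittal/coronal/squamosal/
#' lambdoid); the per-subject size scale has SD 0.0607 (7.61/125.44). Three
#' latent factors drive the population: overall size, a fontanelle/width
#' "area" factor, and an interdigitation "sinuosity" factor.
#'
#' @param n_subjects Number of subjects.
#' @param seed Mandatory RNG seed.
#' @param ax,ay,az Vault half-axes (mm): left-right, posterior-anterior,
#'   inferior-superior.
#' @param size_sd,area_sd,si_sd SDs of the three latent factors (mean 1).
#' @param af_diagonals,pf_diagonals Anterior/posterior fontanelle rhombus
#'   diagonals (anteroposterior, mediolateral; mm).
#' @param lateral_radius Sphenoidal/mastoid fontanelle radius (mm).
#' @param widths Named base suture widths (mm).
#' @param amplitudes Named interdigitation amplitudes (mm).
#' @param wavelength Interdigitation wavelength (mm).
#' @param noise_sd Coordinate noise SD (mm), added after ground truth.
#' @param dense_spacing Dense sampling spacing of the emitted polylines (mm).
#' @param counts Semilandmark counts per border (see [default_counts()]).
#' @param displace Apply a random rigid displacement per subject?
#' @param angle_sd Displacement rotation SD (degrees).
#' @param translation_sd Displacement translation SD (mm).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 30L, seed = 1L,
                             ax = 53.515, ay = 62.72, az = 45,
                             size_sd = 0.0607, area_sd = 0.08, si_sd = 0.25,
                             af_diagonals = c(30, 26),
                             pf_diagonals = c(15.5, 16),
                             lateral_radius = 6,
                             widths = c(metopic = 1.54, sagittal = 5.45,
                                        coronal = 1.88, squamosal = 2.24,
                                        lambdoid = 2.62),
                             amplitudes = c(metopic = 0.2, sagittal = 0.6,
                                            coronal = 0.3, squamosal = 0.15,
                                            lambdoid = 0.35),
                             wavelength = 12, noise_sd = 0.02,
                             dense_spacing = 0.25,
                             counts = default_counts(),
                             displace = TRUE, angle_sd = 8,
                             translation_sd = 15) {
  stopifnot(n_subjects >= 1, ax > 0, ay > 0, az > 0,
            all(af_diagonals > 0), all(pf_diagonals > 0), lateral_radius > 0,
            all(widths >= 0), all(amplitudes >= 0), wavelength > 0,
            noise_sd >= 0, dense_spacing > 0)
  if (missing(seed) && is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (af_diagonals[2] > 0.6 * ax || pf_diagonals[2] > 0.6 * ax) {
    stop("geometrically inconsistent config: fontanelle wider than vault",
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         ax = ax, ay = ay, az = az, size_sd = size_sd, area_sd = area_sd,
         si_sd = si_sd, af_diagonals = af_diagonals,
         pf_diagonals = pf_diagonals, lateral_radius = lateral_radius,
         widths = widths, amplitudes = amplitudes, wavelength = wavelength,
         noise_sd = noise_sd, dense_spacing = dense_spacing, counts = counts,
         displace = displace, angle_sd = angle_sd,
         translation_sd = translation_sd),
    class = "synthetic_config"
  )
}

# ---- 2D template helpers -----------------------------------------------------

densify <- function(a, b, spacing) {
  n <- max(4L, as.integer(ceiling(sqrt(sum((b - a)^2)) / spacing)) + 1L)
  cbind(seq(a[1], b[1], length.out = n), seq(a[2], b[2], length.out = n))
}

circ_arc <- function(center, r, phi0, phi1, spacing) {
  while (phi1 <= phi0) phi1 <- phi1 + 2 * pi
  n <- max(6L, as.integer(ceiling(r * (phi1 - phi0) / spacing)) + 1L)
  phi <- seq(phi0, phi1, length.out = n)
  cbind(center[1] + r * cos(phi), center[2] + r * sin(phi))
}

line_intersect <- function(p1, d1, p2, d2) {
  A <- cbind(d1, -d2)
  t <- solve(A, p2 - p1)
  p1 + t[1] * d1
}

# cut a dense polyline where it first enters the circle; the cut point lies
# exactly on the circle
trim_enter_circle <- function(poly, center, r) {
  d <- sqrt(rowSums(sweep(poly, 2, center)^2))
  idx <- which(d <= r)[1]
  if (is.na(idx) || idx == 1) {
    stop("polyline does not enter the trimming circle", call. = FALSE)
  }
  f <- (d[idx - 1] - r) / (d[idx - 1] - d[idx])
  cut <- poly[idx - 1, ] + f * (poly[idx, ] - poly[idx - 1, ])
  rbind(poly[seq_len(idx - 1), , drop = FALSE], cut)
}

mirror2 <- function(pts) cbind(-pts[, 1], pts[, 2])

piece <- function(pts, suture = NA_character_, side = "M", par = NULL,
                  dir = NULL, radial = FALSE, normal_of = NULL,
                  mirrored = FALSE) {
  list(pts = pts, suture = suture, side = side,
       par = par %||% seq_len(nrow(pts)), dir = dir, radial = radial,
       normal_of = normal_of, mirrored = mirrored)
}

proj2 <- function(pts, u) as.numeric(pts %*% u)

# ---- template construction ---------------------------------------------------

build_template <- function(cfg, a = 1, q = 1) {
  sp <- cfg$dense_spacing
  ax <- cfg$ax; ay <- cfg$ay
  w <- cfg$widths * a
  d1 <- cfg$af_diagonals[1] * a; d2 <- cfg$af_diagonals[2] * a
  p1 <- cfg$pf_diagonals[1] * a; p2 <- cfg$pf_diagonals[2] * a
  rf <- cfg$lateral_radius * a

  yN <- 0.96 * ay
  yA <- 0.38 * ay
  F_ <- c(0, yA + d1 / 2); Bk <- c(0, yA - d1 / 2); Lc <- c(-d2 / 2, yA)
  yP <- -0.72 * ay
  Pf <- c(0, yP + p1 / 2); Pb <- c(0, yP - p1 / 2); Pl <- c(-p2 / 2, yP)
  th_s <- 148 * pi / 180; th_m <- 212 * pi / 180
  rim <- function(th) cbind(0.96 * ax * cos(th), 0.96 * ay * sin(th))
  # lateral fontanelle centres midway between the two squamosal edges, so the
  # squamosal mouths are cut symmetrically
  inward <- function(pt, mm) pt * (1 - mm / sqrt(sum(pt^2)))
  Sph <- inward(as.numeric(rim(th_s)), w[["squamosal"]] / 2)
  Mst <- inward(as.numeric(rim(th_m)), w[["squamosal"]] / 2)

  ang <- function(p, center) atan2(p[2] - center[2], p[1] - center[1])

  # quadratic Bezier with approximately uniform spacing
  bez <- function(P0, C, P1, spacing) {
    t0 <- seq(0, 1, length.out = 400)
    pts <- outer((1 - t0)^2, P0) + outer(2 * t0 * (1 - t0), C) +
      outer(t0^2, P1)
    resample_polyline(pts, max(8L, as.integer(ceiling(
      polyline_length(pts) / spacing)) + 1L))
  }

  # offset edges of a centerline strip; both edges share the centerline
  # arc-length parameter (keeps interdigitation in phase across the suture)
  strip_edges <- function(center, width) {
    n <- nrow(center)
    tang <- rbind(center[2, ] - center[1, ],
                  center[3:n, ] - center[1:(n - 2), ],
                  center[n, ] - center[n - 1, ])
    tang <- tang / sqrt(rowSums(tang^2))
    nor <- cbind(tang[, 2], -tang[, 1])
    if (nor[1, 2] < 0) nor <- -nor   # orient toward anterior at the start
    par <- c(0, cumsum(segment_lengths(center)))
    list(a = center + nor * width / 2, b = center - nor * width / 2,
         par = par)
  }

  # keep the part of an edge polyline after its first crossing of a line
  cross_line <- function(pts, par, p0, dvec) {
    s <- (pts[, 1] - p0[1]) * dvec[2] - (pts[, 2] - p0[2]) * dvec[1]
    i <- which(s[-1] * s[-length(s)] <= 0)[1]
    if (is.na(i)) stop("edge does not cross the trimming line", call. = FALSE)
    f <- s[i] / (s[i] - s[i + 1])
    list(pt = pts[i, ] + f * (pts[i + 1, ] - pts[i, ]),
         par = par[i] + f * (par[i + 1] - par[i]), idx = i, frac = f)
  }
  trim_after_line <- function(pts, par, p0, dvec) {
    cr <- cross_line(pts, par, p0, dvec)
    list(pts = rbind(cr$pt, pts[(cr$idx + 1):nrow(pts), , drop = FALSE]),
         par = c(cr$par, par[(cr$idx + 1):length(par)]))
  }
  trim_before_circle <- function(pts, par, center, r) {
    d <- sqrt(rowSums(sweep(pts, 2, center)^2))
    i <- which(d <= r)[1]
    if (is.na(i) || i == 1) {
      stop("edge does not enter the trimming circle", call. = FALSE)
    }
    f <- (d[i - 1] - r) / (d[i - 1] - d[i])
    list(pts = rbind(pts[seq_len(i - 1), , drop = FALSE],
                     pts[i - 1, ] + f * (pts[i, ] - pts[i - 1, ])),
         par = c(par[seq_len(i - 1)], par[i - 1] + f * (par[i] - par[i - 1])))
  }

  # metopic: edge at x = -wm/2 from nasion to the AF front edge
  M_af <- F_ + (w[["metopic"]] / d2) * (Lc - F_)
  ms_edge <- densify(c(-w[["metopic"]] / 2, yN), M_af, sp)

  # coronal: curved centerline leaving the AF corner along the short diagonal
  # (the centerline starts inside the fontanelle so both offset edges cross
  # the rhombus edge lines, giving a symmetric suture mouth)
  cor_start <- Lc + c(0.25 * d2 / 2, 0)
  cor_center <- bez(cor_start, Lc + c(-0.45 * sqrt(sum((Sph - Lc)^2)), 0),
                    Sph, sp)
  cor_e <- strip_edges(cor_center, w[["coronal"]])
  cfr <- trim_after_line(cor_e$a, cor_e$par, F_, Lc - F_)    # frontal edge
  cfr <- trim_before_circle(cfr$pts, cfr$par, Sph, rf)
  cpa <- trim_after_line(cor_e$b, cor_e$par, Bk, Lc - Bk)    # parietal edge
  cpa <- trim_before_circle(cpa$pts, cpa$par, Sph, rf)
  X_fc <- cfr$pts[1, ]; X_pc <- cpa$pts[1, ]

  # lambdoid: curved centerline leaving the PF corner along the short diagonal
  lam_start <- Pl + c(0.4 * p2 / 2, 0)
  lam_center <- bez(lam_start, Pl + c(-0.5 * sqrt(sum((Mst - Pl)^2)), 0),
                    Mst, sp)
  lam_e <- strip_edges(lam_center, w[["lambdoid"]])
  lpa <- trim_after_line(lam_e$a, lam_e$par, Pf, Pl - Pf)    # parietal edge
  lpa <- trim_before_circle(lpa$pts, lpa$par, Mst, rf)
  loc <- trim_after_line(lam_e$b, lam_e$par, Pb, Pl - Pb)    # occipital edge
  loc <- trim_before_circle(loc$pts, loc$par, Mst, rf)
  X_lp <- lpa$pts[1, ]; X_lo <- loc$pts[1, ]

  # squamosal: temporal edge on the rim, parietal edge offset inward; both
  # sampled at the same rim angles (shared parameter)
  th_grid <- seq(th_s - 0.35, th_m + 0.35, length.out = 3000)
  sq_t_all <- rim(th_grid)
  sq_p_all <- sq_t_all * (1 - w[["squamosal"]] / sqrt(rowSums(sq_t_all^2)))
  arc_par <- 0.96 * sqrt(ax * ay) * th_grid
  # resample a trimmed edge to the emission spacing (carrying the shared
  # parameter by arc-length interpolation)
  respace <- function(e, spacing) {
    s <- c(0, cumsum(segment_lengths(e$pts)))
    n <- max(8L, as.integer(ceiling(s[length(s)] / spacing)) + 1L)
    list(pts = resample_polyline(e$pts, n),
         par = stats::approx(s, e$par, xout = seq(0, s[length(s)],
                                                  length.out = n))$y)
  }
  # temporal edge: trim at both fontanelle circles
  trim_both <- function(pts, par) {
    a_ <- trim_before_circle(pts[rev(seq_len(nrow(pts))), , drop = FALSE],
                             rev(par), Sph, rf)
    b_ <- trim_before_circle(a_$pts[rev(seq_len(nrow(a_$pts))), ,
                                    drop = FALSE],
                             rev(a_$par), Mst, rf)
    b_
  }
  sq_temp <- respace(trim_both(sq_t_all, arc_par), sp)  # sphenoid -> mastoid
  sq_par_f <- respace(trim_both(sq_p_all, arc_par), sp)
  # parietal edge travels mastoid -> sphenoid on border 3
  sq_par <- list(pts = sq_par_f$pts[rev(seq_len(nrow(sq_par_f$pts))), ],
                 par = rev(sq_par_f$par))

  # sagittal: edge at x = -ws/2 between AF back edge and PF front edge
  C3 <- Bk + (w[["sagittal"]] / d2) * (Lc - Bk)
  J7 <- Pf + (w[["sagittal"]] / p2) * (Pl - Pf)
  sag_edge <- densify(C3, J7, sp)

  gap_s <- 1.5 / rf  # angular gap (about 1.5 mm chord) between bone edges
                     # meeting around a lateral fontanelle

  # ---- border 1: metopic | AF front-left | coronal frontal | sphenoid arc
  b1 <- list(
    piece(ms_edge, "metopic", "M", par = proj2(ms_edge, c(0, -1)),
          dir = c(1, 0)),
    piece(densify(M_af, X_fc, sp)),
    piece(cfr$pts, "coronal", "L", par = cfr$par, dir = NULL, radial = FALSE,
          normal_of = "coronal"),
    piece(circ_arc(Sph, rf, ang(cfr$pts[nrow(cfr$pts), ], Sph),
                   atan2(Sph[2], Sph[1]) - gap_s, sp))
  )
  # ---- border 3: sagittal | PF front-left | lambdoid parietal | mastoid arc |
  #      squamosal parietal | sphenoid arc | coronal parietal | AF back-left
  par_arc <- circ_arc(Mst, rf, ang(lpa$pts[nrow(lpa$pts), ], Mst),
                      ang(sq_par$pts[1, ], Mst), sp)
  sph_par_arc <- circ_arc(Sph, rf, ang(sq_par$pts[nrow(sq_par$pts), ], Sph),
                          ang(cpa$pts[nrow(cpa$pts), ], Sph), sp)
  cpa_rev <- list(pts = cpa$pts[rev(seq_len(nrow(cpa$pts))), ],
                  par = rev(cpa$par))
  b3 <- list(
    piece(sag_edge, "sagittal", "M", par = proj2(sag_edge, c(0, -1)),
          dir = c(1, 0)),
    piece(densify(J7, X_lp, sp)),
    piece(lpa$pts, "lambdoid", "L", par = lpa$par, normal_of = "lambdoid"),
    piece(par_arc),
    piece(sq_par$pts, "squamosal", "L", par = sq_par$par, radial = TRUE),
    piece(sph_par_arc),
    piece(cpa_rev$pts, "coronal", "L", par = cpa_rev$par,
          normal_of = "coronal"),
    # stop just short of the corner so the border's two endpoints are
    # corner-adjacent but not coincident
    piece(densify(X_pc, X_pc + 0.97 * (C3 - X_pc), sp))
  )
  # ---- border 5: sphenoid arc | squamosal temporal | mastoid arc
  b5_arc_s <- circ_arc(Sph, rf, atan2(Sph[2], Sph[1]) + gap_s,
                       ang(sq_temp$pts[1, ], Sph), sp)
  b5_arc_m <- circ_arc(Mst, rf, ang(sq_temp$pts[nrow(sq_temp$pts), ], Mst),
                       atan2(Mst[2], Mst[1]) - gap_s, sp)
  b5 <- list(
    piece(b5_arc_s),
    piece(sq_temp$pts, "squamosal", "L", par = sq_temp$par, radial = TRUE),
    piece(b5_arc_m)
  )
  # ---- border 7: mastoid arc L | lambdoid occipital L | PF back edges |
  #      lambdoid occipital R | mastoid arc R
  loc_rev <- list(pts = loc$pts[rev(seq_len(nrow(loc$pts))), ],
                  par = rev(loc$par))
  occ_arc_L <- circ_arc(Mst, rf, atan2(Mst[2], Mst[1]) + gap_s,
                        ang(loc_rev$pts[1, ], Mst), sp)
  pf_bl <- densify(X_lo, Pb, sp)
  pf_br <- densify(Pb, c(-X_lo[1], X_lo[2]), sp)
  b7L <- list(
    piece(occ_arc_L),
    piece(loc_rev$pts, "lambdoid", "L", par = loc_rev$par,
          normal_of = "lambdoid"),
    piece(pf_bl),
    piece(pf_br)
  )
  midline <- c("metopic", "sagittal")
  mirror_piece <- function(p, side) {
    # midline sutures pair across the mirror: keep one group ("M") and the
    # same displacement direction so both edges stay in phase
    keep_dir <- !is.na(p$suture) && p$suture %in% midline
    piece(mirror2(p$pts), p$suture,
          if (is.na(p$suture) || keep_dir) "M" else side,
          par = p$par,
          dir = if (is.null(p$dir)) NULL
                else if (keep_dir) p$dir else c(-p$dir[1], p$dir[2]),
          radial = p$radial, normal_of = p$normal_of, mirrored = TRUE)
  }
  rev_piece <- function(p) {
    piece(p$pts[rev(seq_len(nrow(p$pts))), , drop = FALSE], p$suture, p$side,
          par = rev(p$par), dir = p$dir, radial = p$radial,
          normal_of = p$normal_of, mirrored = p$mirrored)
  }
  b7R <- list(rev_piece(mirror_piece(b7L[[2]], "R")),
              rev_piece(mirror_piece(b7L[[1]], "R")))
  b7 <- c(b7L, b7R)

  borders <- list(`1` = b1, `2` = lapply(b1, mirror_piece, side = "R"),
                  `3` = b3, `4` = lapply(b3, mirror_piece, side = "R"),
                  `5` = b5, `6` = lapply(b5, mirror_piece, side = "R"),
                  `7` = b7)

  # direction fields for the curved strips: the centerline normal, looked up
  # by the shared arc-length parameter
  normal_lookup <- list(
    coronal = list(center = cor_center),
    lambdoid = list(center = lam_center)
  )
  normal_at <- function(suture, par, mirrored) {
    center <- normal_lookup[[suture]]$center
    cum <- c(0, cumsum(segment_lengths(center)))
    n <- nrow(center)
    tang <- rbind(center[2, ] - center[1, ],
                  center[3:n, ] - center[1:(n - 2), ],
                  center[n, ] - center[n - 1, ])
    tang <- tang / sqrt(rowSums(tang^2))
    nor <- cbind(tang[, 2], -tang[, 1])
    if (nor[1, 2] < 0) nor <- -nor
    idx <- pmin(n, pmax(1, findInterval(par, cum)))
    out <- nor[idx, , drop = FALSE]
    if (isTRUE(mirrored)) out[, 1] <- -out[, 1]
    out
  }

  # interdigitation: in-phase sinusoid per (suture, side) group
  amp <- cfg$amplitudes * q
  groups <- list()
  for (b in names(borders)) {
    for (i in seq_along(borders[[b]])) {
      p <- borders[[b]][[i]]
      if (!is.na(p$suture)) {
        key <- paste(p$suture, p$side)
        groups[[key]] <- rbind(groups[[key]],
                               data.frame(border = b, idx = i))
      }
    }
  }
  for (key in names(groups)) {
    g <- groups[[key]]
    suture <- borders[[g$border[1]]][[g$idx[1]]]$suture
    A <- amp[[suture]]
    if (A <= 0) next
    pars <- unlist(lapply(seq_len(nrow(g)), function(r) {
      borders[[g$border[r]]][[g$idx[r]]]$par
    }))
    pr <- range(pars)
    span <- diff(pr)
    cycles <- max(2L, round(span / cfg$wavelength))
    for (r in seq_len(nrow(g))) {
      p <- borders[[g$border[r]]][[g$idx[r]]]
      t_ <- (p$par - pr[1]) / span
      disp <- A * sin(2 * pi * cycles * t_) * sin(pi * t_)^2
      dirm <- if (p$radial) {
        p$pts / sqrt(rowSums(p$pts^2))
      } else if (!is.null(p$normal_of)) {
        normal_at(p$normal_of, p$par, p$mirrored)
      } else {
        matrix(p$dir, nrow(p$pts), 2, byrow = TRUE)
      }
      p$pts <- p$pts + dirm * disp
      borders[[g$border[r]]][[g$idx[r]]] <- p
    }
  }

  # 2D footprint primitives (for area ground truth on near-flat fixtures)
  af_fl <- densify(M_af, X_fc, sp)
  af_bl <- densify(X_pc, C3, sp)
  pf_fl <- densify(J7, X_lp, sp)
  footprints <- list(
    anterior_fontanelle = rbind(
      af_fl, af_bl, mirror2(af_bl)[rev(seq_len(nrow(af_bl))), ],
      mirror2(af_fl)[rev(seq_len(nrow(af_fl))), ]),
    posterior_fontanelle = rbind(
      pf_fl, pf_bl, pf_br, mirror2(pf_fl)[rev(seq_len(nrow(pf_fl))), ]),
    sphenoidal_fontanelle_L = rbind(b1[[4]]$pts, b5_arc_s, sph_par_arc),
    mastoid_fontanelle_L = rbind(par_arc, b5_arc_m, occ_arc_L),
    strips = list(
      metopic = list(a = ms_edge, b = mirror2(ms_edge)),
      sagittal = list(a = sag_edge, b = mirror2(sag_edge)),
      coronal_L = list(a = cfr$pts, b = cpa$pts),
      squamosal_L = list(a = sq_temp$pts,
                         b = sq_par$pts[rev(seq_len(nrow(sq_par$pts))), ]),
      lambdoid_L = list(a = lpa$pts, b = loc$pts)
    )
  )

  list(borders = borders, footprints = footprints,
       anchors = list(Lc = Lc, Sph = Sph, Mst = Mst, Pl = Pl, C3 = C3,
                      J7 = J7, M_af = M_af, X_fc = X_fc, X_pc = X_pc,
                      X_lp = X_lp, X_lo = X_lo))
}

lift_to_vault <- function(pts2, cfg) {
  r2 <- (pts2[, 1] / cfg$ax)^2 + (pts2[, 2] / cfg$ay)^2
  cbind(pts2[, 1], pts2[, 2], cfg$az * sqrt(pmax(0, 1 - r2)))
}

assemble_border_3d <- function(pieces, cfg, scale) {
  pts <- NULL
  boundary_s <- numeric(0)
  for (p in pieces) {
    m <- lift_to_vault(p$pts, cfg) * scale
    if (!is.null(pts) &&
        sqrt(sum((pts[nrow(pts), ] - m[1, ])^2)) < 1e-9) {
      m <- m[-1, , drop = FALSE]
    }
    pts <- rbind(pts, m)
    s_tot <- polyline_length(pts)
    boundary_s <- c(boundary_s, s_tot)
  }
  total <- boundary_s[length(boundary_s)]
  # fractions at piece boundaries (excluding the final endpoint)
  list(pts = pts, fractions = boundary_s[-length(boundary_s)] / total)
}

# ---- subject generation ------------------------------------------------------

#' Generate one synthetic subject
#'
#' Builds the seven border curves, the anatomical landmarks and the axial head
#' contour of one synthetic subject, together with its ground truth: exact
#' junction arc-length fractions (and ordinals at the configured semilandmark
#' counts), per-suture length/width/SI by dense quadrature, cranial L/W/C, and
#' the 2D footprint polygons. Noise and the rigid displacement are applied
#' after ground truth is recorded.
#'
#' @param cfg A [synthetic_config()].
#' @param subject_seed Seed for this subject's random draws.
#' @param latents Optional named list (`size`, `area`, `si`) overriding the
#'   random latent factors.
#' @param subject_id Subject identifier.
#' @return List with `curves` (border-curve tibble), `landmarks`, `truth`
#'   and `latents`.
#' @export
generate_subject <- function(cfg, subject_seed = cfg$seed,
                             latents = NULL, subject_id = "synthetic") {
  set.seed(subject_seed)
  if (is.null(latents)) {
    latents <- list(size = max(0.5, 1 + stats::rnorm(1, 0, cfg$size_sd)),
                    area = max(0.3, 1 + stats::rnorm(1, 0, cfg$area_sd)),
                    si = max(0.05, 1 + stats::rnorm(1, 0, cfg$si_sd)))
  }
  s <- latents$size
  tmpl <- build_template(cfg, a = latents$area, q = latents$si)
  assembled <- lapply(tmpl$borders, assemble_border_3d, cfg = cfg, scale = s)

  counts <- cfg$counts
  junction_fracs <- tibble::tibble(
    border = c(rep(1L, 3), rep(3L, 7), rep(5L, 2), rep(7L, 4)),
    boundary = c(seq_len(3), seq_len(7), seq_len(2), seq_len(4)),
    fraction = c(assembled[["1"]]$fractions,
                 assembled[["3"]]$fractions,
                 assembled[["5"]]$fractions,
                 # border 7: the boundary between its two posterior-fontanelle
                 # edge pieces (the rhombus back corner) is not a junction
                 assembled[["7"]]$fractions[c(1, 2, 4, 5)])
  )
  frac_to_ordinal <- function(frac, n) 1L + as.integer(round(frac * (n - 1L)))
  truth_junctions <- dplyr::mutate(
    junction_fracs,
    ordinal = frac_to_ordinal(.data$fraction,
                              counts[as.character(.data$border)]))

  # dense per-suture measures
  pick <- function(b, i) lift_to_vault(tmpl$borders[[b]][[i]]$pts, cfg) * s
  edge_len <- function(segs) sum(vapply(segs, polyline_length, numeric(1)))
  si_of <- function(seg) {
    polyline_length(seg) / sqrt(sum((seg[1, ] - seg[nrow(seg), ])^2))
  }
  paired_width <- function(A, B, n = 400L) {
    Ar <- resample_polyline(A, n); Br <- resample_polyline(B, n)
    mean(sqrt(rowSums((Ar - Br)^2)))
  }
  nearest_width <- function(As, Bs) {
    A <- do.call(rbind, As); B <- do.call(rbind, Bs)
    mean(nearest_distances(A, B))
  }
  sut <- list(
    metopic = list(e1 = list(pick("1", 1)), e2 = list(pick("2", 1)),
                   paired = TRUE),
    sagittal = list(e1 = list(pick("3", 1)), e2 = list(pick("4", 1)),
                    paired = TRUE),
    coronal = list(e1 = list(pick("1", 3), pick("2", 3)),
                   e2 = list(pick("3", 7), pick("4", 7)), paired = FALSE),
    squamosal = list(e1 = list(pick("3", 5), pick("4", 5)),
                     e2 = list(pick("5", 2), pick("6", 2)), paired = FALSE),
    lambdoid = list(e1 = list(pick("3", 3), pick("4", 3)),
                    e2 = list(pick("7", 2), pick("7", 5)), paired = FALSE)
  )
  measures <- purrr::map_dfr(names(sut), function(nm) {
    sx <- sut[[nm]]
    tibble::tibble(
      suture = nm,
      length = mean(c(edge_len(sx$e1), edge_len(sx$e2))),
      width = if (sx$paired) paired_width(sx$e1[[1]], sx$e2[[1]])
              else nearest_width(sx$e1, sx$e2),
      si = mean(vapply(c(sx$e1, sx$e2), si_of, numeric(1)))
    )
  })

  # landmarks and axial contour (rim ellipse at z = 0)
  th <- seq(0, 2 * pi, length.out = 721)
  contour <- cbind(cfg$ax * cos(th), cfg$ay * sin(th), 0) * s
  lm_pts <- tibble::tibble(
    landmark = c("rhinion", "fmoR", "fmoL", "glabella", "opisthocranion",
                 "eurionL", "eurionR"),
    x = c(0, 0.42 * cfg$ax, -0.42 * cfg$ax, 0, 0, -cfg$ax, cfg$ax) * s,
    y = c(0.99 * cfg$ay, 0.88 * cfg$ay, 0.88 * cfg$ay, cfg$ay, -cfg$ay,
          0, 0) * s,
    z = c(-3, -2, -2, 0, 0, 0, 0) * s
  )
  truth <- list(
    junctions = truth_junctions,
    measures = measures,
    cranial = tibble::tibble(
      cranial_length = 2 * cfg$ay * s,
      cranial_width = 2 * cfg$ax * s,
      cranial_circumference = contour_length(contour, closed = TRUE)),
    footprints = lapply(
      tmpl$footprints[names(tmpl$footprints) != "strips"],
      function(p) p * s),
    strips = lapply(tmpl$footprints$strips, function(st) {
      list(a = st$a * s, b = st$b * s)
    }),
    anchors = lapply(tmpl$anchors, function(p) p * s),
    latents = latents
  )

  curves <- purrr::map_dfr(1:7, function(b) {
    m <- assembled[[as.character(b)]]$pts
    if (cfg$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m), 3)
    }
    tibble::tibble(subject_id = subject_id, border = b,
                   ordinal = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
                   z = m[, 3])
  })
  landmarks <- list(points = dplyr::mutate(lm_pts, subject_id = subject_id,
                                           .before = 1),
                    axial_contour = tibble::as_tibble(as.data.frame(
                      stats::setNames(as.data.frame(contour),
                                      c("x", "y", "z")))))
  if (cfg$displace) {
    ang_ <- stats::rnorm(3, 0, cfg$angle_sd * pi / 180)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang_[1]), sin(ang_[1]),
                   0, -sin(ang_[1]), cos(ang_[1])), 3, 3)
    Ry <- matrix(c(cos(ang_[2]), 0, -sin(ang_[2]), 0, 1, 0,
                   sin(ang_[2]), 0, cos(ang_[2])), 3, 3)
    Rz <- matrix(c(cos(ang_[3]), sin(ang_[3]), 0,
                   -sin(ang_[3]), cos(ang_[3]), 0, 0, 0, 1), 3, 3)
    tf <- list(rotation = Rz %*% Ry %*% Rx,
               translation = stats::rnorm(3, 0, cfg$translation_sd))
    curves <- transform_points(curves, tf)
    landmarks$points <- transform_points(landmarks$points, tf)
    landmarks$axial_contour <- transform_points(landmarks$axial_contour, tf)
  }
  validate_border_curves(curves)
  list(curves = curves, landmarks = landmarks, truth = truth,
       latents = latents)
}

#' Generate a synthetic population
#'
#' `representation = "curves"` runs the full nonlinear generator per subject
#' and returns raw border-curve subjects for the end-to-end pipeline.
#' `representation = "semilandmarks"` returns semilandmark-level geometry that
#' is an exact linear (affine) function of the three latent factors
#' (size scales the template; area and sinuosity act through fixed
#' displacement fields obtained by finite differences of the generator), which
#' gives the reduction and regression modules an exactly recoverable low-rank
#' ground truth.
#'
#' @param cfg A [synthetic_config()].
#' @param representation `"curves"` or `"semilandmarks"`.
#' @return For `"curves"`: list of class `synthetic_population` with
#'   `subjects` (list from [generate_subject()]) and `latents`. For
#'   `"semilandmarks"`: list of class `synthetic_population_sl` with `sl`
#'   (multi-subject semilandmark tibble), `latents` (tibble usable as
#'   covariates: columns `size`, `area`, `si`), `template` and `partition`
#'   inputs.
#' @export
generate_population <- function(cfg,
                                representation = c("curves",
                                                   "semilandmarks")) {
  representation <- match.arg(representation)
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  seeds <- sample.int(2^30, n)
  latents <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    size = pmax(0.5, 1 + stats::rnorm(n, 0, cfg$size_sd)),
    area = pmax(0.3, 1 + stats::rnorm(n, 0, cfg$area_sd)),
    si = pmax(0.05, 1 + stats::rnorm(n, 0, cfg$si_sd))
  )
  if (representation == "curves") {
    subjects <- lapply(seq_len(n), function(i) {
      generate_subject(cfg, subject_seed = seeds[i],
                       latents = list(size = latents$size[i],
                                      area = latents$area[i],
                                      si = latents$si[i]),
                       subject_id = latents$subject_id[i])
    })
    return(structure(list(subjects = subjects, latents = latents,
                          config = cfg),
                     class = "synthetic_population"))
  }
  # semilandmark representation: exact affine function of the latents
  base_cfg <- cfg
  base_cfg$noise_sd <- 0
  base_cfg$displace <- FALSE
  row_of <- function(a, q) {
    subj <- generate_subject(base_cfg, subject_seed = 1L,
                             latents = list(size = 1, area = a, si = q),
                             subject_id = "template")
    sl <- assemble_semilandmarks(subj$curves, cfg$counts)
    list(row = as.numeric(t(as.matrix(sl[, c("x", "y", "z")]))),
         topo = sl[, c("border", "ordinal")], subj = subj)
  }
  delta <- 1e-3
  t0 <- row_of(1, 1)
  field_area <- (row_of(1 + delta, 1)$row - t0$row) / delta
  field_si <- (row_of(1, 1 + delta)$row - t0$row) / delta
  set.seed(cfg$seed + 1L)
  noise <- if (cfg$noise_sd > 0) {
    matrix(stats::rnorm(n * length(t0$row), 0, cfg$noise_sd), n)
  } else {
    matrix(0, n, length(t0$row))
  }
  G0 <- latents$size %o% t0$row +
    (latents$area - 1) %o% field_area +
    (latents$si - 1) %o% field_si + noise
  topo <- t0$topo
  sl <- purrr::map_dfr(seq_len(n), function(i) {
    pts <- rows_to_points(G0[i, ])
    tibble::tibble(subject_id = latents$subject_id[i], border = topo$border,
                   ordinal = topo$ordinal, x = pts[, 1], y = pts[, 2],
                   z = pts[, 3])
  })
  structure(list(sl = sl, latents = latents, template = t0$subj,
                 config = cfg),
            class = "synthetic_population_sl")
}
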