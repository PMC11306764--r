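# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# one default-configuration synthetic subject with semilandmarks + partition
default_subject <- function(seed = 5) {
  cached(paste0("subject", seed), {
    cfg <- synthetic_config(seed = 7)
    subj <- generate_subject(cfg, subject_seed = seed, subject_id = "S1")
    subj$sl <- assemble_semilandmarks(subj$curves)
    subj$partition <- suppressWarnings(partition_sutures(subj$sl))
    subj
  })
}

# exact-linear (semilandmark representation) population with latent covariates
linear_population <- function(n = 30, seed = 11, noise_sd = 0) {
  cached(sprintf("linpop_%d_%d_%g", n, seed, noise_sd), {
    cfg <- synthetic_config(seed = seed, n_subjects = n, noise_sd = noise_sd)
    pop <- generate_population(cfg, representation = "semilandmarks")
    pop$records <- dplyr::bind_cols(
      tibble::tibble(subject_id = pop$latents$subject_id),
      pop$latents[, c("size", "area", "si")])
    pop
  })
}

# seven straight parallel borders with constant inter-border widths (no
# fontanelle widening anywhere); counts follow the default schema
flat_parallel_curves <- function() {
  line <- function(b, x, y0, y1, n) {
    tibble::tibble(subject_id = "flat", border = b, ordinal = seq_len(n),
                   x = x, y = seq(y0, y1, length.out = n), z = 0)
  }
  dplyr::bind_rows(
    line(1, -1, 0, 99, 120), line(2, 1, 0, 99, 120),
    line(3, -1, 110, 309, 240), line(4, 1, 110, 309, 240),
    line(5, -30, 0, 49, 60), line(6, 30, 0, 49, 60),
    line(7, -15, 320, 419, 120)
  )
}

# tiny rank-2 geometry matrix fixture
rank2_matrix <- function(n = 20, p = 30, seed = 9) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * 2), n, 2)
  B <- matrix(stats::rnorm(2 * p), 2, p)
  G0 <- Z %*% B
  rownames(G0) <- sprintf("s%02d", seq_len(n))
  G0
}

expect_lmd_lt <- function(A, B, tol) {
  expect_lt(lmd(A, B), tol)
}
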