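# Variational autoencoder dimension reduction, implemented directly in R
# (full-batch Adam, analytic gradients; gradient correctness is pinned by a
# finite-difference test). Two architectures: dense layers, and a 1D
# convolutional encoder/decoder over the semilandmark sequence (3 channels:
# x, y, z per point). CPU-only by design and sized for small shape samples.

vae_init <- function(shapes, seed) {
  set.seed(seed)
  lapply(shapes, function(s) {
    if (length(s) == 1) {
      numeric(s)
    } else {
      matrix(stats::rnorm(prod(s), sd = sqrt(2 / sum(s))), s[1], s[2])
    }
  })
}

adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- dense architecture ------------------------------------------------------

vae_dense_forward <- function(p_, X, eps_z, beta, encode_only = FALSE) {
  N <- nrow(X)
  H1 <- tanh(sweep(X %*% p_$W1, 2, p_$b1, "+"))
  mu <- sweep(H1 %*% p_$W2, 2, p_$b2, "+")
  if (encode_only) return(list(mu = mu))
  lv <- sweep(H1 %*% p_$W3, 2, p_$b3, "+")
  sd_ <- exp(0.5 * lv)
  z <- mu + sd_ * eps_z
  H2 <- tanh(sweep(z %*% p_$W4, 2, p_$b4, "+"))
  xhat <- sweep(H2 %*% p_$W5, 2, p_$b5, "+")
  recon <- 0.5 * sum((xhat - X)^2) / N
  kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / N
  list(loss = recon + beta * kl, recon = recon, kl = kl, H1 = H1, mu = mu,
       lv = lv, sd_ = sd_, z = z, H2 = H2, xhat = xhat)
}

vae_dense_backward <- function(p_, X, eps_z, beta, fw) {
  N <- nrow(X)
  dxhat <- (fw$xhat - X) / N
  g <- list()
  g$W5 <- crossprod(fw$H2, dxhat); g$b5 <- colSums(dxhat)
  dH2 <- (dxhat %*% t(p_$W5)) * (1 - fw$H2^2)
  g$W4 <- crossprod(fw$z, dH2); g$b4 <- colSums(dH2)
  dz <- dH2 %*% t(p_$W4)
  dmu <- dz + beta * fw$mu / N
  dlv <- dz * eps_z * 0.5 * fw$sd_ + beta * 0.5 * (exp(fw$lv) - 1) / N
  g$W2 <- crossprod(fw$H1, dmu); g$b2 <- colSums(dmu)
  g$W3 <- crossprod(fw$H1, dlv); g$b3 <- colSums(dlv)
  dH1 <- (dmu %*% t(p_$W2) + dlv %*% t(p_$W3)) * (1 - fw$H1^2)
  g$W1 <- crossprod(X, dH1); g$b1 <- colSums(dH1)
  g
}

# ---- 1D convolutional architecture ------------------------------------------

conv_geom <- function(L, kern, stride) {
  kern <- min(kern, L)
  stride <- max(1L, min(stride, L))
  L1 <- as.integer(ceiling((L - kern) / stride)) + 1L
  Ld <- (L1 - 1L) * stride + kern
  list(kern = kern, stride = stride, L1 = L1, Ld = Ld)
}

# gather patches: X_arr (N, Lpad, C) -> (N*L1, kern*C)
conv_gather <- function(X_arr, geom) {
  N <- dim(X_arr)[1]; C <- dim(X_arr)[3]
  out <- matrix(0, N * geom$L1, geom$kern * C)
  pos0 <- (seq_len(geom$L1) - 1L) * geom$stride
  for (c_ in seq_len(C)) {
    for (kp in seq_len(geom$kern)) {
      out[, (c_ - 1L) * geom$kern + kp] <- as.vector(X_arr[, pos0 + kp, c_])
    }
  }
  out
}

# scatter-add: (N*L1, kern*C) -> (N, Ld, C)
conv_scatter <- function(M, geom, N, C) {
  out <- array(0, c(N, geom$Ld, C))
  pos0 <- (seq_len(geom$L1) - 1L) * geom$stride
  for (c_ in seq_len(C)) {
    for (kp in seq_len(geom$kern)) {
      out[, pos0 + kp, c_] <- out[, pos0 + kp, c_] +
        matrix(M[, (c_ - 1L) * geom$kern + kp], N, geom$L1)
    }
  }
  out
}

rows_to_seq <- function(X) {
  # (N, 3L) interleaved rows -> (N, L, 3)
  N <- nrow(X); L <- ncol(X) / 3L
  arr <- array(0, c(N, L, 3))
  for (c_ in 1:3) arr[, , c_] <- X[, (seq_len(L) - 1L) * 3L + c_]
  arr
}

seq_to_rows <- function(arr) {
  N <- dim(arr)[1]; L <- dim(arr)[2]
  X <- matrix(0, N, 3L * L)
  for (c_ in 1:3) X[, (seq_len(L) - 1L) * 3L + c_] <- arr[, , c_]
  X
}

vae_conv_forward <- function(p_, X, eps_z, beta, geom, nfilt,
                             encode_only = FALSE) {
  N <- nrow(X); L <- ncol(X) / 3L
  Xarr <- rows_to_seq(X)
  if (geom$Ld > L) {
    pad <- array(0, c(N, geom$Ld, 3))
    pad[, seq_len(L), ] <- Xarr
    Xarr <- pad
  }
  Xp <- conv_gather(Xarr, geom)
  Hc <- tanh(sweep(Xp %*% p_$Wc, 2, p_$bc, "+"))          # (N*L1, F)
  Hflat <- matrix(array(Hc, c(N, geom$L1, nfilt)), N, geom$L1 * nfilt)
  mu <- sweep(Hflat %*% p_$W2, 2, p_$b2, "+")
  if (encode_only) return(list(mu = mu))
  lv <- sweep(Hflat %*% p_$W3, 2, p_$b3, "+")
  sd_ <- exp(0.5 * lv)
  z <- mu + sd_ * eps_z
  Dflat_pre <- sweep(z %*% p_$W4, 2, p_$b4, "+")
  Dflat <- tanh(Dflat_pre)
  Dr <- matrix(array(Dflat, c(N, geom$L1, nfilt)), N * geom$L1, nfilt)
  contrib <- Dr %*% t(p_$Wd)                               # (N*L1, kern*3)
  Xout <- conv_scatter(contrib, geom, N, 3L)
  for (c_ in 1:3) Xout[, , c_] <- Xout[, , c_] + p_$bd[c_]
  xhat <- seq_to_rows(Xout[, seq_len(L), , drop = FALSE])
  recon <- 0.5 * sum((xhat - X)^2) / N
  kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / N
  list(loss = recon + beta * kl, recon = recon, kl = kl, Xp = Xp, Hc = Hc,
       Hflat = Hflat, mu = mu, lv = lv, sd_ = sd_, z = z, Dflat = Dflat,
       Dr = Dr, xhat = xhat)
}

vae_conv_backward <- function(p_, X, eps_z, beta, geom, nfilt, fw) {
  N <- nrow(X); L <- ncol(X) / 3L
  g <- list()
  dxhat <- (fw$xhat - X) / N
  dXout <- array(0, c(N, geom$Ld, 3))
  dXout[, seq_len(L), ] <- rows_to_seq(dxhat)
  g$bd <- vapply(1:3, function(c_) sum(dXout[, , c_]), numeric(1))
  dcontrib <- conv_gather(dXout, geom)
  g$Wd <- crossprod(dcontrib, fw$Dr)
  dDr <- dcontrib %*% p_$Wd
  dDflat <- matrix(array(dDr, c(N, geom$L1, nfilt)), N, geom$L1 * nfilt)
  dDflat_pre <- dDflat * (1 - fw$Dflat^2)
  g$W4 <- crossprod(fw$z, dDflat_pre); g$b4 <- colSums(dDflat_pre)
  dz <- dDflat_pre %*% t(p_$W4)
  dmu <- dz + beta * fw$mu / N
  dlv <- dz * eps_z * 0.5 * fw$sd_ + beta * 0.5 * (exp(fw$lv) - 1) / N
  g$W2 <- crossprod(fw$Hflat, dmu); g$b2 <- colSums(dmu)
  g$W3 <- crossprod(fw$Hflat, dlv); g$b3 <- colSums(dlv)
  dHflat <- dmu %*% t(p_$W2) + dlv %*% t(p_$W3)
  dHc <- matrix(array(dHflat, c(N, geom$L1, nfilt)), N * geom$L1, nfilt) *
    (1 - fw$Hc^2)
  g$Wc <- crossprod(fw$Xp, dHc); g$bc <- colSums(dHc)
  g
}

#' Variational autoencoder reduction of the standardized geometry
#'
#' Trains a VAE (reparameterization trick, Gaussian decoder, full-batch Adam)
#' on the standardized geometry matrix. `arch = "dense"` uses a single hidden
#' layer on each side; `arch = "conv"` uses a strided 1D convolution over the
#' semilandmark sequence (x, y, z as channels) and a transposed convolution
#' decoder. Reconstruction is the deterministic decode of the encoder mean, so
#' LMD errors are comparable with the PCA variants. A fixed seed gives a
#' bitwise-reproducible loss trajectory on one platform; a divergent loss
#' stops training early with a warning.
#'
#' @param sm A `shape_matrix` from [standardize_shapes()].
#' @param latent_dim Latent dimension.
#' @param arch `"dense"` or `"conv"`.
#' @param hidden Hidden width (dense arch); default 64.
#' @param nfilt,kern,stride Convolution filters / kernel length / stride
#'   (conv arch); defaults 8, 9, 4 (clamped to the sequence length).
#' @param epochs Training epochs; default 300.
#' @param lr Adam learning rate; default 1e-3.
#' @param beta KL weight; default 1.
#' @param seed RNG seed (initialization and reparameterization draws).
#' @return Object of class `shape_vae` (a `shape_reduction`) with the training
#'   `history` (per-epoch loss, reconstruction and KL terms).
#' @export
fit_shape_vae <- function(sm, latent_dim, arch = c("dense", "conv"),
                          hidden = 64L, nfilt = 8L, kern = 9L, stride = 4L,
                          epochs = 300L, lr = 1e-3, beta = 1, seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(inherits(sm, "shape_matrix"), latent_dim >= 1)
  X <- sm$G
  N <- nrow(X); p <- ncol(X)
  d <- as.integer(latent_dim)
  if (arch == "dense") {
    shapes <- list(W1 = c(p, hidden), b1 = hidden, W2 = c(hidden, d),
                   b2 = d, W3 = c(hidden, d), b3 = d, W4 = c(d, hidden),
                   b4 = hidden, W5 = c(hidden, p), b5 = p)
    geom <- NULL
  } else {
    L <- p / 3L
    if (L != floor(L)) stop("conv arch needs 3-channel rows", call. = FALSE)
    geom <- conv_geom(L, kern, stride)
    hflat <- geom$L1 * nfilt
    shapes <- list(Wc = c(geom$kern * 3L, nfilt), bc = nfilt,
                   W2 = c(hflat, d), b2 = d, W3 = c(hflat, d), b3 = d,
                   W4 = c(d, hflat), b4 = hflat,
                   Wd = c(geom$kern * 3L, nfilt), bd = 3L)
  }
  params <- vae_init(shapes, seed)
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  history <- matrix(NA_real_, epochs, 3,
                    dimnames = list(NULL, c("loss", "recon", "kl")))
  diverged <- FALSE
  for (ep in seq_len(epochs)) {
    eps_z <- matrix(stats::rnorm(N * d), N, d)
    fw <- if (arch == "dense") {
      vae_dense_forward(params, X, eps_z, beta)
    } else {
      vae_conv_forward(params, X, eps_z, beta, geom, nfilt)
    }
    if (!is.finite(fw$loss)) {
      warning("VAE training diverged at epoch ", ep, "; stopping early",
              call. = FALSE)
      diverged <- TRUE
      break
    }
    history[ep, ] <- c(fw$loss, fw$recon, fw$kl)
    g <- if (arch == "dense") {
      vae_dense_backward(params, X, eps_z, beta, fw)
    } else {
      vae_conv_backward(params, X, eps_z, beta, geom, nfilt, fw)
    }
    upd <- adam_step(params, g, state, lr, ep)
    params <- upd$params
    state <- upd$state
  }
  model <- structure(
    list(method = paste0("vae_", arch), arch = arch, k = d, params = params,
         geom = geom, nfilt = nfilt, sm = sm, diverged = diverged,
         history = tibble::as_tibble(cbind(epoch = seq_len(epochs),
                                           as.data.frame(history))),
         evr = rep(NA_real_, d)),
    class = c("shape_vae", "shape_reduction")
  )
  model$scores <- project_scores(model, X)
  model
}

#' @export
project_scores.shape_vae <- function(model, G_std) {
  if (model$arch == "dense") {
    vae_dense_forward(model$params, G_std, NULL, 1, encode_only = TRUE)$mu
  } else {
    vae_conv_forward(model$params, G_std, NULL, 1, model$geom, model$nfilt,
                     encode_only = TRUE)$mu
  }
}

#' @export
reconstruct_rows.shape_vae <- function(model, scores) {
  p_ <- model$params
  if (model$arch == "dense") {
    H2 <- tanh(sweep(scores %*% p_$W4, 2, p_$b4, "+"))
    sweep(H2 %*% p_$W5, 2, p_$b5, "+")
  } else {
    geom <- model$geom; nfilt <- model$nfilt
    N <- nrow(scores); L <- ncol(model$sm$G) / 3L
    Dflat <- tanh(sweep(scores %*% p_$W4, 2, p_$b4, "+"))
    Dr <- matrix(array(Dflat, c(N, geom$L1, nfilt)), N * geom$L1, nfilt)
    Xout <- conv_scatter(Dr %*% t(p_$Wd), geom, N, 3L)
    for (c_ in 1:3) Xout[, , c_] <- Xout[, , c_] + p_$bd[c_]
    seq_to_rows(Xout[, seq_len(L), , drop = FALSE])
  }
}
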