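# Low-level array operations for the convolutional engine.
#
# Activations are 4-d arrays (height, width, channels, batch). Convolutions
# are stride-1 with zero "same" padding and are evaluated by im2col + BLAS
# matrix multiply; the im2col gather/scatter indices are precomputed once
# per (H, W, C, K) geometry and reused across time steps and batches.

conv_geom <- function(h, w, c_in, k) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  iv <- rep(seq_len(h), times = w)
  jv <- rep(seq_len(w), each = h)
  base <- iv + (jv - 1L) * hp
  # column q of the patch matrix is (ki, kj, c) with ki fastest, matching a
  # (k, k, c_in, c_out) weight array flattened to (k*k*c_in, c_out)
  off <- as.vector(outer(seq_len(k) - 1L,
                         (seq_len(k) - 1L) * hp, "+"))
  off <- as.vector(outer(off, (seq_len(c_in) - 1L) * hp * wp, "+"))
  idx <- as.integer(outer(base, off, "+"))
  list(h = h, w = w, c_in = c_in, k = k, p = p, hp = hp, wp = wp,
       idx = idx, uidx = sort(unique(idx)))
}

pad_input <- function(x, g) {
  if (g$p == 0L) return(x)
  n <- dim(x)[4]
  xp <- array(0, c(g$hp, g$wp, g$c_in, n))
  xp[g$p + seq_len(g$h), g$p + seq_len(g$w), , ] <- x
  xp
}

# x: (h, w, c_in, n) -> im2col matrix (h*w*n, k*k*c_in)
im2col <- function(x, g) {
  n <- dim(x)[4]
  xp <- pad_input(x, g)
  dim(xp) <- c(g$hp * g$wp * g$c_in, n)
  a <- xp[g$idx, , drop = FALSE]          # (hw * k2c, n)
  dim(a) <- c(g$h * g$w, length(g$idx) %/% (g$h * g$w), n)
  a <- aperm(a, c(1, 3, 2))
  dim(a) <- c(g$h * g$w * n, g$k * g$k * g$c_in)
  a
}

conv_forward <- function(x, w_arr, g) {
  n <- dim(x)[4]
  f_out <- dim(w_arr)[4]
  a <- im2col(x, g)
  wm <- w_arr; dim(wm) <- c(g$k * g$k * g$c_in, f_out)
  y <- a %*% wm
  dim(y) <- c(g$h * g$w, n, f_out)
  y <- aperm(y, c(1, 3, 2))
  dim(y) <- c(g$h, g$w, f_out, n)
  list(y = y, a = a)
}

# dy: (h, w, f_out, n); a: cached im2col matrix
conv_backward <- function(dy, a, w_arr, g, need_dx = TRUE) {
  n <- dim(dy)[4]
  f_out <- dim(w_arr)[4]
  dym <- dy
  dim(dym) <- c(g$h * g$w, f_out, n)
  dym <- aperm(dym, c(1, 3, 2))
  dim(dym) <- c(g$h * g$w * n, f_out)
  dw <- crossprod(a, dym)
  dim(dw) <- dim(w_arr)
  dx <- NULL
  if (need_dx) {
    wm <- w_arr; dim(wm) <- c(g$k * g$k * g$c_in, f_out)
    da <- tcrossprod(dym, wm)             # (hw*n, k2c)
    dim(da) <- c(g$h * g$w, n, g$k * g$k * g$c_in)
    da <- aperm(da, c(1, 3, 2))
    dim(da) <- c(g$h * g$w * g$k * g$k * g$c_in, n)
    acc <- rowsum(da, group = g$idx, reorder = TRUE)
    dxp <- matrix(0, g$hp * g$wp * g$c_in, n)
    dxp[g$uidx, ] <- acc
    dim(dxp) <- c(g$hp, g$wp, g$c_in, n)
    dx <- dxp[g$p + seq_len(g$h), g$p + seq_len(g$w), , , drop = FALSE]
  }
  list(dw = dw, dx = dx)
}

# 2x2 max pooling, stride 2; odd inputs padded with -Inf (ceiling semantics)
maxpool_forward <- function(x) {
  d <- dim(x)
  ho <- ceiling(d[1] / 2); wo <- ceiling(d[2] / 2)
  if (d[1] %% 2L || d[2] %% 2L) {
    xp <- array(-Inf, c(2 * ho, 2 * wo, d[3], d[4]))
    xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
    x <- xp
  }
  dim(x) <- c(2, ho, 2, wo, d[3], d[4])
  s1 <- x[1, , 1, , , , drop = FALSE]; dim(s1) <- c(ho, wo, d[3], d[4])
  s2 <- x[2, , 1, , , , drop = FALSE]; dim(s2) <- c(ho, wo, d[3], d[4])
  s3 <- x[1, , 2, , , , drop = FALSE]; dim(s3) <- c(ho, wo, d[3], d[4])
  s4 <- x[2, , 2, , , , drop = FALSE]; dim(s4) <- c(ho, wo, d[3], d[4])
  y <- pmax(s1, s2, s3, s4)
  m1 <- s1 == y
  m2 <- (s2 == y) & !m1
  m3 <- (s3 == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(y = y, masks = list(m1, m2, m3, m4), in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  ho <- ceiling(d[1] / 2); wo <- ceiling(d[2] / 2)
  dxp <- array(0, c(2, ho, 2, wo, d[3], d[4]))
  dxp[1, , 1, , , ] <- dy * cache$masks[[1]]
  dxp[2, , 1, , , ] <- dy * cache$masks[[2]]
  dxp[1, , 2, , , ] <- dy * cache$masks[[3]]
  dxp[2, , 2, , , ] <- dy * cache$masks[[4]]
  dim(dxp) <- c(2 * ho, 2 * wo, d[3], d[4])
  dxp[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
}

BN_EPS <- 1e-5

# channel-wise batch normalisation over (h, w, batch)
# mode "batch": normalise by minibatch statistics (training)
# mode "running": normalise by stored running statistics (evaluation)
bn_forward <- function(x, gamma, beta, mode = "batch",
                       rmean = NULL, rvar = NULL) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (mode == "batch") {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va[va < 0] <- 0
  } else {
    mu <- rmean; va <- rvar
  }
  istd <- 1 / sqrt(va + BN_EPS)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(istd, each = nrow(xm))
  y <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  dim(y) <- c(d[1], d[2], d[4], d[3])
  y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, xhat = xhat, mu = mu, va = va, istd = istd, d = d)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$d
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], d[3])
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = m)
  # standard reduced form of the batch-statistics backward pass
  s1 <- colSums(dxhat) / m
  s2 <- colSums(dxhat * cache$xhat) / m
  dxm <- rep(cache$istd, each = m) *
    (dxhat - rep(s1, each = m) - cache$xhat * rep(s2, each = m))
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(dxm, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

global_avg_pool <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  g <- colMeans(xm)
  dim(g) <- c(d[3], d[4])
  g                                        # (channels, batch)
}

gap_backward <- function(dg, d) {
  dx <- array(rep(as.vector(dg), each = d[1] * d[2]) / (d[1] * d[2]), d)
  dx
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}
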