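# Literal loop-based transcriptions of the attention equations, used as
# oracles for the vectorized implementations.

oracle_conv <- function(x, wmat, k, pad) {
  # x: H x W x C; wmat: Cout x (k*k*C), column index (c-1)*k*k + (kx-1)*k + ky
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  cout <- nrow(wmat)
  y <- array(0, c(H + 2 * pad - k + 1, W + 2 * pad - k + 1, cout))
  for (co in seq_len(cout)) {
    for (ox in seq_len(dim(y)[2])) for (oy in seq_len(dim(y)[1])) {
      acc <- 0
      for (c in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
        ix <- ox - pad + kx - 1L; iy <- oy - pad + ky - 1L
        if (ix >= 1 && ix <= W && iy >= 1 && iy <= H) {
          acc <- acc + x[iy, ix, c] * wmat[co, (c - 1) * k * k + (kx - 1) * k + ky]
        }
      }
      y[oy, ox, co] <- acc
    }
  }
  y
}

oracle_channel_attention <- function(f, w0, w1) {
  d <- dim(f); C <- d[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(f[, , c])
    mx[c] <- max(f[, , c])
  }
  mlp <- function(v) {
    h <- pmax(as.vector(w0 %*% v), 0)
    as.vector(w1 %*% h)
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

oracle_spatial_attention <- function(f, kernel) {
  d <- dim(f)
  am <- apply(f, c(1, 2), mean)
  mm <- apply(f, c(1, 2), max)
  k <- dim(kernel)[1]; pad <- k %/% 2
  z <- matrix(0, d[1], d[2])
  for (ox in seq_len(d[2])) for (oy in seq_len(d[1])) {
    acc <- 0
    for (kx in seq_len(k)) for (ky in seq_len(k)) {
      ix <- ox - pad + kx - 1L; iy <- oy - pad + ky - 1L
      if (ix >= 1 && ix <= d[2] && iy >= 1 && iy <= d[1]) {
        acc <- acc + am[iy, ix] * kernel[ky, kx, 1] + mm[iy, ix] * kernel[ky, kx, 2]
      }
    }
    z[oy, ox] <- acc
  }
  1 / (1 + exp(-z))
}

oracle_res2net_cbam <- function(x, params) {
  d <- dim(x)
  s <- length(params$group_kernels) + 1L
  cg <- d[3] %/% s
  x0 <- oracle_conv(x, params$w_in, 1L, 0L)
  gs <- lapply(seq_len(s), function(i) x0[, , (i - 1) * cg + seq_len(cg), drop = FALSE])
  ys <- vector("list", s)
  ys[[1]] <- gs[[1]]
  if (s >= 2) ys[[2]] <- oracle_conv(gs[[2]], params$group_kernels[[1]], 3L, 1L)
  if (s >= 3) for (i in 3:s) {
    ys[[i]] <- oracle_conv(gs[[i]] + ys[[i - 1]], params$group_kernels[[i - 1]], 3L, 1L)
  }
  ycat <- array(0, d)
  for (i in seq_len(s)) ycat[, , (i - 1) * cg + seq_len(cg)] <- ys[[i]]
  y <- oracle_conv(ycat, params$w_out, 1L, 0L)
  mc <- oracle_channel_attention(y, params$w0, params$w1)
  f1 <- y
  for (c in seq_len(d[3])) f1[, , c] <- y[, , c] * mc[c]
  ms <- oracle_spatial_attention(f1, params$kernel)
  f2 <- f1
  for (c in seq_len(d[3])) f2[, , c] <- f1[, , c] * ms
  f2 + x
}

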