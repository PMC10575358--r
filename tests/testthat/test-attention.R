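rand_ca_params <- function(C, r = 2L) {
  hidden <- max(1L, C %/% r)
  list(w0 = matrix(rnorm(hidden * C), hidden, C),
       w1 = matrix(rnorm(C * hidden), C, hidden))
}

test_that("channel attention matches its loop oracle and stays in (0,1)", {
  set.seed(21)
  for (i in 1:25) {
    C <- sample(c(2L, 4L, 6L, 8L), 1)
    f <- array(rnorm(4 * 5 * C), c(4, 5, C))
    p <- rand_ca_params(C)
    got <- channel_attention(f, p$w0, p$w1)
    expect_equal(got, oracle_channel_attention(f, p$w0, p$w1), tolerance = 1e-5)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("channel attention degenerate cases follow the sigmoid identities", {
  f <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  z0 <- matrix(0, 2, 4); z1 <- matrix(0, 4, 2)
  expect_equal(channel_attention(f, z0, z1), rep(0.5, 4))
  # spatially constant map: avg pool equals max pool, so Mc = sigmoid(2 MLP(c))
  p <- rand_ca_params(4L)
  fc <- array(rep(c(1, -2, 0.5, 3), each = 9), c(3, 3, 4))
  v <- c(1, -2, 0.5, 3)
  mlp <- function(x) as.vector(p$w1 %*% pmax(p$w0 %*% x, 0))
  expect_equal(channel_attention(fc, p$w0, p$w1),
               1 / (1 + exp(-2 * mlp(v))), tolerance = 1e-12)
  expect_error(channel_attention(f, matrix(0, 2, 3), z1), "shapes")
})

test_that("spatial attention matches a sliding-window oracle", {
  set.seed(22)
  for (i in 1:25) {
    C <- sample(2:5, 1)
    H <- sample(6:9, 1); W <- sample(6:9, 1)
    f <- array(rnorm(H * W * C), c(H, W, C))
    kernel <- array(rnorm(7 * 7 * 2, sd = 0.3), c(7, 7, 2))
    got <- spatial_attention(f, kernel)
    expect_equal(got, oracle_spatial_attention(f, kernel), tolerance = 1e-5)
    expect_true(all(got > 0 & got < 1))
  }
  # zero kernel -> sigmoid(0) everywhere; constant input -> constant interior
  f <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(spatial_attention(f, array(0, c(7, 7, 2))),
               matrix(0.5, 8, 8))
})

test_that("the full CBAM block composes the two attentions", {
  set.seed(23)
  for (i in 1:25) {
    C <- sample(c(2L, 4L, 8L), 1)
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    f <- array(rnorm(H * W * C), c(H, W, C))
    p <- rand_ca_params(C)
    kernel <- array(rnorm(7 * 7 * 2, sd = 0.3), c(7, 7, 2))
    got <- cbam(f, p$w0, p$w1, kernel)
    mc <- oracle_channel_attention(f, p$w0, p$w1)
    f1 <- f
    for (c in seq_len(C)) f1[, , c] <- f[, , c] * mc[c]
    ms <- oracle_spatial_attention(f1, kernel)
    ref <- f1
    for (c in seq_len(C)) ref[, , c] <- f1[, , c] * ms
    expect_equal(got, ref, tolerance = 1e-5)
    expect_identical(dim(got), dim(f))
  }
  # zero input stays zero; all-zero parameters give both attentions = 0.5
  C <- 4L
  p0 <- list(w0 = matrix(0, 2, C), w1 = matrix(0, C, 2))
  z <- array(0, c(5, 5, C))
  expect_equal(cbam(z, p0$w0, p0$w1, array(0, c(7, 7, 2))), z)
  f <- array(rnorm(5 * 5 * C), c(5, 5, C))
  expect_equal(cbam(f, p0$w0, p0$w1, array(0, c(7, 7, 2))), 0.25 * f,
               tolerance = 1e-12)
})

test_that("the Res2Net-CBAM unit matches the literal equation oracle", {
  set.seed(24)
  for (i in 1:25) {
    C <- 8L; s <- sample(c(2L, 4L), 1)
    cg <- C %/% s
    x <- array(rnorm(4 * 4 * C), c(4, 4, C))
    params <- list(
      w_in = matrix(rnorm(C * C, sd = 0.4), C, C),
      group_kernels = lapply(seq_len(s - 1), function(j) {
        matrix(rnorm(cg * 9 * cg, sd = 0.3), cg, 9 * cg)
      }),
      w_out = matrix(rnorm(C * C, sd = 0.4), C, C),
      w0 = matrix(rnorm(4 * C, sd = 0.4), 4, C),
      w1 = matrix(rnorm(C * 4, sd = 0.4), C, 4),
      kernel = array(rnorm(7 * 7 * 2, sd = 0.2), c(7, 7, 2))
    )
    got <- res2net_cbam(x, params)
    expect_equal(got, oracle_res2net_cbam(x, params), tolerance = 1e-5)
    expect_identical(dim(got), dim(x))
  }
})

test_that("Res2Net-CBAM degenerate configurations behave per the equations", {
  C <- 6L
  x <- array(rnorm(5 * 5 * C), c(5, 5, C))
  # s = 1: no group convolutions, Y = w_out w_in X
  p1 <- list(w_in = diag(C), group_kernels = list(), w_out = diag(C),
             w0 = matrix(0, 1, C), w1 = matrix(0, C, 1),
             kernel = array(0, c(7, 7, 2)))
  # both attentions are 0.5 with zero weights: F = 0.25 Y + X
  expect_equal(res2net_cbam(x, p1), 0.25 * x + x, tolerance = 1e-12)
  # zeroed convolution path: the residual input passes through untouched
  p0 <- list(w_in = matrix(0, C, C),
             group_kernels = list(matrix(0, 2, 18), matrix(0, 2, 18)),
             w_out = matrix(0, C, C),
             w0 = matrix(rnorm(3 * C), 3, C), w1 = matrix(rnorm(C * 3), C, 3),
             kernel = array(rnorm(98), c(7, 7, 2)))
  expect_equal(res2net_cbam(x, p0), x, tolerance = 1e-12)
  expect_error(res2net_cbam(x, list(w_in = diag(C),
                                    group_kernels = list(1, 2, 3),
                                    w_out = diag(C))),
               "divisible")
})
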