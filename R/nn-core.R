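# Minimal layer framework for the detector.
#
# Tensors are plain R arrays with dim (H, W, C, N). Every module is an
# environment with fwd(x, train) / bwd(dy) closures; bwd returns the gradient
# w.r.t. the module input and accumulates parameter gradients in place. The
# heavy per-pixel work (im2col convolution, pooling) lives in src/ops.cpp;
# everything here is whole-array vector arithmetic.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- value * 0
  e
}

# broadcast a per-channel vector (length C) over an (H,W,C,N) array
bc_chan <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

# broadcast a (C x N) matrix over an (H,W,C,N) array
bc_cn <- function(m, d) rep(as.vector(m), each = d[1] * d[2])

# per-(c,n) sums of an (H,W,C,N) array -> C x N matrix
sum_cn <- function(x, d) {
  matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# concatenate along the channel axis
cat_c <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    ci <- dim(x)[3]
    out[, , at + seq_len(ci), ] <- x
    at <- at + ci
  }
  out
}

split_c <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(ci) {
    sl <- x[, , at + seq_len(ci), , drop = FALSE]
    at <<- at + ci
    sl
  })
}

collect_params <- function(mod) {
  out <- list()
  if (!is.null(mod$params)) out <- c(out, mod$params)
  for (sm in mod$submodules) out <- c(out, collect_params(sm))
  out
}

zero_grads <- function(params) {
  for (p in params) p$g <- p$v * 0
  invisible(NULL)
}

# ---- Conv + BatchNorm + activation -----------------------------------------

mod_conv <- function(c_in, c_out, k = 1L, s = 1L, p = NULL, act = "silu",
                     bn = TRUE, bias = !bn) {
  if (is.null(p)) p <- k %/% 2L
  m <- new.env()
  m$kind <- "conv"
  m$k <- as.integer(k); m$s <- as.integer(s); m$p <- as.integer(p)
  m$act <- act; m$bn <- bn; m$c_out <- c_out
  m$params <- list(w = new_param(matrix(
    stats::rnorm(c_out * k * k * c_in, sd = sqrt(2 / (k * k * c_in))),
    c_out, k * k * c_in)))
  if (bias) m$params$b <- new_param(numeric(c_out))
  if (bn) {
    m$params$gamma <- new_param(rep(1, c_out))
    m$params$beta <- new_param(numeric(c_out))
    m$run_mean <- numeric(c_out)
    m$run_var <- rep(1, c_out)
    m$bn_momentum <- 0.03
    m$bn_eps <- 1e-5
  }
  m$submodules <- list()
  m$need_dx <- TRUE

  m$fwd <- function(x, train = FALSE) {
    b <- if (!is.null(m$params$b)) m$params$b$v else numeric(0)
    z <- .conv_fwd(x, m$params$w$v, b, m$k, m$s, m$p)
    d <- dim(z)
    if (m$bn) {
      if (train) {
        mu <- rowSums(sum_cn(z, d)) / (d[1] * d[2] * d[4])
        v2 <- rowSums(sum_cn(z * z, d)) / (d[1] * d[2] * d[4])
        va <- pmax(v2 - mu * mu, 0)
        inv_sd <- 1 / sqrt(va + m$bn_eps)
        xhat <- (z - bc_chan(mu, d)) * bc_chan(inv_sd, d)
        dim(xhat) <- d
        m$run_mean <- (1 - m$bn_momentum) * m$run_mean + m$bn_momentum * mu
        m$run_var <- (1 - m$bn_momentum) * m$run_var + m$bn_momentum * va
        m$cache_xhat <- xhat
        m$cache_inv_sd <- inv_sd
        z <- xhat * bc_chan(m$params$gamma$v, d) + bc_chan(m$params$beta$v, d)
        dim(z) <- d
      } else {
        inv_sd <- 1 / sqrt(m$run_var + m$bn_eps)
        a <- m$params$gamma$v * inv_sd
        bb <- m$params$beta$v - m$run_mean * a
        z <- z * bc_chan(a, d) + bc_chan(bb, d)
        dim(z) <- d
      }
    }
    if (train) { m$cache_x <- x; m$cache_z <- z }
    y <- if (m$act == "silu") silu(z) else z
    dim(y) <- d
    y
  }

  m$bwd <- function(dy) {
    d <- dim(dy)
    dz <- if (m$act == "silu") dy * silu_grad(m$cache_z) else dy
    if (m$bn) {
      M <- d[1] * d[2] * d[4]
      xhat <- m$cache_xhat
      m$params$gamma$g <- m$params$gamma$g + rowSums(sum_cn(dz * xhat, d))
      m$params$beta$g <- m$params$beta$g + rowSums(sum_cn(dz, d))
      dxhat <- dz * bc_chan(m$params$gamma$v, d)
      s1 <- rowSums(sum_cn(dxhat, d))
      s2 <- rowSums(sum_cn(dxhat * xhat, d))
      dz <- (dxhat - bc_chan(s1 / M, d) - xhat * bc_chan(s2 / M, d)) *
        bc_chan(m$cache_inv_sd, d)
      dim(dz) <- d
    }
    cb <- .conv_bwd(m$cache_x, m$params$w$v, dz, m$k, m$s, m$p, m$need_dx)
    m$params$w$g <- m$params$w$g + cb$dw
    if (!is.null(m$params$b)) m$params$b$g <- m$params$b$g + cb$db
    m$cache_x <- NULL; m$cache_z <- NULL; m$cache_xhat <- NULL
    cb$dx
  }
  m
}

# ---- Bottleneck and C3 -----------------------------------------------------

mod_bottleneck <- function(c1, c2, shortcut = TRUE, e = 1.0) {
  m <- new.env()
  m$kind <- "bottleneck"
  ch <- max(1L, as.integer(round(c2 * e)))
  m$submodules <- list(cv1 = mod_conv(c1, ch, 1L),
                       cv2 = mod_conv(ch, c2, 3L))
  m$params <- list()
  m$add <- shortcut && c1 == c2
  m$fwd <- function(x, train = FALSE) {
    y <- m$submodules$cv2$fwd(m$submodules$cv1$fwd(x, train), train)
    if (m$add) y <- y + x
    y
  }
  m$bwd <- function(dy) {
    dx <- m$submodules$cv1$bwd(m$submodules$cv2$bwd(dy))
    if (m$add) dx <- dx + dy
    dx
  }
  m
}

mod_c3 <- function(c1, c2, n = 1L, shortcut = TRUE) {
  m <- new.env()
  m$kind <- "c3"
  ch <- max(1L, c2 %/% 2L)
  m$ch <- ch
  bots <- lapply(seq_len(n), function(i) mod_bottleneck(ch, ch, shortcut))
  names(bots) <- paste0("b", seq_len(n))
  m$submodules <- c(list(cv1 = mod_conv(c1, ch, 1L),
                         cv2 = mod_conv(c1, ch, 1L),
                         cv3 = mod_conv(2L * ch, c2, 1L)), bots)
  m$params <- list()
  m$n <- n
  m$fwd <- function(x, train = FALSE) {
    a <- m$submodules$cv1$fwd(x, train)
    for (i in seq_len(m$n)) a <- m$submodules[[paste0("b", i)]]$fwd(a, train)
    b <- m$submodules$cv2$fwd(x, train)
    m$submodules$cv3$fwd(cat_c(list(a, b)), train)
  }
  m$bwd <- function(dy) {
    dcat <- m$submodules$cv3$bwd(dy)
    parts <- split_c(dcat, c(m$ch, m$ch))
    da <- parts[[1]]
    for (i in rev(seq_len(m$n))) da <- m$submodules[[paste0("b", i)]]$bwd(da)
    m$submodules$cv1$bwd(da) + m$submodules$cv2$bwd(parts[[2]])
  }
  m
}

# ---- SPPF ------------------------------------------------------------------

mod_sppf <- function(c1, c2, k = 5L) {
  m <- new.env()
  m$kind <- "sppf"
  ch <- c1 %/% 2L
  m$k <- as.integer(k)
  m$submodules <- list(cv1 = mod_conv(c1, ch, 1L),
                       cv2 = mod_conv(4L * ch, c2, 1L))
  m$params <- list()
  m$fwd <- function(x, train = FALSE) {
    a <- m$submodules$cv1$fwd(x, train)
    p1 <- .maxpool_fwd(a, m$k, 1L, m$k %/% 2L)
    p2 <- .maxpool_fwd(p1$y, m$k, 1L, m$k %/% 2L)
    p3 <- .maxpool_fwd(p2$y, m$k, 1L, m$k %/% 2L)
    if (train) {
      m$cache <- list(da = dim(a), i1 = p1$idx, i2 = p2$idx, i3 = p3$idx)
    }
    m$submodules$cv2$fwd(cat_c(list(a, p1$y, p2$y, p3$y)), train)
  }
  m$bwd <- function(dy) {
    ca <- m$cache
    dcat <- m$submodules$cv2$bwd(dy)
    ch4 <- dim(dcat)[3] %/% 4L
    parts <- split_c(dcat, rep(ch4, 4L))
    n_el <- prod(ca$da)
    dp2 <- .scatter_add(parts[[4]], ca$i3, n_el, ca$da) + parts[[3]]
    dp1 <- .scatter_add(dp2, ca$i2, n_el, ca$da) + parts[[2]]
    da <- .scatter_add(dp1, ca$i1, n_el, ca$da) + parts[[1]]
    m$cache <- NULL
    m$submodules$cv1$bwd(da)
  }
  m
}

# ---- Upsample / Concat -----------------------------------------------------

mod_upsample <- function() {
  m <- new.env()
  m$kind <- "upsample"
  m$params <- list(); m$submodules <- list()
  m$fwd <- function(x, train = FALSE) .upsample2_fwd(x)
  m$bwd <- function(dy) .upsample2_bwd(dy)
  m
}

mod_concat <- function() {
  m <- new.env()
  m$kind <- "concat"
  m$params <- list(); m$submodules <- list()
  m$fwd <- function(xs, train = FALSE) {
    m$sizes <- vapply(xs, function(x) dim(x)[3], integer(1))
    cat_c(xs)
  }
  m$bwd <- function(dy) split_c(dy, m$sizes)
  m
}
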