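# Channel and spatial attention (CBAM) and the Res2Net-CBAM residual unit.
#
# Two surfaces live here. The exported functions (channel_attention,
# spatial_attention, cbam, res2net_cbam) are the plain mathematical maps on a
# single H x W x C feature array with explicit weights -- the form in which
# the attention equations are stated and unit-tested against loop-based
# transcriptions. The mod_* constructors are the trainable network blocks
# (convolutions carrying batch-norm + SiLU, matching the detector's Conv
# convention) with hand-derived backward passes.

with_batch <- function(f) {
  d <- dim(f)
  if (length(d) == 3L) dim(f) <- c(d, 1L)
  f
}

#' Channel attention weights of a feature map
#'
#' Global average pooling and global max pooling reduce the `H x W x C` map
#' to two C-vectors; both pass through the same two-layer perceptron
#' (`W1 relu(W0 .)`), are summed, and squashed with a sigmoid:
#' `Mc = sigmoid(W1 relu(W0 avg) + W1 relu(W0 max))`. Every output lies
#' strictly in (0, 1).
#'
#' @param f Numeric array `H x W x C`.
#' @param w0 Matrix `(C/r) x C` (the shared reduction layer).
#' @param w1 Matrix `C x (C/r)` (the shared expansion layer).
#' @return Numeric vector of length C with entries in (0, 1).
#' @export
channel_attention <- function(f, w0, w1) {
  d <- dim(f)
  if (ncol(w0) != d[3] || nrow(w1) != d[3] || nrow(w0) != ncol(w1)) {
    stop("channel attention weight shapes do not compose with C = ", d[3],
         call. = FALSE)
  }
  fm <- matrix(f, d[1] * d[2], d[3])
  avg <- colMeans(fm)
  mx <- apply(fm, 2L, max)
  mlp <- function(v) w1 %*% pmax(w0 %*% v, 0)
  as.vector(sigmoid(mlp(avg) + mlp(mx)))
}

#' Spatial attention map of a feature map
#'
#' The channel-wise mean map and channel-wise max map (each `H x W`) are
#' stacked into a 2-channel map, convolved with a single 7x7 kernel (padding
#' 3) down to one channel, and sigmoid-normalised.
#'
#' @param f Numeric array `H x W x C`.
#' @param kernel Numeric array `7 x 7 x 2` (or any odd `k x k x 2`); the
#'   first slice weights the mean map, the second the max map. Kernel element
#'   `[ky, kx, ]` multiplies the input pixel offset by `(ky, kx)` from the
#'   window's top-left corner.
#' @return Numeric matrix `H x W` with entries in (0, 1).
#' @export
spatial_attention <- function(f, kernel) {
  d <- dim(f)
  k <- dim(kernel)[1]
  stopifnot(dim(kernel)[2] == k, dim(kernel)[3] == 2L, k %% 2L == 1L)
  fm <- matrix(f, d[1] * d[2], d[3])
  am <- matrix(rowMeans(fm), d[1], d[2])
  mm <- matrix(apply(fm, 1L, max), d[1], d[2])
  catm <- array(c(am, mm), c(d[1], d[2], 2L, 1L))
  z <- .conv_fwd(catm, kernel_to_mat(kernel), numeric(0), k, 1L, k %/% 2L)
  matrix(sigmoid(z), d[1], d[2])
}

# (k,k,2) kernel array -> 1 x (k*k*2) conv weight matrix in the package's
# channel-major, x-then-y column order
kernel_to_mat <- function(kernel) {
  k <- dim(kernel)[1]
  matrix(as.numeric(kernel), 1L, k * k * 2L)
}

#' Apply a full CBAM block to a feature map
#'
#' Channel attention first: `F' = Mc(F) * F` (broadcast over space); then
#' spatial attention: `out = Ms(F') * F'` (broadcast over channels). The
#' output has the shape of the input.
#'
#' @param f Numeric array `H x W x C`.
#' @inheritParams channel_attention
#' @inheritParams spatial_attention
#' @return Numeric array `H x W x C`.
#' @export
cbam <- function(f, w0, w1, kernel) {
  d <- dim(f)
  mc <- channel_attention(f, w0, w1)
  f1 <- f * rep(mc, each = d[1] * d[2])
  dim(f1) <- d
  ms <- spatial_attention(f1, kernel)
  out <- f1 * as.vector(ms)
  dim(out) <- d
  out
}

#' Res2Net-CBAM residual unit (single feature map, explicit weights)
#'
#' The hierarchical residual unit: an entry 1x1 convolution, an even split
#' of the channels into `s` groups, chained 3x3 group convolutions
#' (`Y1 = X1`, `Y2 = K2(X2)`, `Yi = Ki(Xi + Y(i-1))` for `i >= 3`),
#' concatenation, an exit 1x1 convolution giving `Y`, then CBAM
#' (`F1 = Mc(Y)*Y`, `F2 = Ms(F1)*F1`) and the residual connection
#' `F = F2 + X` from the block input. Convolutions here are plain linear
#' maps, the form in which the unit's equations are stated; inside the
#' detector the block's convolutions additionally carry batch-norm + SiLU.
#'
#' @param x Numeric array `H x W x C` with `C` divisible by `s`.
#' @param params List with `w_in` (`C x C` matrix, entry 1x1 conv),
#'   `group_kernels` (list of `s - 1` matrices `(C/s) x (9 C/s)`, the 3x3
#'   convs for groups 2..s), `w_out` (`C x C`, exit 1x1 conv), and the CBAM
#'   weights `w0`, `w1`, `kernel`.
#' @return Numeric array `H x W x C`.
#' @export
res2net_cbam <- function(x, params) {
  d <- dim(x)
  s <- length(params$group_kernels) + 1L
  if (d[3] %% s != 0L) {
    stop("channel count ", d[3], " not divisible by scale s = ", s, call. = FALSE)
  }
  cg <- d[3] %/% s
  x4 <- with_batch(x)
  x0 <- .conv_fwd(x4, params$w_in, numeric(0), 1L, 1L, 0L)
  groups <- split_c(x0, rep(cg, s))
  ys <- vector("list", s)
  ys[[1]] <- groups[[1]]
  for (i in seq_len(s)[-1]) {
    inp <- if (i == 2L) groups[[i]] else groups[[i]] + ys[[i - 1L]]
    ys[[i]] <- .conv_fwd(inp, params$group_kernels[[i - 1L]], numeric(0),
                         3L, 1L, 1L)
  }
  y <- .conv_fwd(cat_c(ys), params$w_out, numeric(0), 1L, 1L, 0L)
  dim(y) <- d
  out <- cbam(y, params$w0, params$w1, params$kernel) + x
  dim(out) <- d
  out
}

# ---- trainable network blocks ----------------------------------------------

mod_channel_attention <- function(C, r = 16L) {
  m <- new.env()
  m$kind <- "channel_attention"
  hidden <- max(1L, C %/% r)
  m$params <- list(
    w0 = new_param(matrix(stats::rnorm(hidden * C, sd = sqrt(2 / C)), hidden, C)),
    w1 = new_param(matrix(stats::rnorm(C * hidden, sd = sqrt(2 / hidden)), C, hidden))
  )
  m$submodules <- list()
  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    HW <- d[1] * d[2]
    avg <- matrix(colSums(matrix(x, HW, d[3] * d[4])) / HW, d[3], d[4])
    sm <- .spat_max(x)
    w0 <- m$params$w0$v; w1 <- m$params$w1$v
    pre_a <- w0 %*% avg; pre_m <- w0 %*% sm$y
    h_a <- pmax(pre_a, 0); h_m <- pmax(pre_m, 0)
    mc <- sigmoid(w1 %*% h_a + w1 %*% h_m)
    y <- x * bc_cn(mc, d)
    dim(y) <- d
    if (train) {
      m$cache <- list(x = x, d = d, avg = avg, mx = sm$y, midx = sm$idx,
                      pre_a = pre_a, pre_m = pre_m, h_a = h_a, h_m = h_m,
                      mc = mc)
    }
    y
  }
  m$bwd <- function(dy) {
    ca <- m$cache
    d <- ca$d; HW <- d[1] * d[2]
    dx <- dy * bc_cn(ca$mc, d)
    dmc <- sum_cn(dy * ca$x, d)
    dz <- dmc * ca$mc * (1 - ca$mc)
    w0 <- m$params$w0$v; w1 <- m$params$w1$v
    dh_a <- crossprod(w1, dz); dh_m <- dh_a
    dpre_a <- dh_a * (ca$pre_a > 0); dpre_m <- dh_m * (ca$pre_m > 0)
    m$params$w1$g <- m$params$w1$g + dz %*% t(ca$h_a) + dz %*% t(ca$h_m)
    m$params$w0$g <- m$params$w0$g + dpre_a %*% t(ca$avg) + dpre_m %*% t(ca$mx)
    davg <- crossprod(w0, dpre_a)
    dmax <- crossprod(w0, dpre_m)
    dx <- dx + bc_cn(davg / HW, d)
    # scatter max-branch gradient to the argmax pixels
    cn <- seq_len(d[3] * d[4]) - 1L
    pos <- cn * HW + as.vector(ca$midx)
    dmx_flat <- numeric(length(dx))
    dmx_flat[pos] <- as.vector(dmax)
    dx <- dx + dmx_flat
    dim(dx) <- d
    m$cache <- NULL
    dx
  }
  m
}

mod_spatial_attention <- function(k = 7L) {
  m <- new.env()
  m$kind <- "spatial_attention"
  m$k <- as.integer(k)
  m$params <- list(w = new_param(matrix(
    stats::rnorm(k * k * 2L, sd = sqrt(2 / (k * k * 2L))), 1L, k * k * 2L)))
  m$submodules <- list()
  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    HW <- d[1] * d[2]
    xr <- x; dim(xr) <- c(HW, d[3], d[4])
    am <- matrix(0, HW, d[4])
    for (n in seq_len(d[4])) am[, n] <- rowMeans(xr[, , n, drop = FALSE])
    cm <- .chan_max(x)
    catm <- array(0, c(d[1], d[2], 2L, d[4]))
    catm[, , 1L, ] <- am
    catm[, , 2L, ] <- cm$y
    z <- .conv_fwd(catm, m$params$w$v, numeric(0), m$k, 1L, m$k %/% 2L)
    ms <- sigmoid(z)                       # (H,W,1,N)
    msm <- matrix(ms, HW, d[4])
    full <- msm[, rep(seq_len(d[4]), each = d[3]), drop = FALSE]
    y <- x * as.vector(full)
    dim(y) <- d
    if (train) {
      m$cache <- list(x = x, d = d, catm = catm, ms = ms, full = full,
                      cidx = cm$idx)
    }
    y
  }
  m$bwd <- function(dy) {
    ca <- m$cache
    d <- ca$d; HW <- d[1] * d[2]
    dx <- dy * as.vector(ca$full)
    prod_ <- dy * ca$x
    dim(prod_) <- c(HW, d[3], d[4])
    dms <- matrix(0, HW, d[4])
    for (n in seq_len(d[4])) dms[, n] <- rowSums(prod_[, , n, drop = FALSE])
    msv <- matrix(ca$ms, HW, d[4])
    dz <- dms * msv * (1 - msv)
    dim(dz) <- c(d[1], d[2], 1L, d[4])
    cb <- .conv_bwd(ca$catm, m$params$w$v, dz, m$k, 1L, m$k %/% 2L, TRUE)
    m$params$w$g <- m$params$w$g + cb$dw
    dcat <- cb$dx
    dam <- dcat[, , 1L, , drop = FALSE]   # (H,W,1,N)
    dmm <- dcat[, , 2L, , drop = FALSE]
    # mean branch: spread over channels
    damm <- matrix(dam, HW, d[4])
    dx <- dx + as.vector(damm[, rep(seq_len(d[4]), each = d[3]), drop = FALSE]) / d[3]
    # max branch: scatter to argmax channel
    n_idx <- rep(seq_len(d[4]) - 1L, each = HW)
    hw_idx <- rep(seq_len(HW), times = d[4])
    pos <- n_idx * (HW * d[3]) + (as.vector(ca$cidx) - 1L) * HW + hw_idx
    dmx_flat <- numeric(length(dx))
    dmx_flat[pos] <- dmx_flat[pos] + as.vector(dmm)
    dx <- dx + dmx_flat
    dim(dx) <- d
    m$cache <- NULL
    dx
  }
  m
}

mod_cbam <- function(C, r = 16L, k = 7L) {
  m <- new.env()
  m$kind <- "cbam"
  m$params <- list()
  m$submodules <- list(ca = mod_channel_attention(C, r),
                       sa = mod_spatial_attention(k))
  m$fwd <- function(x, train = FALSE) {
    m$submodules$sa$fwd(m$submodules$ca$fwd(x, train), train)
  }
  m$bwd <- function(dy) {
    m$submodules$ca$bwd(m$submodules$sa$bwd(dy))
  }
  m
}

mod_res2net_cbam <- function(C, s = 4L, r = 16L) {
  if (C %% s != 0L) {
    stop("Res2Net-CBAM: channel count ", C, " not divisible by scale s = ", s,
         call. = FALSE)
  }
  m <- new.env()
  m$kind <- "res2net_cbam"
  m$s <- as.integer(s)
  m$cg <- C %/% s
  ks <- if (s > 1L) {
    lapply(seq_len(s - 1L), function(i) mod_conv(m$cg, m$cg, 3L))
  } else {
    list()
  }
  if (length(ks)) names(ks) <- paste0("k", seq_len(s - 1L) + 1L)
  m$submodules <- c(
    list(cv1 = mod_conv(C, C, 1L), cv2 = mod_conv(C, C, 1L),
         ca = mod_channel_attention(C, r), sa = mod_spatial_attention(7L)),
    ks
  )
  m$params <- list()
  m$fwd <- function(x, train = FALSE) {
    x0 <- m$submodules$cv1$fwd(x, train)
    groups <- split_c(x0, rep(m$cg, m$s))
    ys <- vector("list", m$s)
    ys[[1]] <- groups[[1]]
    for (i in seq_len(m$s)[-1]) {
      inp <- if (i == 2L) groups[[i]] else groups[[i]] + ys[[i - 1L]]
      ys[[i]] <- m$submodules[[paste0("k", i)]]$fwd(inp, train)
    }
    y <- m$submodules$cv2$fwd(cat_c(ys), train)
    f1 <- m$submodules$ca$fwd(y, train)
    f2 <- m$submodules$sa$fwd(f1, train)
    f2 + x
  }
  m$bwd <- function(dy) {
    df1 <- m$submodules$sa$bwd(dy)
    dyy <- m$submodules$ca$bwd(df1)
    dy0_parts <- split_c(m$submodules$cv2$bwd(dyy), rep(m$cg, m$s))
    dgroups <- vector("list", m$s)
    carry <- NULL
    for (i in rev(seq_len(m$s))) {
      if (i == 1L) {
        dgroups[[1]] <- dy0_parts[[1]]
        if (!is.null(carry)) dgroups[[1]] <- dgroups[[1]] + carry
        break
      }
      dyi <- dy0_parts[[i]]
      if (!is.null(carry)) dyi <- dyi + carry
      dinp <- m$submodules[[paste0("k", i)]]$bwd(dyi)
      dgroups[[i]] <- dinp
      carry <- if (i > 2L) dinp else NULL
    }
    dx0 <- cat_c(dgroups)
    m$submodules$cv1$bwd(dx0) + dy
  }
  m
}
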