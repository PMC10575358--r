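# Training: anchor-matched target assignment, composite detection loss
# (CIoU box term + binary cross-entropy objectness and classification) with
# analytic gradients, Adam/SGD updates, and the epoch loop.

# stable log(1 + exp(-|z|)) + max(z, 0) - z * t  (BCE with logits)
bce_logits <- function(z, t) {
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

# CIoU between center-format boxes, with analytic gradients w.r.t. the
# predicted (px, py, pw, ph). The aspect coefficient alpha is treated as a
# constant (detached), as is conventional for this loss.
ciou_grad <- function(px, py, pw, ph, gx, gy, gw, gh) {
  eps <- 1e-9
  p1x <- px - pw / 2; p2x <- px + pw / 2
  p1y <- py - ph / 2; p2y <- py + ph / 2
  g1x <- gx - gw / 2; g2x <- gx + gw / 2
  g1y <- gy - gh / 2; g2y <- gy + gh / 2
  ix1 <- pmax(p1x, g1x); ix2 <- pmin(p2x, g2x)
  iy1 <- pmax(p1y, g1y); iy2 <- pmin(p2y, g2y)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  ap <- pw * ph; ag <- gw * gh
  un <- ap + ag - inter + eps
  iou <- inter / un
  pos <- inter > 0
  ax <- pos & (p1x > g1x); bx <- pos & (p2x < g2x)
  ay <- pos & (p1y > g1y); by_ <- pos & (p2y < g2y)
  dI_dpx <- ih * (bx - ax)
  dI_dpy <- iw * (by_ - ay)
  dI_dpw <- 0.5 * ih * (ax + bx)
  dI_dph <- 0.5 * iw * (ay + by_)
  diou_d <- function(dI, dAp) (dI * un - inter * (dAp - dI)) / un^2
  dIoU_dpx <- diou_d(dI_dpx, 0)
  dIoU_dpy <- diou_d(dI_dpy, 0)
  dIoU_dpw <- diou_d(dI_dpw, ph)
  dIoU_dph <- diou_d(dI_dph, pw)
  # center-distance penalty rho^2 / c^2 over the enclosing box diagonal
  cw <- pmax(p2x, g2x) - pmin(p1x, g1x)
  chh <- pmax(p2y, g2y) - pmin(p1y, g1y)
  c2 <- cw^2 + chh^2 + eps
  rho2 <- (px - gx)^2 + (py - gy)^2
  mx <- p1x < g1x; nx <- p2x > g2x
  my <- p1y < g1y; ny <- p2y > g2y
  dcw_dpx <- nx - mx; dcw_dpw <- 0.5 * (nx + mx)
  dch_dpy <- ny - my; dch_dph <- 0.5 * (ny + my)
  dpen <- function(drho2, dc2) (drho2 * c2 - rho2 * dc2) / c2^2
  dpen_dpx <- dpen(2 * (px - gx), 2 * cw * dcw_dpx)
  dpen_dpy <- dpen(2 * (py - gy), 2 * chh * dch_dpy)
  dpen_dpw <- dpen(0, 2 * cw * dcw_dpw)
  dpen_dph <- dpen(0, 2 * chh * dch_dph)
  # aspect-consistency term
  delta <- atan(gw / (gh + eps)) - atan(pw / (ph + eps))
  v <- 4 / pi^2 * delta^2
  alpha <- v / (1 - iou + v + eps)   # detached
  datan_den <- 1 + (pw / (ph + eps))^2
  datan_dpw <- (1 / (ph + eps)) / datan_den
  datan_dph <- (-pw / (ph + eps)^2) / datan_den
  dv_dpw <- -8 / pi^2 * delta * datan_dpw
  dv_dph <- -8 / pi^2 * delta * datan_dph
  ciou <- iou - rho2 / c2 - alpha * v
  list(
    ciou = ciou,
    dpx = dIoU_dpx - dpen_dpx,
    dpy = dIoU_dpy - dpen_dpy,
    dpw = dIoU_dpw - dpen_dpw - alpha * dv_dpw,
    dph = dIoU_dph - dpen_dph - alpha * dv_dph,
    iou = iou
  )
}

# indexed += that accumulates over duplicated indices
add_at <- function(arr, idx, val) {
  if (anyDuplicated(idx)) {
    s <- rowsum(val, idx)
    at <- as.numeric(rownames(s))
    arr[at] <- arr[at] + s[, 1L]
  } else {
    arr[idx] <- arr[idx] + val
  }
  arr
}

# Anchor-matched targets per scale. annotations: tibble with columns
# n (1-based batch slot), class_id, xmin..ymax in input pixels.
build_targets <- function(annotations, config, input_hw) {
  anchor_t <- 4
  lapply(seq_along(config$strides), function(si) {
    st <- config$strides[si]
    gH <- input_hw[1] %/% st; gW <- input_hw[2] %/% st
    a_g <- config$anchors[[si]] / st
    ann <- annotations
    if (nrow(ann) == 0L) {
      return(list(n = integer(0), gH = gH, gW = gW))
    }
    gx <- (ann$xmin + ann$xmax) / 2 / st
    gy <- (ann$ymin + ann$ymax) / 2 / st
    gw <- (ann$xmax - ann$xmin) / st
    gh <- (ann$ymax - ann$ymin) / st
    rows <- list(); k <- 0L
    for (a in 1:3) {
      r <- pmax(pmax(gw / a_g[a, 1], a_g[a, 1] / gw),
                pmax(gh / a_g[a, 2], a_g[a, 2] / gh))
      sel <- which(r < anchor_t)
      if (length(sel) == 0L) next
      fx <- gx[sel] %% 1; fy <- gy[sel] %% 1
      offs <- list(c(0, 0))
      for (j in seq_along(sel)) {
        i <- sel[j]
        cands <- list(c(0, 0))
        if (fx[j] < 0.5 && gx[i] > 1) cands <- c(cands, list(c(-1, 0)))
        if (fx[j] >= 0.5 && gx[i] < gW - 1) cands <- c(cands, list(c(1, 0)))
        if (fy[j] < 0.5 && gy[i] > 1) cands <- c(cands, list(c(0, -1)))
        if (fy[j] >= 0.5 && gy[i] < gH - 1) cands <- c(cands, list(c(0, 1)))
        for (off in cands) {
          ci <- floor(gx[i]) + off[1]; cj <- floor(gy[i]) + off[2]
          if (ci < 0 || ci >= gW || cj < 0 || cj >= gH) next
          k <- k + 1L
          rows[[k]] <- c(ann$n[i], a, ci, cj, gx[i], gy[i], gw[i], gh[i],
                         ann$class_id[i])
        }
      }
    }
    if (k == 0L) return(list(n = integer(0), gH = gH, gW = gW))
    tm <- do.call(rbind, rows)
    list(n = as.integer(tm[, 1]), a = as.integer(tm[, 2]),
         ci = as.integer(tm[, 3]), cj = as.integer(tm[, 4]),
         gx = tm[, 5], gy = tm[, 6], gw = tm[, 7], gh = tm[, 8],
         class_id = as.integer(tm[, 9]), gH = gH, gW = gW)
  })
}

# Composite detection loss with gradient w.r.t. each raw head output.
detection_loss <- function(raw, targets, config,
                           w_box = 0.05, w_obj = 1.0, w_cls = 0.5,
                           balance = c(4.0, 1.0, 0.4)) {
  nc <- config$num_classes
  no <- nc + 5L
  lbox <- 0; lobj <- 0; lcls <- 0
  draws <- vector("list", length(raw))
  for (si in seq_along(raw)) {
    arr <- raw[[si]]
    d <- dim(arr)   # (gH, gW, 3*no, N)
    gH <- d[1]; gW <- d[2]; N <- d[4]
    tg <- targets[[si]]
    draw <- array(0, d)
    tobj <- array(0, c(gH, gW, 3L, N))
    lin <- function(cj, ci, ch, n) {
      # 0-based cj (y), ci (x), ch; 1-based n
      cj + gH * ci + gH * gW * ch + gH * gW * (3L * no) * (n - 1L) + 1
    }
    n_pos <- length(tg$n)
    if (n_pos > 0L) {
      base_ch <- (tg$a - 1L) * no
      i_tx <- lin(tg$cj, tg$ci, base_ch + 0L, tg$n)
      i_ty <- lin(tg$cj, tg$ci, base_ch + 1L, tg$n)
      i_tw <- lin(tg$cj, tg$ci, base_ch + 2L, tg$n)
      i_th <- lin(tg$cj, tg$ci, base_ch + 3L, tg$n)
      sx <- sigmoid(arr[i_tx]); sy <- sigmoid(arr[i_ty])
      sw <- sigmoid(arr[i_tw]); sh <- sigmoid(arr[i_th])
      a_g <- config$anchors[[si]] / config$strides[si]
      aw <- a_g[tg$a, 1L]; ah <- a_g[tg$a, 2L]
      px <- 2 * sx - 0.5 + tg$ci; py <- 2 * sy - 0.5 + tg$cj
      pw <- (2 * sw)^2 * aw; ph <- (2 * sh)^2 * ah
      cg <- ciou_grad(px, py, pw, ph, tg$gx, tg$gy, tg$gw, tg$gh)
      lbox <- lbox + mean(1 - cg$ciou)
      scale <- w_box / n_pos
      draw <- add_at(draw, i_tx, -scale * cg$dpx * 2 * sx * (1 - sx))
      draw <- add_at(draw, i_ty, -scale * cg$dpy * 2 * sy * (1 - sy))
      draw <- add_at(draw, i_tw, -scale * cg$dpw * 2 * pw * (1 - sw))
      draw <- add_at(draw, i_th, -scale * cg$dph * 2 * ph * (1 - sh))
      tobj[cbind(tg$cj + 1L, tg$ci + 1L, tg$a, tg$n)] <-
        pmax(pmin(cg$ciou, 1), 0)
      # classification: one-hot BCE over the positives
      i_cls <- rep(i_tx, nc) +
        gH * gW * (5L + rep(seq_len(nc) - 1L, each = n_pos))
      zc <- arr[i_cls]
      tcls <- as.numeric(rep(tg$class_id, nc) == rep(seq_len(nc) - 1L, each = n_pos))
      lcls <- lcls + sum(bce_logits(zc, tcls)) / (n_pos * nc)
      draw <- add_at(draw, i_cls, w_cls * (sigmoid(zc) - tcls) / (n_pos * nc))
    }
    # objectness over every cell/anchor
    ch_obj <- (0:2) * no + 4L
    i_obj <- as.vector(vapply(ch_obj, function(ch) {
      as.vector(outer(seq_len(gH * gW) - 1L,
                      gH * gW * ch + gH * gW * (3L * no) * (seq_len(N) - 1L),
                      `+`)) + 1
    }, numeric(gH * gW * N)))
    dim(i_obj) <- c(gH * gW, N, 3L)
    i_obj <- as.vector(aperm(i_obj, c(1L, 3L, 2L)))  # order (hw, a, n) = tobj layout
    zo <- arr[i_obj]
    to <- as.vector(tobj)
    lobj_s <- mean(bce_logits(zo, to)) * balance[si]
    lobj <- lobj + lobj_s
    draw[i_obj] <- draw[i_obj] +
      w_obj * balance[si] * (sigmoid(zo) - to) / length(zo)
    draws[[si]] <- draw
  }
  list(loss = w_box * lbox + w_obj * lobj + w_cls * lcls,
       lbox = lbox, lobj = lobj, lcls = lcls, draws = draws)
}

# Backpropagate head gradients through the whole layer graph.
backward_network <- function(net, draws) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  grads[[n_layers]] <- draws
  for (i in rev(seq_len(n_layers))) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    dx <- ly$module$bwd(g)
    dxs <- if (ly$kind %in% c("concat", "detect")) dx else list(dx)
    for (j in seq_along(ly$from)) {
      f <- ly$from[j]
      if (f == 0L || is.null(dxs[[j]])) next
      grads[[f]] <- if (is.null(grads[[f]])) dxs[[j]] else grads[[f]] + dxs[[j]]
    }
    grads[[i]] <- NULL
  }
  invisible(NULL)
}

make_optimizer <- function(params, kind = "adam", lr = 0.002,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           momentum = 0.9) {
  st <- new.env()
  st$t <- 0L
  st$m <- lapply(params, function(p) p$v * 0)
  if (kind == "adam") st$v2 <- lapply(params, function(p) p$v * 0)
  function(step_lr = lr) {
    st$t <- st$t + 1L
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (kind == "adam") {
        st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * p$g
        st$v2[[i]] <- beta2 * st$v2[[i]] + (1 - beta2) * p$g^2
        mhat <- st$m[[i]] / (1 - beta1^st$t)
        vhat <- st$v2[[i]] / (1 - beta2^st$t)
        p$v <- p$v - step_lr * mhat / (sqrt(vhat) + eps)
      } else {
        st$m[[i]] <- momentum * st$m[[i]] + p$g
        p$v <- p$v - step_lr * st$m[[i]]
      }
    }
    invisible(NULL)
  }
}

#' Train the part detector
#'
#' Full-batch-shuffled mini-batch training with the composite detection
#' loss: CIoU box regression, binary cross-entropy objectness (targets set
#' to the detached box IoU at matched anchors, per-scale balance weights
#' 4/1/0.4), and binary cross-entropy classification, with loss weights
#' 0.05/1.0/0.5. Anchor matching uses the width/height-ratio criterion
#' (ratio < 4) with the two nearest neighbouring cells also assigned.
#' Deterministic given `seed`.
#'
#' @param scenes A scene set as produced by [generate_scenes()]: list with
#'   `images` (named list of `H x W x 3` arrays, 0-255) and `annotations`
#'   (tibble with `image_id`, `class_id`, `xmin`..`ymax`).
#' @param config A [detector_config()] matching the scene canvas size.
#' @param epochs Number of passes over the data (default 50).
#' @param batch_size Images per gradient step (default 8).
#' @param lr Peak learning rate (default 0.01, Adam); linear warm-up over
#'   the first 3 epochs, cosine decay to 10% afterwards.
#' @param loss_weights Named weights of the three loss terms
#'   (default `c(box = 0.05, obj = 1, cls = 1)`; the classification gain
#'   is raised from the detector family's 0.5 so the part-species label,
#'   the harder half of this task, gets equal footing).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed RNG seed covering initialisation, batch order and flips.
#' @param hflip_prob Probability of horizontally flipping each training image
#'   (with box mirroring and wing-label swap) per epoch, the in-loop form of
#'   the flip augmentation (default 0.5; 0 disables).
#' @param verbose Print a line per epoch.
#' @return An object of class `"detector_fit"`: list with `net`, `history`
#'   (tibble: epoch, loss, lbox, lobj, lcls), `config`.
#' @export
train_detector <- function(scenes, config, epochs = 50L, batch_size = 8L,
                           lr = 0.01, optimizer = "adam", seed = 1L,
                           hflip_prob = 0.5,
                           loss_weights = c(box = 0.05, obj = 1, cls = 1),
                           verbose = FALSE) {
  if (length(scenes$images) == 0L) stop("empty training set", call. = FALSE)
  set.seed(seed)
  net <- build_network(config)
  params <- unlist(lapply(net$layers, function(l) collect_params(l$module)),
                   use.names = FALSE)
  opt <- make_optimizer(params, kind = optimizer, lr = lr)
  ids <- names(scenes$images)
  imgs <- lapply(scenes$images, function(im) im / 255)
  ann_by_img <- split(scenes$annotations, scenes$annotations$image_id)
  input_hw <- dim(imgs[[1]])[1:2]
  n_img <- length(imgs)
  n_batches <- ceiling(n_img / batch_size)
  total_steps <- epochs * n_batches
  warmup <- 3L * n_batches
  history <- vector("list", epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    ep_loss <- c(loss = 0, lbox = 0, lobj = 0, lcls = 0)
    for (b in seq_len(n_batches)) {
      sel <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n_img)]
      N <- length(sel)
      x <- array(0, c(input_hw[1], input_hw[2], 3L, N))
      ann_list <- vector("list", N)
      n_species <- config$num_classes %/% 4L
      for (j in seq_len(N)) {
        im <- imgs[[sel[j]]]
        a <- ann_by_img[[ids[sel[j]]]]
        if (hflip_prob > 0 && stats::runif(1) < hflip_prob) {
          fl <- hflip(im, a, n_species = n_species)
          im <- fl$image
          a <- fl$annotations
        }
        x[, , , j] <- im
        if (!is.null(a) && nrow(a) > 0L) {
          a$n <- j
          ann_list[[j]] <- a
        }
      }
      ann <- dplyr::bind_rows(ann_list)
      if (!"n" %in% names(ann)) ann <- tibble::tibble(n = integer(0), class_id = integer(0),
                                                xmin = double(0), ymin = double(0),
                                                xmax = double(0), ymax = double(0))
      targets <- build_targets(ann, config, input_hw)
      res <- forward_network(net, x, train = TRUE)
      ls <- detection_loss(res$raw, targets, config,
                           w_box = loss_weights[["box"]],
                           w_obj = loss_weights[["obj"]],
                           w_cls = loss_weights[["cls"]])
      zero_grads(params)
      backward_network(net, ls$draws)
      step <- step + 1L
      fac <- if (step <= warmup) {
        step / warmup
      } else {
        0.1 + 0.9 * 0.5 * (1 + cos(pi * (step - warmup) / max(1, total_steps - warmup)))
      }
      opt(lr * fac)
      ep_loss <- ep_loss +
        c(ls$loss, ls$lbox, ls$lobj, ls$lcls) / n_batches
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss[1],
                                    lbox = ep_loss[2], lobj = ep_loss[3],
                                    lcls = ep_loss[4])
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f (box %.4f obj %.4f cls %.4f)\n",
                  ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
    }
  }
  structure(list(net = net, history = dplyr::bind_rows(history),
                 config = config),
            class = "detector_fit")
}

#' @export
print.detector_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("Trained part detector: %d epochs, final loss %.4f\n",
              nrow(x$history), last$loss))
  print(x$net)
  invisible(x)
}

#' Tidy a detector fit: the per-epoch loss history
#' @param x A `detector_fit`.
#' @param ... Unused.
#' @return Tibble `epoch`, `loss`, `lbox`, `lobj`, `lcls`.
#' @export
tidy.detector_fit <- function(x, ...) x$history

#' One-row summary of a detector fit
#' @param x A `detector_fit`.
#' @param ... Unused.
#' @return One-row tibble with final losses and epoch count.
#' @export
glance.detector_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), loss = last$loss,
                 lbox = last$lbox, lobj = last$lobj, lcls = last$lcls)
}

#' Plot the training-loss history
#' @param object A `detector_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.detector_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", title = "Training loss") +
    ggplot2::theme_minimal()
}
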