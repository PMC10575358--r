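# Detection head, anchor decode, and non-maximum suppression.

mod_detect <- function(nc, anchors, ch, strides, input_size) {
  m <- new.env()
  m$kind <- "detect"
  m$nc <- as.integer(nc)
  m$no <- as.integer(nc + 5L)
  m$anchors <- anchors
  m$strides <- strides
  convs <- lapply(seq_along(ch), function(i) {
    cv <- mod_conv(ch[i], 3L * m$no, k = 1L, act = "none", bn = FALSE, bias = TRUE)
    # prior-aware bias init: low objectness, near-uniform class scores
    g <- input_size / strides[i]
    b <- cv$params$b$v
    for (a in 0:2) {
      base <- a * m$no
      b[base + 5L] <- log(8 / g^2)
      b[base + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.99))
    }
    cv$params$b$v <- b
    cv
  })
  names(convs) <- paste0("cv", seq_along(ch))
  m$submodules <- convs
  m$params <- list()
  m$fwd <- function(xs, train = FALSE) {
    lapply(seq_along(xs), function(i) {
      m$submodules[[i]]$fwd(xs[[i]], train)
    })
  }
  m$bwd <- function(dys) {
    lapply(seq_along(dys), function(i) m$submodules[[i]]$bwd(dys[[i]]))
  }
  m
}

#' Decode raw detector output into detection records
#'
#' Applies the anchor-based decode at each scale: for cell `(cx, cy)` and
#' anchor `(aw, ah)`, the box center is `(2 s(tx) - 0.5 + cx) * stride`, the
#' size `(2 s(tw))^2 * aw` (`s` the sigmoid), confidence is
#' `s(objectness) * max_class s(class score)`, and the arg-max class gives
#' the part-species label. Records below `conf_threshold` are dropped;
#' boxes are clipped to the image.
#'
#' @param raw List of three arrays `g x g x 3*(nc+5)` (one image) or
#'   `g x g x 3*(nc+5) x 1`, strides 8/16/32 — the `raw` element of
#'   [forward_network()] for a single image.
#' @param config The [detector_config()] the network was built with.
#' @param conf_threshold Minimum confidence (default 0.25; use 0.001 when
#'   evaluating mAP).
#' @param image_id Identifier attached to the records.
#' @return A tibble of detections: `image_id`, `class_id`, `species_id`,
#'   `part`, `confidence`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
decode_predictions <- function(raw, config, conf_threshold = 0.25,
                               image_id = "img") {
  nc <- config$num_classes
  no <- nc + 5L
  sz <- config$input_size
  n_species <- nc %/% 4L
  out <- vector("list", length(raw) * 3L)
  k <- 0L
  for (si in seq_along(raw)) {
    arr <- raw[[si]]
    d <- dim(arr)
    if (length(d) == 4L) {
      stopifnot(d[4] == 1L)
      dim(arr) <- d[1:3]
      d <- dim(arr)
    }
    H <- d[1]; W <- d[2]
    stride <- config$strides[si]
    HW <- H * W
    dim(arr) <- c(HW, no, 3L)
    p <- seq_len(HW) - 1L
    cell_y <- p %% H
    cell_x <- p %/% H
    for (a in 1:3) {
      obj <- sigmoid(arr[, 5L, a])
      keep0 <- obj >= conf_threshold  # class factor can only lower confidence
      if (!any(keep0)) next
      cls <- sigmoid(arr[keep0, 5L + seq_len(nc), a, drop = FALSE])
      dim(cls) <- c(sum(keep0), nc)
      best <- max.col(cls, ties.method = "first")
      best_p <- cls[cbind(seq_len(nrow(cls)), best)]
      conf <- obj[keep0] * best_p
      keep <- conf >= conf_threshold
      if (!any(keep)) next
      sxy <- sigmoid(arr[keep0, 1:2, a, drop = FALSE])
      swh <- sigmoid(arr[keep0, 3:4, a, drop = FALSE])
      dim(sxy) <- c(sum(keep0), 2L); dim(swh) <- c(sum(keep0), 2L)
      bx <- (2 * sxy[, 1L] - 0.5 + cell_x[keep0]) * stride
      by <- (2 * sxy[, 2L] - 0.5 + cell_y[keep0]) * stride
      bw <- (2 * swh[, 1L])^2 * config$anchors[[si]][a, 1L]
      bh <- (2 * swh[, 2L])^2 * config$anchors[[si]][a, 2L]
      cid <- (best - 1L)[keep]
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        image_id = image_id,
        class_id = cid,
        confidence = conf[keep],
        xmin = pmax(0, bx[keep] - bw[keep] / 2),
        ymin = pmax(0, by[keep] - bh[keep] / 2),
        xmax = pmin(sz, bx[keep] + bw[keep] / 2),
        ymax = pmin(sz, by[keep] + bh[keep] / 2)
      )
    }
  }
  det <- if (k == 0L) {
    tibble::tibble(image_id = character(), class_id = integer(),
                   confidence = double(), xmin = double(), ymin = double(),
                   xmax = double(), ymax = double())
  } else {
    dplyr::bind_rows(out[seq_len(k)])
  }
  det <- det[det$xmax > det$xmin & det$ymax > det$ymin, ]
  dec <- decode_class(det$class_id, n_species = n_species)
  det$species_id <- dec$species_id
  det$part <- dec$part
  dplyr::select(det, "image_id", "class_id", "species_id", "part",
                "confidence", "xmin", "ymin", "xmax", "ymax")
}

#' Per-class greedy non-maximum suppression
#'
#' Within each class, detections are taken in order of descending confidence
#' and kept only if their IoU with every already-kept detection of that
#' class is below `iou_threshold`.
#'
#' @param detections Tibble of detections (see [decode_predictions()]).
#' @param iou_threshold Suppression threshold in (0, 1), default 0.45.
#' @return The kept subset, original columns preserved.
#' @export
nms <- function(detections, iou_threshold = 0.45) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  if (nrow(detections) <= 1L) return(detections)
  keep_rows <- integer(0)
  groups <- split(seq_len(nrow(detections)),
                  paste(detections$image_id, detections$class_id))
  for (rows in groups) {
    g <- detections[rows, ]
    ord <- order(-g$confidence, g$xmin, g$ymin)
    boxes <- as.matrix(g[, c("xmin", "ymin", "xmax", "ymax")])
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) == 0L ||
          all(box_iou(boxes[i, , drop = FALSE],
                      boxes[kept, , drop = FALSE]) < iou_threshold)) {
        kept <- c(kept, i)
      }
    }
    keep_rows <- c(keep_rows, rows[kept])
  }
  detections[sort(keep_rows), ]
}

#' Detect parts in a set of images
#'
#' Runs the detector in evaluation mode over a list of images, decodes and
#' suppresses, and returns one detection tibble.
#'
#' @param net A `"detector"` (or `"detector_fit"`, from which the network is
#'   taken).
#' @param images Named list of `H x W x 3` arrays on the 0-255 scale; names
#'   are the image ids.
#' @param conf_threshold Confidence floor (0.25 for inference, 0.001 for mAP
#'   evaluation).
#' @param iou_threshold NMS threshold (default 0.45).
#' @return A tibble of detections across all images.
#' @export
detect_images <- function(net, images, conf_threshold = 0.25,
                          iou_threshold = 0.45) {
  if (inherits(net, "detector_fit")) net <- net$net
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  dets <- purrr::map2(images, ids, function(img, id) {
    x <- img / 255
    res <- forward_network(net, x, train = FALSE)
    nms(decode_predictions(res$raw, net$config, conf_threshold, image_id = id),
        iou_threshold)
  })
  dplyr::bind_rows(dets)
}
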