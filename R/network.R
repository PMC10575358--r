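# The improved single-stage detector: backbone Conv/C3 with a Res2Net-CBAM
# unit after every backbone C3, SPPF, an FPN+PAN neck with a CBAM block at
# each of the three output scales, and a 3-scale anchor-based head.

#' Default anchor boxes (pixels at 640x640 input)
#'
#' Three scales (strides 8, 16, 32), three (w, h) pairs per scale.
#' @return A list of three 3x2 matrices.
#' @export
default_anchors <- function() {
  list(
    matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
    matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
    matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE)
  )
}

#' Detector configuration
#'
#' The layer graph is fixed (see [layer_plan()]); the configuration scales
#' its widths and depths and sets the label space.
#'
#' @param num_classes Number of detection classes (default 800 = 200 species
#'   x 4 parts).
#' @param width_multiple Channel-width multiplier in (0, 1]; channel counts
#'   are rounded to the nearest multiple of 8 (minimum 8).
#' @param depth_multiple Repeat-count multiplier in (0, 1] for the C3 blocks.
#' @param input_size Square input edge, divisible by 32 (default 640).
#' @param anchors List of three 3x2 anchor matrices, in pixels at 640 input.
#' @param res2net_scale Group count s of the Res2Net-CBAM units (default 4).
#' @param reduction_ratio Channel-attention bottleneck ratio r (default 16).
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(num_classes = 800L, width_multiple = 1,
                            depth_multiple = 1, input_size = 640L,
                            anchors = default_anchors(),
                            res2net_scale = 4L, reduction_ratio = 16L) {
  stopifnot(input_size %% 32L == 0L, width_multiple > 0, width_multiple <= 1,
            depth_multiple > 0, depth_multiple <= 1)
  structure(
    list(num_classes = as.integer(num_classes),
         width_multiple = width_multiple, depth_multiple = depth_multiple,
         input_size = as.integer(input_size), anchors = anchors,
         res2net_scale = as.integer(res2net_scale),
         reduction_ratio = as.integer(reduction_ratio),
         strides = c(8L, 16L, 32L)),
    class = "detector_config"
  )
}

round8 <- function(x) pmax(8L, as.integer(round(x / 8) * 8))

scale_depth <- function(n, depth_multiple) pmax(1L, as.integer(round(n * depth_multiple)))

#' The detector's layer plan
#'
#' One row per layer: module kind, input layer indices (`-1` = previous),
#' repeat count and base channel width at full multipliers. The backbone
#' carries a Res2Net-CBAM unit after each C3 block (layers 3, 6, 9, 12) and
#' ends in SPPF; the neck is FPN (top-down) + PAN (bottom-up) with a CBAM
#' block after each output-scale C3 (layers 22, 26, 30); the head consumes
#' layers 22, 26, 30.
#'
#' @return A tibble with columns `layer`, `module`, `from`, `number`,
#'   `c_out`, `extra`.
#' @export
layer_plan <- function() {
  tibble::tribble(
    ~layer, ~module,        ~from,          ~number, ~c_out, ~extra,
    0L,  "conv",          list(-1L),       1L,  80L,   list(k = 6L, s = 2L, p = 2L),
    1L,  "conv",          list(-1L),       1L,  160L,  list(k = 3L, s = 2L),
    2L,  "c3",            list(-1L),       4L,  160L,  list(shortcut = TRUE),
    3L,  "res2net_cbam",  list(-1L),       1L,  160L,  list(),
    4L,  "conv",          list(-1L),       1L,  320L,  list(k = 3L, s = 2L),
    5L,  "c3",            list(-1L),       8L,  320L,  list(shortcut = TRUE),
    6L,  "res2net_cbam",  list(-1L),       1L,  320L,  list(),
    7L,  "conv",          list(-1L),       1L,  640L,  list(k = 3L, s = 2L),
    8L,  "c3",            list(-1L),       12L, 640L,  list(shortcut = TRUE),
    9L,  "res2net_cbam",  list(-1L),       1L,  640L,  list(),
    10L, "conv",          list(-1L),       1L,  1280L, list(k = 3L, s = 2L),
    11L, "c3",            list(-1L),       4L,  1280L, list(shortcut = TRUE),
    12L, "res2net_cbam",  list(-1L),       1L,  1280L, list(),
    13L, "sppf",          list(-1L),       1L,  1280L, list(k = 5L),
    14L, "conv",          list(-1L),       1L,  640L,  list(k = 1L, s = 1L),
    15L, "upsample",      list(-1L),       1L,  640L,  list(),
    16L, "concat",        list(-1L, 9L),   1L,  1280L, list(),
    17L, "c3",            list(-1L),       4L,  640L,  list(shortcut = FALSE),
    18L, "conv",          list(-1L),       1L,  320L,  list(k = 1L, s = 1L),
    19L, "upsample",      list(-1L),       1L,  320L,  list(),
    20L, "concat",        list(-1L, 6L),   1L,  640L,  list(),
    21L, "c3",            list(-1L),       4L,  320L,  list(shortcut = FALSE),
    22L, "cbam",          list(-1L),       1L,  320L,  list(),
    23L, "conv",          list(-1L),       1L,  320L,  list(k = 3L, s = 2L),
    24L, "concat",        list(-1L, 18L),  1L,  640L,  list(),
    25L, "c3",            list(-1L),       4L,  640L,  list(shortcut = FALSE),
    26L, "cbam",          list(-1L),       1L,  640L,  list(),
    27L, "conv",          list(-1L),       1L,  640L,  list(k = 3L, s = 2L),
    28L, "concat",        list(-1L, 14L),  1L,  1280L, list(),
    29L, "c3",            list(-1L),       4L,  1280L, list(shortcut = FALSE),
    30L, "cbam",          list(-1L),       1L,  1280L, list(),
    31L, "detect",        list(22L, 26L, 30L), 1L, NA_integer_, list()
  )
}

#' Build the detector
#'
#' Constructs the full layer graph of [layer_plan()] at the configured width
#' and depth multipliers. Parameter initialisation draws from R's RNG, so
#' `set.seed()` before building gives a reproducible network.
#'
#' @param config A [detector_config()].
#' @return An object of class `"detector"`.
#' @export
build_network <- function(config = detector_config()) {
  plan <- layer_plan()
  n_layers <- nrow(plan)
  layers <- vector("list", n_layers)
  c_outs <- integer(n_layers)
  for (i in seq_len(n_layers)) {
    row <- plan[i, ]
    kind <- row$module
    from <- vapply(row$from[[1]], function(f) {
      if (f < 0L) i - 1L + f + 1L else f + 1L   # to 1-based layer index
    }, integer(1))
    extra <- row$extra[[1]]
    c_in <- if (kind == "conv" && i == 1L) {
      3L
    } else {
      sum(c_outs[from])
    }
    c_out <- if (is.na(row$c_out)) NA_integer_ else round8(row$c_out * config$width_multiple)
    mod <- switch(kind,
      conv = mod_conv(c_in, c_out, k = extra$k, s = extra$s,
                      p = if (!is.null(extra$p)) extra$p else extra$k %/% 2L),
      c3 = mod_c3(c_in, c_out, n = scale_depth(row$number, config$depth_multiple),
                  shortcut = extra$shortcut),
      res2net_cbam = mod_res2net_cbam(c_out, s = config$res2net_scale,
                                      r = config$reduction_ratio),
      sppf = mod_sppf(c_in, c_out, k = extra$k),
      upsample = mod_upsample(),
      concat = mod_concat(),
      cbam = mod_cbam(c_out, r = config$reduction_ratio),
      detect = mod_detect(config$num_classes, config$anchors, c_outs[from],
                          config$strides, config$input_size),
      stop("unknown module kind: ", kind)
    )
    if (kind %in% c("res2net_cbam", "cbam") && c_in != c_out) {
      stop("layer ", i - 1L, " (", kind, "): input channels ", c_in,
           " do not match configured width ", c_out, call. = FALSE)
    }
    if (kind == "concat" && length(unique(from)) != length(from)) {
      stop("layer ", i - 1L, " (concat): duplicate inputs", call. = FALSE)
    }
    layers[[i]] <- list(module = mod, from = from, kind = kind)
    # bookkeeping: pass-through layers carry their realized input width, so
    # concatenated widths stay exact under any width multiplier
    c_outs[i] <- if (kind %in% c("upsample", "concat")) {
      c_in
    } else if (is.na(c_out)) {
      0L
    } else {
      c_out
    }
  }
  layers[[1]]$module$need_dx <- FALSE
  structure(
    list(layers = layers, config = config, c_outs = c_outs),
    class = "detector"
  )
}

#' Run the detector forward
#'
#' @param net A `"detector"` from [build_network()].
#' @param x Input batch: numeric array `H x W x 3 x N` (or `H x W x 3` for a
#'   single image), pixel values already scaled to `[0, 1]`. `H` and `W`
#'   must be divisible by 32.
#' @param train Training mode: batch-norm uses batch statistics and every
#'   module caches activations for the backward pass.
#' @param collect_shapes Also return a per-layer shape table (the Table-style
#'   audit of the realized graph).
#' @return A list with `raw` (list of three arrays
#'   `g x g x 3*(num_classes+5) x N`, strides 8/16/32) and, when requested,
#'   `shapes` (tibble `layer`, `module`, `h`, `w`, `c`).
#' @export
forward_network <- function(net, x, train = FALSE, collect_shapes = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input size must be divisible by 32, got ", d[1], "x", d[2],
         call. = FALSE)
  }
  n_layers <- length(net$layers)
  outputs <- vector("list", n_layers)
  shapes <- if (collect_shapes) vector("list", n_layers) else NULL
  for (i in seq_len(n_layers)) {
    ly <- net$layers[[i]]
    inputs <- lapply(ly$from, function(f) if (f == 0L) x else outputs[[f]])
    y <- if (ly$kind %in% c("concat", "detect")) {
      ly$module$fwd(inputs, train)
    } else {
      ly$module$fwd(inputs[[1]], train)
    }
    outputs[[i]] <- y
    if (collect_shapes) {
      dd <- if (ly$kind == "detect") dim(y[[1]]) else dim(y)
      shapes[[i]] <- tibble::tibble(layer = i - 1L, module = ly$kind,
                                    h = dd[1], w = dd[2], c = dd[3])
    }
    if (!train && !collect_shapes) {
      # free outputs no longer referenced downstream (memory, full-width pass)
      still_needed <- vapply(seq_len(n_layers), function(j) {
        j > i && any(vapply(net$layers[[j]]$from, function(f) f <= i, logical(1)) &
                       vapply(net$layers[[j]]$from, function(f) f >= 1, logical(1)))
      }, logical(1))
      keep <- unique(unlist(lapply(which(still_needed), function(j) net$layers[[j]]$from)))
      drop_idx <- setdiff(seq_len(i - 1L), keep)
      for (j in drop_idx) outputs[j] <- list(NULL)
    }
  }
  res <- list(raw = outputs[[n_layers]])
  if (collect_shapes) {
    det <- outputs[[n_layers]]
    det_rows <- purrr::map2_dfr(seq_along(det), det, function(s, y) {
      dd <- dim(y)
      tibble::tibble(layer = n_layers - 1L, module = "detect",
                     h = dd[1], w = dd[2], c = dd[3])
    })
    shapes[[n_layers]] <- det_rows
    res$shapes <- dplyr::bind_rows(shapes)
  }
  res
}

#' Expected layer output shapes at full multipliers, 640x640 input
#'
#' The documented contract of the realized graph: for every layer, the
#' output height, width and channel count (the detection head contributes
#' one row per scale with its raw channel count `3 * (num_classes + 5)`).
#' [audit_shapes()] checks a forward pass against this table.
#'
#' @param num_classes Label-space size (default 800).
#' @return A tibble with `layer`, `module`, `h`, `w`, `c`.
#' @export
reference_shapes_640 <- function(num_classes = 800L) {
  sizes <- c(320L, 160L, 160L, 160L, 80L, 80L, 80L, 40L, 40L, 40L, 20L, 20L,
             20L, 20L, 20L, 40L, 40L, 40L, 40L, 80L, 80L, 80L, 80L, 40L, 40L,
             40L, 40L, 20L, 20L, 20L, 20L)
  chans <- c(80L, 160L, 160L, 160L, 320L, 320L, 320L, 640L, 640L, 640L,
             1280L, 1280L, 1280L, 1280L, 640L, 640L, 1280L, 640L, 320L, 320L,
             640L, 320L, 320L, 320L, 640L, 640L, 640L, 640L, 1280L, 1280L, 1280L)
  plan <- layer_plan()
  body <- tibble::tibble(layer = 0:30, module = plan$module[1:31],
                         h = sizes, w = sizes, c = chans)
  head_rows <- tibble::tibble(layer = 31L, module = "detect",
                              h = c(80L, 40L, 20L), w = c(80L, 40L, 20L),
                              c = rep(3L * (num_classes + 5L), 3L))
  dplyr::bind_rows(body, head_rows)
}

#' Audit a forward pass against the documented layer shapes
#'
#' Runs one forward pass on a random input and compares every layer's output
#' shape (via forward hooks) with [reference_shapes_640()], scaled to the
#' configured input size and width.
#'
#' @param net A `"detector"` built at full multipliers for the strict audit,
#'   or any configuration (the reference is rescaled accordingly).
#' @param seed RNG seed for the probe input.
#' @return A tibble joining realized and expected shapes with a logical
#'   `ok` column.
#' @export
audit_shapes <- function(net, seed = 1L) {
  cfg <- net$config
  x <- with_local_seed(seed,
    array(stats::runif(cfg$input_size^2 * 3), c(cfg$input_size, cfg$input_size, 3, 1)))
  got <- forward_network(net, x, train = FALSE, collect_shapes = TRUE)$shapes
  ref <- reference_shapes_640(cfg$num_classes)
  ref$h <- as.integer(ref$h * cfg$input_size / 640L)
  ref$w <- as.integer(ref$w * cfg$input_size / 640L)
  body <- ref$layer <= 30L
  ref$c[body] <- round8(ref$c[body] * cfg$width_multiple)
  out <- dplyr::left_join(got, ref, by = c("layer", "module"),
                          suffix = c("_got", "_ref"),
                          relationship = "many-to-many")
  # detect rows: match by grid size
  det <- out$module == "detect"
  out <- out[!det | out$h_got == out$h_ref, ]
  out$ok <- out$h_got == out$h_ref & out$w_got == out$w_ref &
    out$c_got == out$c_ref
  tibble::as_tibble(out)
}

#' @export
print.detector <- function(x, ...) {
  n_par <- sum(vapply(seq_along(x$layers), function(i) {
    sum(vapply(collect_params(x$layers[[i]]$module), function(p) length(p$v),
               numeric(1)))
  }, numeric(1)))
  cat(sprintf("Part detector: %d layers, %s parameters\n",
              length(x$layers), format(n_par, big.mark = ",")))
  cat(sprintf("  classes %d | width x%.3g | depth x%.3g | input %d\n",
              x$config$num_classes, x$config$width_multiple,
              x$config$depth_multiple, x$config$input_size))
  invisible(x)
}
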