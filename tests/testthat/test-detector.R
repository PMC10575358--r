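tiny_cfg <- function(nc = 8L, input = 64L) {
  detector_config(num_classes = nc, width_multiple = 0.125,
                  depth_multiple = 0.125, input_size = input)
}

test_that("the realized head emits nc+5 values per anchor at three strides", {
  set.seed(51)
  cfg <- tiny_cfg(nc = 8L, input = 64L)
  net <- build_network(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  raw <- forward_network(net, x)$raw
  expect_length(raw, 3L)
  expect_equal(vapply(raw, function(r) dim(r)[1], integer(1)), c(8L, 4L, 2L))
  expect_equal(vapply(raw, function(r) dim(r)[3], integer(1)),
               rep(3L * (8L + 5L), 3L))
  # one class: per-anchor vector has 6 entries
  set.seed(51)
  net1 <- build_network(tiny_cfg(nc = 4L, input = 64L))
  raw1 <- forward_network(net1, x)$raw
  expect_equal(dim(raw1[[1]])[3], 3L * 9L)
})

test_that("spatial grids follow stride arithmetic for any divisible input", {
  set.seed(52)
  cfg <- tiny_cfg(nc = 4L, input = 96L)
  net <- build_network(cfg)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  raw <- forward_network(net, x)$raw
  expect_equal(vapply(raw, function(r) dim(r)[1], integer(1)),
               as.integer(96 / c(8, 16, 32)))
  expect_error(forward_network(net, array(0, c(50, 50, 3, 1))), "divisible")
})

test_that("evaluation-mode forward is deterministic and batch-consistent", {
  set.seed(53)
  net <- build_network(tiny_cfg())
  x1 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  xb <- array(0, c(64, 64, 3, 2))
  xb[, , , 1] <- x1; xb[, , , 2] <- x1
  raw_a <- forward_network(net, x1)$raw
  raw_b <- forward_network(net, xb)$raw
  for (s in 1:3) {
    expect_equal(raw_b[[s]][, , , 1], raw_a[[s]][, , , 1])
    expect_equal(raw_b[[s]][, , , 1], raw_b[[s]][, , , 2])
  }
  raw_c <- forward_network(net, x1)$raw
  expect_identical(raw_a, raw_c)
})

test_that("decode reproduces the per-cell anchor arithmetic", {
  cfg <- tiny_cfg(nc = 4L, input = 64L)
  grids <- 64L / cfg$strides
  raw <- lapply(seq_len(3), function(s) {
    array(-20, c(grids[s], grids[s], 3L * 9L, 1L))
  })
  expect_equal(nrow(decode_predictions(raw, cfg, conf_threshold = 0.001)), 0L)
  # activate one cell: scale 1 (stride 8), anchor 2, cell x=3, y=2 (0-based)
  tx <- 0.4; ty <- -0.3; tw <- 0.2; th <- -0.1
  no <- 9L; a <- 2L
  raw[[1]][2 + 1, 3 + 1, (a - 1) * no + 1:4, 1] <- c(tx, ty, tw, th)
  raw[[1]][2 + 1, 3 + 1, (a - 1) * no + 5, 1] <- 4      # objectness
  raw[[1]][2 + 1, 3 + 1, (a - 1) * no + 5 + 3, 1] <- 3  # class 2 (0-based)
  det <- decode_predictions(raw, cfg, conf_threshold = 0.25)
  expect_equal(nrow(det), 1L)
  sig <- function(z) 1 / (1 + exp(-z))
  cx <- (2 * sig(tx) - 0.5 + 3) * 8
  cy <- (2 * sig(ty) - 0.5 + 2) * 8
  bw <- (2 * sig(tw))^2 * cfg$anchors[[1]][2, 1]
  bh <- (2 * sig(th))^2 * cfg$anchors[[1]][2, 2]
  expect_equal(det$xmin, cx - bw / 2, tolerance = 1e-12)
  expect_equal(det$ymax, cy + bh / 2, tolerance = 1e-12)
  expect_equal(det$class_id, 2L)
  expect_equal(det$confidence, sig(4) * sig(3), tolerance = 1e-12)
  # decoded class carries species and part
  expect_equal(det$part, decode_class(2L, n_species = 1L)$part)

  # threshold monotonicity: conf 0 output is a superset of conf 0.25 output
  det0 <- decode_predictions(raw, cfg, conf_threshold = 0)
  expect_true(nrow(det0) >= nrow(det))
  expect_true(all(det$confidence %in% det0$confidence))
})

got_rows <- function(det, got) {
  key <- function(d) paste(d$class_id, d$confidence, d$xmin, d$ymin)
  which(key(det) %in% key(got))
}

test_that("NMS equals the brute-force suppression oracle", {
  one <- tibble::tibble(image_id = "a", class_id = 0L, species_id = 1L,
                        part = "head", confidence = 0.8,
                        xmin = 0, ymin = 0, xmax = 10, ymax = 10)
  expect_equal(nms(one, 0.45), one)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, confidence = 0.6))
  kept <- nms(two, 0.45)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.8)

  set.seed(55)
  for (rep in 1:10) {
    n <- 10L
    det <- tibble::tibble(
      image_id = "a",
      class_id = sample(0:1, n, replace = TRUE),
      confidence = round(runif(n), 3),
      xmin = runif(n, 0, 60), ymin = runif(n, 0, 60)
    )
    det$xmax <- det$xmin + runif(n, 10, 40)
    det$ymax <- det$ymin + runif(n, 10, 40)
    got <- nms(det, 0.45)
    # O(n^2) reference: per class, scan by confidence, keep if clear of all kept
    ref_rows <- integer(0)
    for (cl in unique(det$class_id)) {
      rows <- which(det$class_id == cl)
      rows <- rows[order(-det$confidence[rows], det$xmin[rows], det$ymin[rows])]
      kept_r <- integer(0)
      for (i in rows) {
        clear <- TRUE
        for (j in kept_r) {
          iou <- box_iou(as.numeric(det[i, c("xmin", "ymin", "xmax", "ymax")]),
                         as.numeric(det[j, c("xmin", "ymin", "xmax", "ymax")]))
          if (iou >= 0.45) { clear <- FALSE; break }
        }
        if (clear) kept_r <- c(kept_r, i)
      }
      ref_rows <- c(ref_rows, kept_r)
    }
    expect_setequal(which(seq_len(n) %in% ref_rows), which(seq_len(n) %in% got_rows(det, got)))
  }
  expect_error(nms(one, 1.5))
})

test_that("width scaling rounds channels to multiples of 8", {
  set.seed(56)
  cfg <- detector_config(num_classes = 4L, width_multiple = 0.125,
                         depth_multiple = 0.125, input_size = 64L)
  net <- build_network(cfg)
  expect_true(all(net$c_outs[net$c_outs > 0] %% 8L == 0L))
  # stem: 80 * 0.125 = 10 -> 8
  expect_equal(net$c_outs[1], 8L)
})
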