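box_at <- function(x, y, w = 10, h = 10) c(x, y, x + w, y + h)

toy_frame <- function(det_list, gt_list) {
  det <- dplyr::bind_rows(lapply(det_list, function(d) {
    tibble::tibble(image_id = d$im, class_id = d$cl, confidence = d$conf,
                   xmin = d$box[1], ymin = d$box[2],
                   xmax = d$box[3], ymax = d$box[4])
  }))
  gt <- dplyr::bind_rows(lapply(gt_list, function(g) {
    tibble::tibble(image_id = g$im, class_id = g$cl,
                   xmin = g$box[1], ymin = g$box[2],
                   xmax = g$box[3], ymax = g$box[4])
  }))
  list(det = det, gt = gt)
}

test_that("box IoU matches hand arithmetic", {
  a <- c(0, 0, 10, 10)
  expect_equal(as.numeric(box_iou(a, a)), 1)
  expect_equal(as.numeric(box_iou(a, c(5, 0, 15, 10))), 50 / 150)
  expect_equal(as.numeric(box_iou(a, c(20, 20, 30, 30))), 0)
  m <- box_iou(rbind(a, c(0, 0, 5, 5)), rbind(a, c(10, 10, 20, 20)))
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(m[2, 1], 25 / 100)
})

test_that("matching flags perfect detections as TP and misses as FN", {
  tf <- toy_frame(
    det_list = list(list(im = "a", cl = 0L, conf = 0.9, box = box_at(0, 0)),
                    list(im = "a", cl = 1L, conf = 0.8, box = box_at(20, 0))),
    gt_list = list(list(im = "a", cl = 0L, box = box_at(0, 0)),
                   list(im = "a", cl = 1L, box = box_at(20, 0)))
  )
  m <- match_detections(tf$det, tf$gt)
  expect_true(all(m$matches$tp))
  pr <- precision_recall(m)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  m0 <- match_detections(tf$det[0, ], tf$gt)
  expect_warning(pr0 <- precision_recall(m0), "no detections")
  expect_equal(pr0$fn, 2L)
  expect_equal(pr0$recall, 0)
})

test_that("greedy matching equals a brute-force assignment oracle on a toy layout", {
  # 5 detections, 3 truths, one class, one image
  gt_boxes <- list(box_at(0, 0), box_at(30, 0), box_at(60, 0))
  det <- list(
    list(im = "a", cl = 0L, conf = 0.95, box = box_at(1, 1)),    # hits gt1
    list(im = "a", cl = 0L, conf = 0.90, box = box_at(2, 2)),    # gt1 taken -> FP
    list(im = "a", cl = 0L, conf = 0.85, box = box_at(31, 0)),   # hits gt2
    list(im = "a", cl = 0L, conf = 0.80, box = box_at(100, 100)),# FP
    list(im = "a", cl = 0L, conf = 0.75, box = box_at(59, 1))    # hits gt3
  )
  tf <- toy_frame(det, lapply(gt_boxes, function(b) list(im = "a", cl = 0L, box = b)))
  m <- match_detections(tf$det, tf$gt, iou_threshold = 0.5)
  # brute-force oracle: walk detections by confidence, claim best free truth
  claimed <- rep(FALSE, 3)
  flags <- logical(5)
  ord <- order(-tf$det$confidence)
  for (i in ord) {
    ious <- vapply(seq_along(gt_boxes), function(j) {
      as.numeric(box_iou(as.numeric(tf$det[i, c("xmin", "ymin", "xmax", "ymax")]),
                         gt_boxes[[j]]))
    }, numeric(1))
    ious[claimed] <- -1
    j <- which.max(ious)
    if (ious[j] >= 0.5) { claimed[j] <- TRUE; flags[i] <- TRUE }
  }
  expect_equal(m$matches$tp, flags[ord])
  expect_equal(sum(m$matches$tp), 3L)
})

test_that("precision and recall are the exact TP ratios", {
  fake <- structure(list(
    matches = tibble::tibble(confidence = rep(1, 10),
                             tp = rep(c(TRUE, FALSE), c(8, 2))),
    gt_counts = tibble::tibble(class_id = 0L, n_gt = 10L)
  ), class = "detection_match")
  pr <- precision_recall(fake)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)
  fake$gt_counts$n_gt <- 10L
  fake$matches <- fake$matches[1:10, ]
  fake$matches$tp <- rep(c(TRUE, FALSE), c(7, 3))
  expect_equal(precision_recall(fake)$recall, 0.7)
})

test_that("average precision follows the interpolated-sum formula", {
  # ranked flags (TP, FP, TP, TP, FP) with 4 ground truths
  fake <- structure(list(
    matches = tibble::tibble(class_id = 0L,
                             confidence = c(0.9, 0.8, 0.7, 0.6, 0.5),
                             tp = c(TRUE, FALSE, TRUE, TRUE, FALSE)),
    gt_counts = tibble::tibble(class_id = 0L, n_gt = 4L)
  ), class = "detection_match")
  # literal-formula oracle: AP = sum (r_{i+1} - r_i) P_inter(r_{i+1})
  tp_cum <- cumsum(fake$matches$tp); fp_cum <- cumsum(!fake$matches$tp)
  rec <- tp_cum / 4; prec <- tp_cum / (tp_cum + fp_cum)
  ap_ref <- 0
  r_prev <- 0
  for (i in seq_along(rec)) {
    p_inter <- max(prec[rec >= rec[i]])
    ap_ref <- ap_ref + (rec[i] - r_prev) * p_inter
    r_prev <- rec[i]
  }
  expect_equal(average_precision(fake, 0L), ap_ref)
  expect_equal(ap_ref, 0.625)  # hand sum: .25*1 + .25*.75 + .25*.75

  # all TP at full recall -> 1; no TP -> 0
  all_tp <- fake
  all_tp$matches$tp <- rep(TRUE, 5)
  all_tp$gt_counts$n_gt <- 5L
  expect_equal(average_precision(all_tp, 0L), 1)
  none <- fake
  none$matches$tp <- rep(FALSE, 5)
  expect_equal(average_precision(none, 0L), 0)
  expect_error(average_precision(fake, 3L), "no ground truth")
})

test_that("deleting a false positive never lowers AP", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 8L
    flags <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(flags)) flags[1] <- TRUE
    if (!any(!flags)) flags[n] <- FALSE
    fake <- structure(list(
      matches = tibble::tibble(class_id = 0L,
                               confidence = seq(0.9, 0.1, length.out = n),
                               tp = flags),
      gt_counts = tibble::tibble(class_id = 0L, n_gt = sum(flags) + 1L)
    ), class = "detection_match")
    ap0 <- average_precision(fake, 0L)
    drop <- which(!flags)[1]
    fake$matches <- fake$matches[-drop, ]
    expect_gte(average_precision(fake, 0L), ap0)
    expect_lte(average_precision(fake, 0L), 1)
  }
})

test_that("mAP is exactly the mean of per-class APs", {
  expect_equal(mean_ap(c(1, 0)), 0.5)
  expect_equal(mean_ap(c(0.4, 0.4, 0.4)), 0.4)
  set.seed(42)
  aps <- runif(5)
  expect_equal(mean_ap(aps), sum(aps) / 5)
  expect_error(mean_ap(numeric(0)), "no classes")
})

test_that("the full evaluation chain matches brute force on toy scenes", {
  set.seed(43)
  tf <- toy_frame(
    det_list = list(
      list(im = "a", cl = 0L, conf = 0.9, box = box_at(0, 0)),
      list(im = "a", cl = 0L, conf = 0.6, box = box_at(50, 50)),
      list(im = "b", cl = 0L, conf = 0.8, box = box_at(5, 5)),
      list(im = "b", cl = 4L, conf = 0.7, box = box_at(30, 30)),
      list(im = "b", cl = 4L, conf = 0.3, box = box_at(90, 90))
    ),
    gt_list = list(
      list(im = "a", cl = 0L, box = box_at(0, 0)),
      list(im = "b", cl = 0L, box = box_at(6, 6)),
      list(im = "b", cl = 4L, box = box_at(30, 30)),
      list(im = "b", cl = 4L, box = box_at(60, 60))
    )
  )
  rep_ <- evaluate_detections(tf$det, tf$gt, conf_threshold = 0)
  # class 0: flags (a:TP, b:TP, a-far:FP) ranked 0.9, 0.8, 0.6 -> TP TP FP
  # AP = 1.0 over recall 0..1 (2 truths found before any FP)
  # class 4: flags TP (0.7), FP-far (0.3), 2 truths -> AP = 0.5
  expect_equal(rep_$ap_per_class$ap[rep_$ap_per_class$class_id == 0L], 1)
  expect_equal(rep_$ap_per_class$ap[rep_$ap_per_class$class_id == 4L], 0.5)
  expect_equal(rep_$map50, 0.75)
  expect_equal(rep_$map50, mean(rep_$ap_per_class$ap))
  gl <- glance(rep_)
  expect_equal(gl$map50, 0.75)
  td <- tidy(rep_)
  expect_equal(nrow(td), 2L)
})
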