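#' Intersection-over-union of two box sets
#'
#' Boxes are 0-based half-open `(xmin, ymin, xmax, ymax)`. With `a` an
#' `n x 4` and `b` an `m x 4` matrix, returns the `n x m` IoU matrix.
#'
#' @param a,b Numeric matrices with 4 columns (or length-4 vectors).
#' @return Matrix of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4L)
  b <- matrix(as.numeric(b), ncol = 4L)
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3L], b[, 3L], pmin) - outer(a[, 1L], b[, 1L], pmax))
  iy <- pmax(0, outer(a[, 4L], b[, 4L], pmin) - outer(a[, 2L], b[, 2L], pmax))
  inter <- ix * iy
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / pmax(un, .Machine$double.eps)
  dim(out) <- c(n, m)
  out
}

#' Match detections to ground-truth boxes at an IoU threshold
#'
#' Per class, detections are ranked by descending confidence (ties broken by
#' class id then box area, so the ranking is reproducible) and greedily claim
#' the not-yet-claimed ground-truth box of the same image with the highest
#' IoU at or above the threshold. A detection that claims a box is a true
#' positive; otherwise a false positive. Each ground-truth box can be claimed
#' at most once; unclaimed boxes are false negatives.
#'
#' @param detections Tibble with `image_id`, `class_id`, `confidence`,
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @param ground_truth Tibble with `image_id`, `class_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @param iou_threshold True-positive criterion (default 0.5, i.e. mAP@0.5).
#' @return An object of class `"detection_match"`: list with `matches`
#'   (ranked detection tibble plus logical `tp`), `gt_counts` (tibble
#'   `class_id`, `n_gt`), and `iou_threshold`.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  det <- detections
  if (nrow(det) > 0L) {
    det$.area <- (det$xmax - det$xmin) * (det$ymax - det$ymin)
    det <- dplyr::arrange(det, dplyr::desc(.data$confidence),
                          .data$class_id, .data$.area)
    det$.area <- NULL
  }
  det$tp <- logical(nrow(det))
  gt_counts <- ground_truth |>
    dplyr::count(.data$class_id, name = "n_gt") |>
    tibble::as_tibble()
  claimed <- logical(nrow(ground_truth))
  if (nrow(det) > 0L && nrow(ground_truth) > 0L) {
    gt_key <- paste(ground_truth$image_id, ground_truth$class_id)
    gt_by_key <- split(seq_len(nrow(ground_truth)), gt_key)
    gt_boxes <- as.matrix(ground_truth[, c("xmin", "ymin", "xmax", "ymax")])
    det_boxes <- as.matrix(det[, c("xmin", "ymin", "xmax", "ymax")])
    for (i in seq_len(nrow(det))) {
      cand <- gt_by_key[[paste(det$image_id[i], det$class_id[i])]]
      cand <- cand[!claimed[cand]]
      if (length(cand) == 0L) next
      ious <- box_iou(det_boxes[i, , drop = FALSE], gt_boxes[cand, , drop = FALSE])
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        claimed[cand[j]] <- TRUE
        det$tp[i] <- TRUE
      }
    }
  }
  structure(
    list(matches = tibble::as_tibble(det), gt_counts = gt_counts,
         iou_threshold = iou_threshold),
    class = "detection_match"
  )
}

#' Aggregate precision and recall of a detection match
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)` over all
#' detections at or above `conf_threshold`. A zero denominator yields 0 with
#' a warning.
#'
#' @param match A `"detection_match"` from [match_detections()].
#' @param conf_threshold Minimum confidence counted (default 0: all).
#' @return A one-row tibble with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(match, conf_threshold = 0) {
  m <- match$matches[match$matches$confidence >= conf_threshold, ]
  tp <- sum(m$tp)
  fp <- sum(!m$tp)
  n_gt <- sum(match$gt_counts$n_gt)
  fn <- n_gt - tp
  if (tp + fp == 0L) warning("no detections: precision defined as 0")
  if (n_gt == 0L) warning("no ground truth: recall defined as 0")
  tibble::tibble(
    precision = if (tp + fp > 0L) tp / (tp + fp) else 0,
    recall = if (n_gt > 0L) tp / n_gt else 0,
    tp = tp, fp = fp, fn = fn
  )
}

#' Average precision of one class (all-point interpolation)
#'
#' Over the class's confidence-ranked detections, the cumulative
#' precision/recall curve is interpolated with
#' `P_inter(r) = max{precision at recall >= r}` and integrated as
#' `AP = sum_i (r_{i+1} - r_i) * P_inter(r_{i+1})` from `r_0 = 0`.
#'
#' @param match A `"detection_match"`.
#' @param class_id Class to evaluate; must have at least one ground truth.
#' @return A single number in `[0, 1]`.
#' @export
average_precision <- function(match, class_id) {
  n_gt <- match$gt_counts$n_gt[match$gt_counts$class_id == class_id]
  if (length(n_gt) == 0L || n_gt == 0L) {
    stop("class ", class_id, " has no ground truth; excluded from AP", call. = FALSE)
  }
  m <- match$matches[match$matches$class_id == class_id, ]
  if (nrow(m) == 0L || !any(m$tp)) return(0)
  tp_cum <- cumsum(m$tp)
  fp_cum <- cumsum(!m$tp)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # interpolated precision: running max from the right
  p_inter <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * p_inter)
}

#' Mean average precision over classes
#'
#' Arithmetic mean of per-class AP over the classes that have ground truth.
#'
#' @param ap_per_class Named numeric vector (or tibble with `ap` column) of
#'   per-class average precisions.
#' @return A single number.
#' @export
mean_ap <- function(ap_per_class) {
  if (is.data.frame(ap_per_class)) ap_per_class <- ap_per_class$ap
  if (length(ap_per_class) == 0L) stop("no classes with ground truth", call. = FALSE)
  mean(ap_per_class)
}

#' Full detection evaluation report
#'
#' Matches detections to ground truth at `iou_threshold`, computes aggregate
#' precision/recall at `conf_threshold`, per-class AP for every class with
#' ground truth, and their mean (mAP@IoU).
#'
#' @inheritParams match_detections
#' @param conf_threshold Confidence floor for the aggregate precision/recall
#'   operating point (default 0.001).
#' @return An object of class `"metrics_report"`: list with `precision`,
#'   `recall`, `ap_per_class` (tibble `class_id`, `ap`), `map50`, `n_images`,
#'   `iou_threshold`, `conf_threshold`.
#' @export
evaluate_detections <- function(detections, ground_truth, iou_threshold = 0.5,
                                conf_threshold = 0.001) {
  match <- match_detections(detections, ground_truth, iou_threshold)
  pr <- precision_recall(match, conf_threshold)
  classes <- sort(match$gt_counts$class_id[match$gt_counts$n_gt > 0L])
  ap <- vapply(classes, function(cl) average_precision(match, cl), numeric(1))
  structure(
    list(
      precision = pr$precision, recall = pr$recall,
      tp = pr$tp, fp = pr$fp, fn = pr$fn,
      ap_per_class = tibble::tibble(class_id = classes, ap = ap),
      map50 = mean_ap(ap),
      n_images = length(unique(ground_truth$image_id)),
      iou_threshold = iou_threshold, conf_threshold = conf_threshold
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU %.2f, conf >= %g)\n",
              x$iou_threshold, x$conf_threshold))
  cat(sprintf("  images    : %d\n", x$n_images))
  cat(sprintf("  precision : %.4f   recall : %.4f   (TP %d / FP %d / FN %d)\n",
              x$precision, x$recall, x$tp, x$fp, x$fn))
  cat(sprintf("  mAP@%.1f   : %.4f over %d classes\n",
              x$iou_threshold, x$map50, nrow(x$ap_per_class)))
  invisible(x)
}

#' Tidy a metrics report: one row per class with its AP
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble `class_id`, `species_id`, `part`, `ap`.
#' @export
tidy.metrics_report <- function(x, ...) {
  n_species <- max(x$ap_per_class$class_id %/% 4L + 1L, 1L)
  dec <- decode_class(x$ap_per_class$class_id, n_species = n_species)
  tibble::tibble(
    class_id = x$ap_per_class$class_id,
    species_id = dec$species_id,
    part = dec$part,
    ap = x$ap_per_class$ap
  )
}

#' One-row summary of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    precision = x$precision, recall = x$recall, map50 = x$map50,
    n_classes = nrow(x$ap_per_class), n_images = x$n_images
  )
}

#' Plot per-class average precision
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidy(object)
  df$label <- sprintf("%03d_%s", df$species_id, df$part)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$ap),
                                   y = .data$ap, fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("AP@%.1f", object$iou_threshold),
                  title = sprintf("Per-class average precision (mAP %.3f)",
                                  object$map50)) +
    ggplot2::theme_minimal()
}
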