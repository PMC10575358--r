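#' Enumerate all part-weight vectors on a simplex grid
#'
#' All 4-tuples `(w_head, w_leftwing, w_rightwing, w_tail)` of non-negative
#' multiples of `step_hundredths` (in hundredths) that sum to exactly 100.
#' At the method's grid of 0.01 (`step_hundredths = 1`) there are
#' `choose(103, 3) = 176,851` such vectors. Weights are kept as integers so
#' "sums to one" is exact.
#'
#' @param step_hundredths Grid step in hundredths (1 = 0.01). Must divide 100.
#' @return A tibble with integer columns `w_head`, `w_leftwing`,
#'   `w_rightwing`, `w_tail`, in ascending lexicographic order.
#' @export
#' @examples
#' nrow(enumerate_weight_vectors(50))  # 10
enumerate_weight_vectors <- function(step_hundredths = 1L) {
  step <- as.integer(step_hundredths)
  if (is.na(step) || step < 1L || 100L %% step != 0L) {
    stop("step_hundredths must be a positive divisor of 100", call. = FALSE)
  }
  g <- seq.int(0L, 100L, by = step)
  # w1 slow, w2, w3 fast; w4 is the remainder
  grid <- expand.grid(w_rightwing = g, w_leftwing = g, w_head = g,
                      KEEP.OUT.ATTRS = FALSE)
  s <- grid$w_head + grid$w_leftwing + grid$w_rightwing
  keep <- s <= 100L
  out <- tibble::tibble(
    w_head = as.integer(grid$w_head[keep]),
    w_leftwing = as.integer(grid$w_leftwing[keep]),
    w_rightwing = as.integer(grid$w_rightwing[keep]),
    w_tail = as.integer(100L - s[keep])
  )
  dplyr::arrange(out, .data$w_head, .data$w_leftwing, .data$w_rightwing)
}

#' Weighted confidence vote over the part records of one image
#'
#' Each part record votes for its predicted species with weight
#' `w_part / 100 * confidence`; the species with the largest summed score
#' wins. An exact score tie is broken toward the lower species id. If no
#' record carries positive weighted score the vote abstains.
#'
#' @param records Tibble with columns `part`, `species_id`, `confidence`
#'   for a single image (at most one row per part).
#' @param weights Integer weight vector in hundredths: a named numeric/list
#'   with entries `w_head`, `w_leftwing`, `w_rightwing`, `w_tail`, or an
#'   unnamed length-4 vector in part order.
#' @return A one-row tibble with `species_id` (NA on abstention) and `score`.
#' @export
weighted_vote <- function(records, weights) {
  w <- as_weight4(weights)
  if (nrow(records) == 0L) {
    return(tibble::tibble(species_id = NA_integer_, score = 0))
  }
  sc <- records$confidence * w[part_ordinal(records$part) + 1L] / 100
  tab <- rowsum(sc, group = records$species_id)
  species <- as.integer(rownames(tab))
  ord <- order(species)            # ties -> lowest species id
  tab <- tab[ord, 1L]
  species <- species[ord]
  best <- which.max(tab)
  if (tab[best] <= 0) {
    return(tibble::tibble(species_id = NA_integer_, score = 0))
  }
  tibble::tibble(species_id = species[best], score = unname(tab[best]))
}

as_weight4 <- function(weights) {
  nm <- paste0("w_", part_types())
  if (is.data.frame(weights)) weights <- unlist(weights[1, , drop = TRUE])
  if (!is.null(names(weights)) && all(nm %in% names(weights))) {
    w <- as.numeric(weights[nm])
  } else if (length(weights) == 4L) {
    w <- as.numeric(weights)
  } else {
    stop("weights must be a length-4 vector or carry names ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  w
}

#' Classification accuracy of per-image predictions
#'
#' Fraction of images whose predicted species equals the true species.
#' Abstentions (`NA` predictions) count as errors.
#'
#' @param predictions Tibble with columns `image_id`, `species_id`.
#' @param truth Tibble with columns `image_id`, `species_id`.
#' @return A single number in `[0, 1]`.
#' @export
classification_accuracy <- function(predictions, truth) {
  if (!setequal(predictions$image_id, truth$image_id)) {
    stop("predictions and truth must cover the same image set", call. = FALSE)
  }
  joined <- dplyr::inner_join(predictions, truth, by = "image_id",
                              suffix = c("_pred", "_true"))
  mean(!is.na(joined$species_id_pred) &
         joined$species_id_pred == joined$species_id_true)
}

#' Exhaustive part-weight search maximising classification accuracy
#'
#' Evaluates the weighted confidence vote under every weight vector on the
#' simplex grid (all `choose(100/step + 3, 3)` of them; 176,851 at the 0.01
#' grid) and returns the accuracy maximiser. Ties across weight vectors go to
#' the lexicographically smallest vector (ordered `w_head`, `w_leftwing`,
#' `w_rightwing`, `w_tail`); the number of tied maximisers is reported.
#'
#' The search is vectorised: per image the candidate species are the (at
#' most four) species its part records name, and all weight vectors are
#' scored against them in one matrix product.
#'
#' @param part_table Tibble of part records (`image_id`, `part`,
#'   `species_id`, `confidence`), at most one row per (image, part) — see
#'   [select_best_per_part()].
#' @param truth Tibble with `image_id`, `species_id` covering every image in
#'   `part_table` (images with no records at all may appear only in `truth`;
#'   they count as abstentions).
#' @param step_hundredths Simplex grid step in hundredths (default 1 = 0.01).
#' @return An object of class `"fusion_result"`: a list with
#'   `best_weights` (one-row tibble), `best_accuracy`, `n_evaluated`,
#'   `n_tied`, `n_abstained`, `predictions` (per-image tibble under the best
#'   weights), and `accuracies` (per-vector accuracy, aligned with
#'   `enumerate_weight_vectors(step_hundredths)`).
#' @export
grid_search_weights <- function(part_table, truth, step_hundredths = 1L) {
  if (nrow(truth) == 0L) stop("empty table: no images to evaluate", call. = FALSE)
  if (!all(part_table$image_id %in% truth$image_id)) {
    stop("truth is missing images present in the part table", call. = FALSE)
  }
  wv <- enumerate_weight_vectors(step_hundredths)
  W <- cbind(wv$w_head, wv$w_leftwing, wv$w_rightwing, wv$w_tail) / 100
  n_w <- nrow(W)
  images <- truth$image_id
  n_img <- length(images)

  recs <- dplyr::filter(part_table, .data$confidence > 0)
  recs$part_ord <- part_ordinal(recs$part) + 1L
  by_img <- split(recs[c("part_ord", "species_id", "confidence")], recs$image_id)

  correct <- numeric(n_w)
  n_abstain <- 0L
  for (i in seq_len(n_img)) {
    r <- by_img[[images[i]]]
    if (is.null(r) || nrow(r) == 0L) {
      n_abstain <- n_abstain + 1L
      next
    }
    cand <- sort(unique(r$species_id))
    A <- matrix(0, nrow = 4L, ncol = length(cand))
    A[cbind(r$part_ord, match(r$species_id, cand))] <- r$confidence
    S <- W %*% A                                   # n_w x n_cand scores
    if (ncol(S) == 1L) {
      hit <- (S[, 1L] > 0) & (cand[1L] == truth$species_id[i])
    } else {
      top <- max.col(S, ties.method = "first")     # first = lowest species id
      smax <- S[cbind(seq_len(n_w), top)]
      hit <- (smax > 0) & (cand[top] == truth$species_id[i])
    }
    correct <- correct + hit
  }
  acc <- correct / n_img
  best_acc <- max(acc)
  tied <- which(acc == best_acc)
  best_idx <- tied[1L]                             # wv is lexicographic

  best_w <- wv[best_idx, ]
  preds <- predict_species(part_table, best_w, image_ids = images)
  structure(
    list(
      best_weights = best_w,
      best_accuracy = best_acc,
      n_evaluated = n_w,
      n_tied = length(tied),
      n_abstained = n_abstain,
      step_hundredths = as.integer(step_hundredths),
      predictions = preds,
      accuracies = acc
    ),
    class = "fusion_result"
  )
}

#' Per-image species predictions under a fixed weight vector
#'
#' @param part_table Tibble of part records.
#' @param weights Weight vector (see [weighted_vote()]).
#' @param image_ids Optional full image universe; images without records are
#'   emitted with `species_id = NA` (abstention).
#' @return Tibble with `image_id`, `species_id`, `score`.
#' @export
predict_species <- function(part_table, weights, image_ids = NULL) {
  w <- as_weight4(weights)
  groups <- split(part_table, part_table$image_id)
  out <- purrr::imap(groups, function(g, id) {
    v <- weighted_vote(g, w)
    v$image_id <- id
    v
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(species_id = integer(), score = double(),
                          image_id = character())
  }
  if (!is.null(image_ids)) {
    missing <- setdiff(as.character(image_ids), res$image_id)
    if (length(missing)) {
      res <- dplyr::bind_rows(res, tibble::tibble(
        species_id = NA_integer_, score = 0, image_id = missing))
    }
    res <- res[match(as.character(image_ids), res$image_id), ]
  }
  dplyr::select(res, "image_id", "species_id", "score")
}

#' @export
print.fusion_result <- function(x, ...) {
  w <- x$best_weights
  cat("Part-weight grid search (step ", x$step_hundredths / 100, ")\n", sep = "")
  cat(sprintf("  evaluated : %d weight vectors\n", x$n_evaluated))
  cat(sprintf("  best      : head %.2f, leftwing %.2f, rightwing %.2f, tail %.2f\n",
              w$w_head / 100, w$w_leftwing / 100, w$w_rightwing / 100, w$w_tail / 100))
  cat(sprintf("  accuracy  : %.4f  (%d tied maximiser%s, %d abstention%s)\n",
              x$best_accuracy, x$n_tied, if (x$n_tied == 1L) "" else "s",
              x$n_abstained, if (x$n_abstained == 1L) "" else "s"))
  invisible(x)
}

#' Tidy a fusion result
#'
#' One row per part with its optimal weight.
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return A tibble with `part`, `weight` (on the 0-1 scale).
#' @export
tidy.fusion_result <- function(x, ...) {
  tibble::tibble(
    part = part_types(),
    weight = as.numeric(x$best_weights[paste0("w_", part_types())]) / 100
  )
}

#' One-row summary of a fusion result
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.fusion_result <- function(x, ...) {
  tibble::tibble(
    best_accuracy = x$best_accuracy,
    n_evaluated = x$n_evaluated,
    n_tied = x$n_tied,
    n_abstained = x$n_abstained,
    step = x$step_hundredths / 100
  )
}

#' Plot the accuracy profile of a weight grid search
#'
#' Accuracy as a function of the head weight (the remaining weight mass
#' spread over the other parts), summarised by the per-`w_head` maximum.
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_result <- function(object, ...) {
  wv <- enumerate_weight_vectors(object$step_hundredths)
  df <- tibble::tibble(w_head = wv$w_head / 100, accuracy = object$accuracies)
  prof <- dplyr::summarise(dplyr::group_by(df, .data$w_head),
                           accuracy = max(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$w_head, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_weights$w_head / 100,
                        linetype = "dashed") +
    ggplot2::labs(x = "head weight", y = "best accuracy at this head weight",
                  title = "Weight-search accuracy profile") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
NULL
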