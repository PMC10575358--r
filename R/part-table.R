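#' Reduce raw detections to the per-image part table
#'
#' For every (image, part type) group, keeps exactly the highest-confidence
#' detection and discards the rest, so each image retains at most four
#' records — one per part. Confidence ties are broken deterministically
#' toward the lower class id, then the smaller box area, so the result does
#' not depend on input order.
#'
#' @param detections Tibble of detections with columns `image_id`,
#'   `class_id` (or `part` + `species_id`), `confidence`, and optionally
#'   box columns `xmin`, `ymin`, `xmax`, `ymax` (used only for tie-breaks).
#' @param n_species Species vocabulary size for decoding `class_id`.
#' @return A tibble with columns `image_id`, `part`, `species_id`,
#'   `confidence`, one row per detected (image, part).
#' @export
select_best_per_part <- function(detections, n_species = 200L) {
  if (nrow(detections) == 0L) {
    return(tibble::tibble(image_id = character(), part = character(),
                          species_id = integer(), confidence = double()))
  }
  det <- detections
  if (!all(c("part", "species_id") %in% names(det))) {
    dec <- decode_class(det$class_id, n_species = n_species)
    det$part <- dec$part
    det$species_id <- dec$species_id
  }
  if (!"class_id" %in% names(det)) {
    det$class_id <- encode_class(det$species_id, det$part, n_species = n_species)
  }
  det$.area <- if ("xmin" %in% names(det)) {
    (det$xmax - det$xmin) * (det$ymax - det$ymin)
  } else {
    0
  }
  out <- det |>
    dplyr::arrange(.data$image_id, .data$part,
                   dplyr::desc(.data$confidence), .data$class_id, .data$.area) |>
    dplyr::distinct(.data$image_id, .data$part, .keep_all = TRUE) |>
    dplyr::select("image_id", "part", "species_id", "confidence")
  tibble::as_tibble(out)
}

#' Write / read a part table as CSV
#'
#' @param part_table Tibble from [select_best_per_part()].
#' @param path CSV path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_part_table <- function(part_table, path) {
  utils::write.csv(part_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_part_table
#' @export
read_part_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(image_id = "character")))
}
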