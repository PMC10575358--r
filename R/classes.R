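#' The four bird part types
#'
#' The part vocabulary used throughout the package: head, left wing, right
#' wing, tail, in that fixed order. The ordinal of a part (0-based position in
#' this vector) is stable and enters the class encoding.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' part_types()
part_types <- function() {
  c("head", "leftwing", "rightwing", "tail")
}

#' Ordinal of a part type
#'
#' @param part Character vector of part names (see [part_types()]).
#' @return Integer vector of 0-based ordinals (head = 0, ..., tail = 3).
#' @export
part_ordinal <- function(part) {
  idx <- match(part, part_types())
  if (anyNA(idx)) {
    bad <- unique(part[is.na(idx)])
    stop("unknown part type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' Encode (species, part) as a detector class id
#'
#' The detector's label space crosses 200 species with 4 parts into 800
#' classes. Encoding is species-major: `class_id = (species_id - 1) * 4 +
#' ordinal(part)`, so the species is recovered by integer division by 4.
#'
#' @param species_id Integer vector in `1:n_species`.
#' @param part Character vector of part names, recycled against `species_id`.
#' @param n_species Number of species in the label space (default 200).
#' @return Integer vector of class ids in `0:(4 * n_species - 1)`.
#' @seealso [decode_class()]
#' @export
#' @examples
#' encode_class(1, "head")    # 0
#' encode_class(200, "tail")  # 799
encode_class <- function(species_id, part, n_species = 200L) {
  species_id <- as.integer(species_id)
  if (anyNA(species_id) || any(species_id < 1L) || any(species_id > n_species)) {
    stop("species_id must lie in 1..", n_species, call. = FALSE)
  }
  (species_id - 1L) * 4L + part_ordinal(part)
}

#' Decode a detector class id into (species, part)
#'
#' Inverse of [encode_class()].
#'
#' @param class_id Integer vector in `0:(4 * n_species - 1)`.
#' @param n_species Number of species in the label space (default 200).
#' @return A tibble with columns `class_id`, `species_id`, `part`.
#' @export
#' @examples
#' decode_class(c(0L, 5L, 799L))
decode_class <- function(class_id, n_species = 200L) {
  class_id <- as.integer(class_id)
  if (anyNA(class_id) || any(class_id < 0L) || any(class_id >= 4L * n_species)) {
    stop("class_id must lie in 0..", 4L * n_species - 1L, call. = FALSE)
  }
  tibble::tibble(
    class_id = class_id,
    species_id = class_id %/% 4L + 1L,
    part = part_types()[class_id %% 4L + 1L]
  )
}

#' Class-name strings for the part-species label space
#'
#' One name per class id, `"<species_id:03d>_<part>"` (e.g. `"017_leftwing"`),
#' in class-id order. This is also the object-name dialect written into the
#' VOC XML files.
#'
#' @param n_species Number of species (default 200, giving 800 names).
#' @return Character vector of length `4 * n_species`.
#' @export
class_names <- function(n_species = 200L) {
  dec <- decode_class(seq_len(4L * n_species) - 1L, n_species = n_species)
  sprintf("%03d_%s", dec$species_id, dec$part)
}

#' Parse class-name strings back to species and part
#'
#' @param name Character vector in the `"<species_id>_<part>"` dialect.
#' @return A tibble with columns `species_id`, `part`.
#' @keywords internal
parse_object_name <- function(name) {
  m <- regmatches(name, regexec("^([0-9]+)_(head|leftwing|rightwing|tail)$", name))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(
      "object name(s) not in '<species_id>_<part>' form: ",
      paste(unique(name[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    species_id = as.integer(vapply(m, `[`, character(1), 2L)),
    part = vapply(m, `[`, character(1), 3L)
  )
}
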