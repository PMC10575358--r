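#' Read part annotations from a PASCAL VOC XML file
#'
#' Parses one VOC annotation file into a tibble of part boxes. Object names
#' must follow the `"<species_id>_<part>"` dialect written by
#' [write_voc_xml()]. VOC stores 1-based inclusive pixel coordinates; they are
#' converted to the package's internal 0-based half-open convention
#' `(xmin - 1, ymin - 1, xmax, ymax)`, under which box width is simply
#' `xmax - xmin`.
#'
#' @param path Path to a VOC XML file.
#' @param n_species Size of the species vocabulary (default 200).
#' @return A tibble with one row per `<object>`: columns `image_id`, `part`,
#'   `species_id`, `class_id`, `xmin`, `ymin`, `xmax`, `ymax`, `width`,
#'   `height` (image size).
#' @export
read_voc_xml <- function(path, n_species = 200L) {
  if (!file.exists(path)) stop("no such annotation file: ", path, call. = FALSE)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed VOC XML in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  image_id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  if (is.na(image_id) || !nzchar(image_id)) {
    image_id <- sub("\\.xml$", "", basename(path))
  } else {
    image_id <- sub("\\.(png|jpg|jpeg)$", "", image_id, ignore.case = TRUE)
  }
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) == 0L) {
    return(tibble::tibble(
      image_id = character(), part = character(), species_id = integer(),
      class_id = integer(), xmin = double(), ymin = double(),
      xmax = double(), ymax = double(), width = integer(), height = integer()
    ))
  }
  nm <- xml2::xml_text(xml2::xml_find_first(objs, "./name"))
  parsed <- parse_object_name(nm)
  num <- function(field) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(objs, paste0("./bndbox/", field))))
  }
  # VOC 1-based inclusive -> 0-based half-open
  ann <- tibble::tibble(
    image_id = image_id,
    part = parsed$part,
    species_id = parsed$species_id,
    class_id = encode_class(parsed$species_id, parsed$part, n_species = n_species),
    xmin = num("xmin") - 1, ymin = num("ymin") - 1,
    xmax = num("xmax"), ymax = num("ymax"),
    width = width, height = height
  )
  if (any(ann$xmin >= ann$xmax) || any(ann$ymin >= ann$ymax)) {
    stop("degenerate box (xmin >= xmax or ymin >= ymax) in ", path, call. = FALSE)
  }
  ann
}

#' Write part annotations to a PASCAL VOC XML file
#'
#' Inverse of [read_voc_xml()]: internal 0-based half-open coordinates are
#' converted back to VOC's 1-based inclusive convention. Object names are
#' written as `"<species_id:03d>_<part>"`.
#'
#' @param annotations Tibble with columns `part`, `species_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (0-based half-open, in pixels). May have zero rows.
#' @param image_meta List or vector with `width`, `height` and optionally
#'   `depth` (default 3) of the image.
#' @param path Output path.
#' @param image_id Image identifier written to `<filename>`; defaults to the
#'   file's base name.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(annotations, image_meta, path,
                          image_id = sub("\\.xml$", "", basename(path))) {
  width <- as.integer(image_meta[["width"]])
  height <- as.integer(image_meta[["height"]])
  depth <- if (!is.null(image_meta[["depth"]])) as.integer(image_meta[["depth"]]) else 3L
  n <- nrow(annotations)
  if (n > 0L) {
    ok <- annotations$xmin >= 0 & annotations$ymin >= 0 &
      annotations$xmax <= width & annotations$ymax <= height &
      annotations$xmin < annotations$xmax & annotations$ymin < annotations$ymax
    if (!all(ok)) {
      stop("box out of image bounds or degenerate in annotations for ", image_id, call. = FALSE)
    }
  }
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "JPEGImages")
  xml2::xml_add_child(doc, "filename", paste0(image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(width))
  xml2::xml_add_child(size, "height", as.character(height))
  xml2::xml_add_child(size, "depth", as.character(depth))
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(n)) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name",
      sprintf("%03d_%s", annotations$species_id[i], annotations$part[i]))
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    # 0-based half-open -> VOC 1-based inclusive
    xml2::xml_add_child(bb, "xmin", as.character(as.integer(annotations$xmin[i] + 1)))
    xml2::xml_add_child(bb, "ymin", as.character(as.integer(annotations$ymin[i] + 1)))
    xml2::xml_add_child(bb, "xmax", as.character(as.integer(annotations$xmax[i])))
    xml2::xml_add_child(bb, "ymax", as.character(as.integer(annotations$ymax[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read every annotation file of a dataset manifest
#'
#' @param manifest Tibble with columns `image_path`, `annotation_path` and
#'   optionally `split`.
#' @param n_species Size of the species vocabulary.
#' @return One tibble of annotations, row-bound over files, with the
#'   manifest's `split` carried along when present.
#' @export
read_manifest_annotations <- function(manifest, n_species = 200L) {
  anns <- purrr::map(seq_len(nrow(manifest)), function(i) {
    a <- read_voc_xml(manifest$annotation_path[i], n_species = n_species)
    if ("split" %in% names(manifest)) a$split <- manifest$split[i]
    a
  })
  dplyr::bind_rows(anns)
}

#' Write a train/test manifest file
#'
#' Plain TSV with columns `image_path`, `annotation_path`, `split`.
#'
#' @param manifest Tibble as in [read_manifest_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a manifest file written by [write_manifest()]
#' @param path Manifest TSV path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
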