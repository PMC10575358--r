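# Synthetic fixtures with the statistical structure the method assumes:
# schematic "birds" whose four part glyphs encode the species (for detector
# training/evaluation), and part-record tables with planted per-part
# informativeness (for the fusion weight search).

#' Distinct species colours for synthetic scenes
#'
#' Fully saturated hues, equally spaced, so distinct species have distinct
#' glyph colours (the separability guarantee) and stay far from the
#' achromatic background clutter.
#'
#' @param n_species Number of species.
#' @return `n_species x 3` matrix of RGB values in 0-255.
#' @export
species_palette <- function(n_species) {
  t(grDevices::col2rgb(grDevices::hsv((seq_len(n_species) - 1) / n_species, 1, 1)))
}

glyph_mask <- function(part, w, h) {
  xg <- matrix(rep((seq_len(w) - 0.5) / w, each = h), h, w)
  yg <- matrix(rep((seq_len(h) - 0.5) / h, times = w), h, w)
  switch(part,
    head = (xg - 0.5)^2 + (yg - 0.5)^2 <= 0.25,
    leftwing = abs(yg - 0.5) <= xg / 2,
    rightwing = abs(yg - 0.5) <= (1 - xg) / 2,
    tail = matrix(TRUE, h, w)
  )
}

#' Generate synthetic part-annotated bird scenes
#'
#' Each image holds one schematic bird: up to four non-overlapping part
#' glyphs (head = disc, left wing = left-pointing triangle, right wing =
#' right-pointing triangle, tail = bar), all filled with the species' colour
#' from [species_palette()], on a dark noisy background with achromatic
#' clutter rectangles. Bounding boxes are tight around the glyphs. Each part
#' is independently omitted with probability `occlusion_prob`. Deterministic
#' given `seed`.
#'
#' @param n_images Number of scenes.
#' @param n_species Number of species (>= 2, <= 200).
#' @param canvas_size Square canvas edge in pixels, divisible by 32
#'   (default 160).
#' @param occlusion_prob Per-part omission probability (default 0.1).
#' @param clutter Number of background clutter rectangles (default 6).
#' @param glyph_range Min/max glyph edge in pixels (default c(14, 44)).
#' @param seed RNG seed.
#' @param id_prefix Prefix for image ids.
#' @return A list with `images` (named list of `H x W x 3` arrays, 0-255),
#'   `annotations` (tibble in the [read_voc_xml()] layout), `truth`
#'   (tibble `image_id`, `species_id`), `n_species`, `canvas_size`.
#' @export
generate_scenes <- function(n_images, n_species = 8L, canvas_size = 160L,
                            occlusion_prob = 0.1, clutter = 6L,
                            glyph_range = c(14, 44), seed = 1L,
                            id_prefix = "scene") {
  stopifnot(n_species >= 2L, n_species <= 200L)
  if (canvas_size < 2 * (max(glyph_range) + 4)) {
    stop("canvas too small for the configured glyph sizes", call. = FALSE)
  }
  set.seed(seed)
  pal <- species_palette(n_species)
  cs <- as.integer(canvas_size)
  half <- cs %/% 2L
  images <- vector("list", n_images)
  anns <- vector("list", n_images)
  truth_sp <- integer(n_images)
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n_images))
  for (i in seq_len(n_images)) {
    sp <- sample.int(n_species, 1L)
    truth_sp[i] <- sp
    img <- array(40 + stats::runif(cs * cs * 3, -10, 10), c(cs, cs, 3L))
    for (cl in seq_len(clutter)) {
      cw <- sample(8:40, 1L); chh <- sample(8:40, 1L)
      cx <- sample.int(cs - cw, 1L); cy <- sample.int(cs - chh, 1L)
      img[cy + seq_len(chh), cx + seq_len(cw), ] <- stats::runif(1, 70, 170)
    }
    quadrants <- sample(list(c(0L, 0L), c(half, 0L), c(0L, half), c(half, half)))
    rows <- list()
    for (pi in seq_along(part_types())) {
      if (stats::runif(1) < occlusion_prob) next
      part <- part_types()[pi]
      w <- if (part == "tail") {
        round(stats::runif(1, max(20, glyph_range[1]), glyph_range[2]))
      } else {
        round(stats::runif(1, glyph_range[1], glyph_range[2]))
      }
      h <- if (part == "tail") {
        round(stats::runif(1, 8, w * 0.5))
      } else if (part == "head") {
        w
      } else {
        round(stats::runif(1, glyph_range[1], glyph_range[2]))
      }
      q <- quadrants[[pi]]
      margin <- 2L
      x0 <- q[1] + sample.int(half - w - 2L * margin, 1L) + margin
      y0 <- q[2] + sample.int(half - h - 2L * margin, 1L) + margin
      mask <- glyph_mask(part, w, h)
      for (ch in 1:3) {
        sub <- img[y0 + seq_len(h), x0 + seq_len(w), ch]
        sub[mask] <- pal[sp, ch]
        img[y0 + seq_len(h), x0 + seq_len(w), ch] <- sub
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_id = ids[i], part = part, species_id = sp,
        class_id = encode_class(sp, part, n_species = n_species),
        xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h,
        width = cs, height = cs
      )
    }
    images[[i]] <- img
    anns[[i]] <- dplyr::bind_rows(rows)
  }
  names(images) <- ids
  list(
    images = images,
    annotations = dplyr::bind_rows(anns),
    truth = tibble::tibble(image_id = ids, species_id = truth_sp),
    n_species = as.integer(n_species),
    canvas_size = cs
  )
}

#' Write a scene set to a VOC-layout directory
#'
#' Creates `JPEGImages/` (PNG files), `Annotations/` (VOC XML), a manifest
#' TSV and a `truth.csv`.
#'
#' @param scenes A scene set from [generate_scenes()].
#' @param dir Output directory (created if needed).
#' @param split Split label written into the manifest (default "train").
#' @return The manifest tibble, invisibly.
#' @export
write_scenes <- function(scenes, dir, split = "train") {
  img_dir <- file.path(dir, "JPEGImages")
  ann_dir <- file.path(dir, "Annotations")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(scenes$images)
  ann_by_img <- split(scenes$annotations, scenes$annotations$image_id)
  rows <- purrr::map(ids, function(id) {
    ip <- file.path(img_dir, paste0(id, ".png"))
    ap <- file.path(ann_dir, paste0(id, ".xml"))
    png::writePNG(scenes$images[[id]] / 255, ip)
    a <- ann_by_img[[id]]
    if (is.null(a)) a <- scenes$annotations[0, ]
    write_voc_xml(a, list(width = scenes$canvas_size,
                          height = scenes$canvas_size, depth = 3L),
                  ap, image_id = id)
    tibble::tibble(image_path = ip, annotation_path = ap, split = split)
  })
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  utils::write.csv(scenes$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a scene directory written by [write_scenes()]
#' @param dir Directory holding `JPEGImages/`, `Annotations/`, `manifest.tsv`.
#' @param n_species Species vocabulary size of the scene set.
#' @return A scene list as from [generate_scenes()] (without `truth` if no
#'   `truth.csv` is present).
#' @export
read_scenes <- function(dir, n_species) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  images <- lapply(manifest$image_path, function(p) png::readPNG(p) * 255)
  names(images) <- sub("\\.png$", "", basename(manifest$image_path))
  anns <- read_manifest_annotations(manifest, n_species = n_species)
  out <- list(images = images, annotations = anns,
              n_species = as.integer(n_species),
              canvas_size = dim(images[[1]])[1])
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) {
    out$truth <- tibble::as_tibble(utils::read.csv(tp, stringsAsFactors = FALSE))
  }
  out
}

#' Species of a glyph crop by nearest colour template
#'
#' The construction-level classifier used to certify scene separability:
#' saturated pixels inside the box are averaged and matched to the nearest
#' palette colour.
#'
#' @param image `H x W x 3` array, 0-255.
#' @param box Numeric `(xmin, ymin, xmax, ymax)`, 0-based half-open.
#' @param n_species Palette size.
#' @return The inferred `species_id`.
#' @export
nearest_template_species <- function(image, box, n_species) {
  xs <- (floor(box[1]) + 1):ceiling(box[3])
  ys <- (floor(box[2]) + 1):ceiling(box[4])
  crop <- image[ys, xs, , drop = FALSE]
  m <- matrix(crop, ncol = 3L)
  sat <- apply(m, 1L, max) - apply(m, 1L, min)
  sel <- m[sat > 60, , drop = FALSE]
  if (nrow(sel) == 0L) sel <- m
  mu <- colMeans(sel)
  pal <- species_palette(n_species)
  which.min(colSums((t(pal) - mu)^2))
}

#' Generate a part-record table with planted per-part informativeness
#'
#' Emulates the output of a part detector on a labelled validation split:
#' for each image, each part survives with probability `1 - dropout`; a
#' surviving record names the true species with its part's correctness
#' probability `p_part`, else a uniformly drawn wrong species. Confidence is
#' Beta(8, 2)-distributed for correct records and Beta(2, 4) for incorrect
#' ones, making confidence informative, as the weighted vote assumes.
#' The default `p_part` plants a strongly informative head, moderately
#' informative wings and a weak tail. Deterministic given `seed`.
#'
#' @param n_images Number of images.
#' @param n_species Species vocabulary size (default 200).
#' @param p_part Per-part correctness probabilities, order
#'   head/leftwing/rightwing/tail (default `c(0.95, 0.5, 0.5, 0.3)`).
#' @param dropout Per-part missing-record probability (default 0.1).
#' @param conf_correct,conf_incorrect Beta shape pairs for the confidence
#'   draws.
#' @param seed RNG seed.
#' @param id_prefix Image-id prefix.
#' @return A list with `records` (tibble `image_id`, `part`, `species_id`,
#'   `confidence`, at most one row per (image, part)) and `truth` (tibble
#'   `image_id`, `species_id`).
#' @export
generate_detection_table <- function(n_images, n_species = 200L,
                                     p_part = c(0.95, 0.5, 0.5, 0.3),
                                     dropout = 0.1,
                                     conf_correct = c(8, 2),
                                     conf_incorrect = c(2, 4),
                                     seed = 1L, id_prefix = "img") {
  stopifnot(length(p_part) == 4L, all(p_part >= 0), all(p_part <= 1),
            dropout >= 0, dropout <= 1)
  set.seed(seed)
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n_images))
  truth <- tibble::tibble(image_id = ids,
                          species_id = sample.int(n_species, n_images,
                                                  replace = TRUE))
  rows <- vector("list", 4L)
  for (pi in 1:4) {
    part <- part_types()[pi]
    survive <- stats::runif(n_images) >= dropout
    n_s <- sum(survive)
    if (n_s == 0L) next
    correct <- stats::runif(n_s) < p_part[pi]
    sp <- truth$species_id[survive]
    wrong <- vapply(sp[!correct], function(s) {
      sample(setdiff(seq_len(n_species), s), 1L)
    }, integer(1))
    sp[!correct] <- wrong
    conf <- numeric(n_s)
    conf[correct] <- stats::rbeta(sum(correct), conf_correct[1], conf_correct[2])
    conf[!correct] <- stats::rbeta(sum(!correct), conf_incorrect[1],
                                   conf_incorrect[2])
    rows[[pi]] <- tibble::tibble(
      image_id = ids[survive], part = part, species_id = sp,
      confidence = conf, correct = correct
    )
  }
  records <- dplyr::arrange(dplyr::bind_rows(rows), .data$image_id, .data$part)
  list(records = records, truth = truth)
}
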