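#' Horizontal flip of an image and its part boxes
#'
#' Mirrors the image about the vertical axis and maps every box
#' `(xmin, ymin, xmax, ymax)` to `(W - xmax, ymin, W - xmin, ymax)` (0-based
#' half-open coordinates, `W` the image width). Because a mirrored left wing
#' looks like a right wing, the wing labels (and their class ids) are swapped
#' by default; disable with `swap_wings = FALSE`.
#'
#' @param image Numeric array `H x W x 3` on the 0-255 scale.
#' @param annotations Tibble of part boxes as returned by [read_voc_xml()];
#'   may be missing/NULL to flip the image alone.
#' @param swap_wings Exchange leftwing/rightwing labels on flip (default TRUE).
#' @param n_species Species vocabulary size for re-encoding class ids.
#' @return A list with elements `image` and `annotations`.
#' @export
hflip <- function(image, annotations = NULL, swap_wings = TRUE, n_species = 200L) {
  W <- dim(image)[2]
  flipped <- image[, W:1, , drop = FALSE]
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- annotations
    new_xmin <- W - ann$xmax
    new_xmax <- W - ann$xmin
    ann$xmin <- new_xmin
    ann$xmax <- new_xmax
    if (swap_wings) {
      ann$part <- dplyr::case_match(ann$part,
        "leftwing" ~ "rightwing",
        "rightwing" ~ "leftwing",
        .default = ann$part
      )
      ann$class_id <- encode_class(ann$species_id, ann$part, n_species = n_species)
    }
    annotations <- ann
  }
  list(image = flipped, annotations = annotations)
}

#' Multiplicative brightness adjustment
#'
#' Each pixel value `v` becomes `min(max(v * factor, 0), 255)`. Boxes are
#' unaffected by a photometric transform, so none are taken or returned.
#'
#' @param image Numeric array on the 0-255 scale.
#' @param factor Positive gain; values > 1 brighten.
#' @return Adjusted image, same shape.
#' @export
adjust_brightness <- function(image, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  pmin(pmax(image * factor, 0), 255)
}

#' Additive Gaussian pixel noise
#'
#' Adds i.i.d. `Normal(0, sigma^2)` noise to every pixel and channel, then
#' clips to `[0, 255]`. Deterministic given `(image, sigma, seed)`: the draw
#' uses a local RNG state that does not disturb the caller's.
#'
#' @param image Numeric array on the 0-255 scale.
#' @param sigma Noise standard deviation in pixel-intensity units (default 10).
#' @param seed Integer seed for the noise draw.
#' @return Noisy image, same shape.
#' @export
add_gaussian_noise <- function(image, sigma = 10, seed = 0L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(image)
  noisy <- with_local_seed(seed, image + stats::rnorm(length(image), sd = sigma))
  dim(noisy) <- dim(image)
  pmin(pmax(noisy, 0), 255)
}

# Run expr under a temporary RNG state; restores the caller's state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Expand a training set with the three photometric/geometric augmentations
#'
#' Produces one horizontally flipped, one brightened and one noised copy of
#' the input scene (the augmentation scheme used for training-split images),
#' each with consistent annotations.
#'
#' @param image Numeric array `H x W x 3`, 0-255.
#' @param annotations Tibble of part boxes for the image.
#' @param config List of options: `brightness_factor` (default 1.5),
#'   `noise_sigma` (default 10), `seed` (default 0), `swap_wings_on_flip`
#'   (default TRUE).
#' @param n_species Species vocabulary size.
#' @return A list of `list(image, annotations, tag)` entries, tags
#'   `"hflip"`, `"bright"`, `"noise"`.
#' @export
augment_scene <- function(image, annotations, config = list(), n_species = 200L) {
  cfg <- utils::modifyList(
    list(brightness_factor = 1.5, noise_sigma = 10, seed = 0L,
         swap_wings_on_flip = TRUE),
    config
  )
  stopifnot(cfg$brightness_factor > 0, cfg$noise_sigma >= 0)
  fl <- hflip(image, annotations, swap_wings = cfg$swap_wings_on_flip,
              n_species = n_species)
  list(
    list(image = fl$image, annotations = fl$annotations, tag = "hflip"),
    list(image = adjust_brightness(image, cfg$brightness_factor),
         annotations = annotations, tag = "bright"),
    list(image = add_gaussian_noise(image, cfg$noise_sigma, cfg$seed),
         annotations = annotations, tag = "noise")
  )
}
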