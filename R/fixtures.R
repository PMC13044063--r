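#' Generate one synthetic garlic-like image
#'
#' Draws a bright, clove-ridged elliptical bulb on a near-black background
#' (emulating produce photographed on dark cloth) and, for the damaged
#' classes, a class-specific damage patch: a brown abrasion on the upper bulb
#' body for `local_damage`, or a grayish rot band anchored at the bulb base
#' for `root_damage`. Damage patches perturb both colour and intensity so the
#' three classes are separable by simple channel statistics, which lets small
#' networks learn them quickly. The rendered geometry (bulb and damage
#' bounding boxes, 0-based half-open) is returned as ground truth for
#' segmentation and Grad-CAM checks. Fully determined by `seed`.
#'
#' @param class_label One of `"local_damage"`, `"root_damage"`, `"normal"`.
#' @param image_size Square image side in pixels (>= 64), default 224.
#' @param seed Integer seed; the image is a pure function of it.
#' @param noise_sigma Gaussian pixel noise s.d. in \[0, 1\] units, default 0.01.
#' @return A `garlic_fixture`: list with `image` (H x W x 3 in \[0, 1\]),
#'   `label`, `bulb_bbox`, `damage_bbox` (`NULL` for normal), and the
#'   generating parameters.
#' @examples
#' fx <- generate_garlic_image("local_damage", image_size = 64, seed = 3)
#' fx$bulb_bbox
#' @export
generate_garlic_image <- function(class_label = c("normal", "local_damage", "root_damage"),
                                  image_size = 224L, seed = 1L,
                                  noise_sigma = 0.01) {
  class_label <- match.arg(class_label)
  if (image_size < 64) {
    abort("`image_size` must be at least 64.", class = "garlicnet_error_param")
  }
  n <- as.integer(image_size)
  set.seed(seed)

  rr <- matrix(seq_len(n), n, n)          # row index grid
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)

  # bulb geometry: ellipse near the centre, slightly taller than wide
  cy <- n / 2 + runif(1, -0.04, 0.04) * n
  cx <- n / 2 + runif(1, -0.04, 0.04) * n
  ry <- runif(1, 0.28, 0.34) * n
  rx <- runif(1, 0.24, 0.30) * n
  d2 <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2
  bulb <- d2 <= 1

  # clove ridges: radial intensity modulation, plus edge falloff
  theta <- atan2(cc - cx, rr - cy)
  n_cloves <- sample(6:9, 1)
  ridges <- 1 - 0.12 * abs(sin(n_cloves / 2 * theta))
  falloff <- 1 - 0.25 * pmax(d2, 0)
  base_int <- runif(1, 0.75, 0.9)
  bulb_shade <- base_int * ridges * falloff

  tint <- c(1.0, 0.94, 0.84)  # warm off-white skin
  img <- array(0.02, dim = c(n, n, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bulb] <- (bulb_shade * tint[ch])[bulb]
    img[, , ch] <- plane
  }

  damage_bbox <- NULL
  damage <- NULL
  if (class_label == "local_damage") {
    # brown abrasion on the upper bulb body
    ang <- runif(1, -pi / 3, pi / 3)
    py <- cy - 0.4 * ry * cos(ang)
    px <- cx + 0.4 * rx * sin(ang)
    pr_y <- runif(1, 0.30, 0.40) * ry
    pr_x <- runif(1, 0.30, 0.40) * rx
    damage <- (((rr - py) / pr_y)^2 + ((cc - px) / pr_x)^2 <= 1) & bulb
    dam_col <- c(0.58, 0.30, 0.10)
  } else if (class_label == "root_damage") {
    # blue-gray rot band anchored at the bulb base (bottom of the ellipse)
    py <- cy + 0.7 * ry
    pr_y <- runif(1, 0.28, 0.36) * ry
    pr_x <- runif(1, 0.65, 0.80) * rx
    damage <- (((rr - py) / pr_y)^2 + ((cc - cx) / pr_x)^2 <= 1) & bulb
    dam_col <- c(0.30, 0.36, 0.60)
  }
  if (!is.null(damage) && any(damage)) {
    mottle <- 1 + 0.15 * sin(rr / 2) * cos(cc / 2)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[damage] <- (dam_col[ch] * mottle)[damage]
      img[, , ch] <- plane
    }
    idx <- which(damage, arr.ind = TRUE)
    damage_bbox <- c(row_min = min(idx[, 1]) - 1L, col_min = min(idx[, 2]) - 1L,
                     row_max = max(idx[, 1]), col_max = max(idx[, 2]))
  }

  img <- img + array(rnorm(n * n * 3, 0, noise_sigma), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)
  # keep the background safely below the 0.3 threshold
  bg <- !bulb
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bg] <- pmin(plane[bg], 0.05)
    img[, , ch] <- plane
  }

  idx <- which(bulb, arr.ind = TRUE)
  bulb_bbox <- c(row_min = min(idx[, 1]) - 1L, col_min = min(idx[, 2]) - 1L,
                 row_max = max(idx[, 1]), col_max = max(idx[, 2]))

  structure(
    list(image = img, label = class_label,
         bulb_bbox = as.integer(bulb_bbox) |> setNames(names(bulb_bbox)),
         damage_bbox = if (!is.null(damage_bbox))
           as.integer(damage_bbox) |> setNames(names(damage_bbox)),
         image_size = n, seed = as.integer(seed), noise_sigma = noise_sigma),
    class = "garlic_fixture"
  )
}

garlic_classes <- function() c("local_damage", "root_damage", "normal")

#' Generate a balanced synthetic garlic dataset
#'
#' A tibble dataset of `3 * n_per_class` labeled synthetic images (see
#' [generate_garlic_image()]), balanced across the three classes, with
#' ground-truth bulb and damage geometry in manifest columns. Deterministic
#' for a fixed `seed`.
#'
#' @param n_per_class Images per class (>= 1).
#' @param image_size Square image side in pixels, default 224.
#' @param seed Master seed; per-image seeds are derived from it.
#' @return A tibble with columns `sample_id`, `class` (factor over the three
#'   labels), `image` (list-column of H x W x 3 arrays), `seed`, and
#'   ground-truth bbox columns `bulb_bbox`, `damage_bbox` (list-columns).
#' @examples
#' ds <- generate_garlic_dataset(2, image_size = 64, seed = 7)
#' dplyr::count(ds, class)
#' @export
generate_garlic_dataset <- function(n_per_class, image_size = 224L, seed = 1L) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  total <- 3L * n_per_class
  seeds <- sample.int(2^30, total)
  classes <- rep(garlic_classes(), each = n_per_class)
  fx <- purrr::map2(classes, seeds, function(cl, sd) {
    generate_garlic_image(cl, image_size = image_size, seed = sd)
  })
  tibble::tibble(
    sample_id = sprintf("%s_%04d", classes, sequence(rep(n_per_class, 3L))),
    class = factor(classes, levels = garlic_classes()),
    image = purrr::map(fx, "image"),
    seed = seeds,
    bulb_bbox = purrr::map(fx, "bulb_bbox"),
    damage_bbox = purrr::map(fx, "damage_bbox")
  )
}

#' Write a dataset to a class-folder image tree
#'
#' Writes each image as a PNG under `root/<class>/<sample_id>.png` and a
#' `manifest.csv` of sample ids, classes and ground-truth bounding boxes.
#'
#' @param dataset A tibble from [generate_garlic_dataset()] (or any tibble
#'   with `sample_id`, `class`, `image` columns).
#' @param root Output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_image_folder <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (cl in levels(dataset$class)) {
    dir.create(file.path(root, cl), showWarnings = FALSE)
  }
  for (i in seq_len(nrow(dataset))) {
    path <- file.path(root, as.character(dataset$class[i]),
                      paste0(dataset$sample_id[i], ".png"))
    write_image(dataset$image[[i]], path)
  }
  fmt_bbox <- function(b) if (is.null(b)) NA_character_ else paste(b, collapse = ";")
  manifest <- tibble::tibble(
    sample_id = dataset$sample_id,
    class = as.character(dataset$class),
    bulb_bbox = purrr::map_chr(dataset$bulb_bbox %||% rep(list(NULL), nrow(dataset)), fmt_bbox),
    damage_bbox = purrr::map_chr(dataset$damage_bbox %||% rep(list(NULL), nrow(dataset)), fmt_bbox)
  )
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(root)
}
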