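#' Deterministic offline dataset augmentation
#'
#' Expands every original image to `factor` images: the original itself plus
#' `factor - 1` transformed copies, alternating additive Gaussian noise
#' (sigma 0.02 in \[0, 1\] units, clipped) and random rotation (uniform in
#' \[-30, +30\] degrees, black padding consistent with the dark-cloth
#' background). With the default `factor = 3` each original contributes one
#' noise-injected and one rotated copy, so per-class counts triple exactly
#' (95 originals become 285, 296 become 888). Label-preserving and fully
#' deterministic for a fixed `seed`; each output row records its `origin_id`
#' so splits can keep all copies of one original together.
#'
#' @param dataset Tibble with `sample_id`, `class` and `image` columns (see
#'   [generate_garlic_dataset()] or [load_image_folder()]).
#' @param factor Expansion factor (>= 1); 1 returns the dataset unchanged
#'   (plus an `origin_id` column).
#' @param seed Integer seed.
#' @param noise_sigma Gaussian noise s.d., default 0.02.
#' @param max_angle Rotation half-range in degrees, default 30.
#' @return Tibble with `factor` times the rows per class and an added
#'   `origin_id` column.
#' @export
augment_dataset <- function(dataset, factor = 3L, seed = 1L,
                            noise_sigma = 0.02, max_angle = 30) {
  stopifnot(factor >= 1)
  if (nrow(dataset) == 0) {
    abort("Cannot augment an empty dataset.", class = "garlicnet_error_param")
  }
  base <- dataset
  base$origin_id <- base$sample_id
  if (factor == 1L) return(base)
  set.seed(seed)
  copies <- list(base)
  for (j in seq_len(factor - 1L)) {
    kind <- if (j %% 2L == 1L) "noise" else "rot"
    cp <- dataset
    cp$origin_id <- dataset$sample_id
    cp$sample_id <- paste0(dataset$sample_id, "_", kind, j)
    cp$image <- purrr::map(dataset$image, function(img) {
      if (kind == "noise") {
        pmin(pmax(img + array(rnorm(length(img), 0, noise_sigma), dim = dim(img)), 0), 1)
      } else {
        rotate_image(img, runif(1, -max_angle, max_angle))
      }
    })
    copies[[j + 1L]] <- cp
  }
  out <- dplyr::bind_rows(copies)
  dplyr::arrange(out, .data$origin_id, .data$sample_id)
}

# Rotate about the centre, keeping the original canvas, black padding.
rotate_image <- function(img, angle) {
  d <- dim(img)
  out <- EBImage::rotate(img, angle, output.dim = c(d[1], d[2]), bg.col = 0)
  out <- pmin(pmax(as.numeric(out), 0), 1)
  dim(out) <- d
  out
}

#' 6:2:2 split arithmetic
#'
#' Train count is `round(0.6 n)`; the remainder is apportioned between
#' validation and test by largest remainder against their 0.2 quotas, with
#' ties broken toward test. The three counts always sum to `n`; e.g. 285 maps
#' to (171, 57, 57) and 888 maps to a train count of 533.
#'
#' @param n Number of items (>= 5).
#' @param ratios Split ratios, fixed default `c(0.6, 0.2, 0.2)`.
#' @return Named integer vector `c(train, val, test)`.
#' @examples
#' split_622(285)  # 171 57 57
#' split_622(10)   # 6 2 2
#' @export
split_622 <- function(n, ratios = c(0.6, 0.2, 0.2)) {
  if (n < 5) abort("`n` must be at least 5.", class = "garlicnet_error_param")
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  n_train <- as.integer(round(ratios[1] * n))
  m <- n - n_train
  q_val <- ratios[2] / (ratios[2] + ratios[3]) * m
  n_val <- as.integer(floor(q_val))
  n_test <- as.integer(floor(m - q_val))
  left <- m - n_val - n_test
  if (left > 0) {
    rem_val <- q_val - n_val
    rem_test <- (m - q_val) - n_test
    # largest remainder; ties go to test
    if (rem_val > rem_test) n_val <- n_val + left else n_test <- n_test + left
  }
  c(train = n_train, val = as.integer(n_val), test = as.integer(n_test))
}

#' Stratified train/validation/test split plan
#'
#' Assigns every row of a dataset to train/val/test with per-class 6:2:2
#' arithmetic ([split_622()]). When the dataset carries an `origin_id` column
#' (from [augment_dataset()]) all copies of one original are kept in the same
#' partition by default, avoiding augmentation leakage across partitions;
#' `split_after_augment = TRUE` instead splits the expanded rows directly,
#' reproducing the post-augmentation bookkeeping of fixed published counts.
#'
#' @param dataset Tibble with a `class` column (and optionally `origin_id`).
#' @param seed Integer seed for the within-class shuffle.
#' @param split_after_augment Logical; ignore `origin_id` grouping.
#' @return The dataset with an added `partition` factor column
#'   (train/val/test).
#' @export
split_plan <- function(dataset, seed = 1L, split_after_augment = FALSE) {
  set.seed(seed)
  has_origin <- "origin_id" %in% names(dataset) && !split_after_augment
  dataset$partition <- factor(NA, levels = c("train", "val", "test"))
  for (cl in levels(factor(dataset$class))) {
    in_class <- which(dataset$class == cl)
    if (has_origin) {
      origins <- unique(dataset$origin_id[in_class])
      origins <- sample(origins)
      cnt <- split_622(length(origins))
      part <- rep(c("train", "val", "test"), times = cnt)
      names(part) <- origins
      dataset$partition[in_class] <- part[dataset$origin_id[in_class]]
    } else {
      idx <- sample(in_class)
      cnt <- split_622(length(idx))
      dataset$partition[idx] <- rep(c("train", "val", "test"), times = cnt)
    }
  }
  dataset
}

#' Stratified k-fold partition
#'
#' Partitions indices into `k` folds of sizes differing by at most one,
#' stratified by class when `x` is a dataset with a `class` column. Returns
#' the standard cross-validation pairing: for each fold, the held-out
#' validation indices and the remaining training indices.
#'
#' @param x Either a single integer `n` (unstratified) or a tibble with a
#'   `class` column.
#' @param k Number of folds, default 5.
#' @param seed Integer seed.
#' @return List of `k` lists, each with `train_idx` and `val_idx`.
#' @export
kfold <- function(x, k = 5L, seed = 1L) {
  set.seed(seed)
  if (is.numeric(x) && length(x) == 1) {
    n <- as.integer(x)
    if (n < k) abort("`n` must be at least `k`.", class = "garlicnet_error_param")
    fold_of <- sample(rep_len(seq_len(k), n))
  } else {
    n <- nrow(x)
    if (n < k) abort("Need at least `k` rows.", class = "garlicnet_error_param")
    fold_of <- integer(n)
    # walk classes through a single global fold cycle so sizes stay within
    # one of each other both per class and overall
    ordered <- unlist(lapply(levels(factor(x$class)),
                             function(cl) sample(which(x$class == cl))))
    fold_of[ordered] <- rep_len(seq_len(k), n)
  }
  purrr::map(seq_len(k), function(f) {
    list(train_idx = which(fold_of != f), val_idx = which(fold_of == f))
  })
}
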