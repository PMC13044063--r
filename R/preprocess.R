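#' Convert an RGB image to grayscale
#'
#' Luminance-weighted channel combination with the Rec.601 luma weights
#' (0.299, 0.587, 0.114), the standard convention in image-processing
#' libraries.
#'
#' @param image H x W x 3 numeric array with values in \[0, 1\].
#' @return H x W numeric matrix in \[0, 1\].
#' @export
to_grayscale <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be an H x W x 3 array.", class = "garlicnet_error_dims")
  }
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Threshold a grayscale image into a binary mask
#'
#' Pixels below `threshold` become 0 (background), pixels at or above it
#' become 1 (foreground). The fixed default of 0.3 sits in the trough of the
#' bimodal gray histogram produced by bright garlic bulbs on a black-cloth
#' background. Exact equality maps to foreground (half-open convention).
#'
#' @param gray H x W numeric matrix in \[0, 1\].
#' @param threshold Cutoff in the open interval (0, 1); default 0.3.
#' @return H x W matrix with values exactly 0 or 1.
#' @export
binarize <- function(gray, threshold = 0.3) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1).",
          class = "garlicnet_error_param")
  }
  mask <- (gray >= threshold) * 1
  dim(mask) <- dim(gray)
  mask
}

#' Apply a binary mask to an image
#'
#' Per-channel pixelwise product: foreground pixels keep their original
#' values, background pixels become exactly 0 (black).
#'
#' @param image H x W x 3 numeric array.
#' @param mask H x W binary matrix from [binarize()].
#' @return Masked H x W x 3 array.
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (length(d) != 3 || !identical(d[1:2], dim(mask))) {
    abort("`image` (H x W x 3) and `mask` (H x W) must agree in H and W.",
          class = "garlicnet_error_dims")
  }
  image * array(mask, dim = d)
}

# 8-connected labeling: 4-connected components from EBImage::bwlabel, then
# merge labels that touch diagonally (union-find on the small label graph).
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Isolate the largest foreground component
#'
#' Labels the mask's 8-connected components, keeps only the largest one
#' (removing all others from both mask and masked image), traces its oriented
#' boundary contour, and computes the tight bounding box. Coordinates are
#' 0-based; the bounding box is half-open `(row_min, col_min, row_max,
#' col_max)`.
#'
#' @param masked H x W x 3 masked image (background already 0).
#' @param mask H x W binary mask with at least one foreground pixel.
#' @return A `segmentation_result`: list with `masked_image`, `mask`, `bbox`,
#'   `contour` (ordered 0-based (row, col) boundary coordinates) and
#'   `n_foreground`.
#' @export
extract_target <- function(masked, mask) {
  if (!any(mask > 0)) {
    abort("Mask has no foreground pixels (nothing above threshold).",
          class = "garlicnet_error_no_foreground")
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  largest <- which.max(sizes)  # ties -> smallest label, deterministic
  keep <- lab == largest
  new_mask <- keep * 1
  dim(new_mask) <- dim(mask)
  contour <- EBImage::ocontour(keep * 1L)[[1]]
  rows <- which(keep, arr.ind = TRUE)
  bbox <- c(
    row_min = min(rows[, 1]) - 1L, col_min = min(rows[, 2]) - 1L,
    row_max = max(rows[, 1]), col_max = max(rows[, 2])
  )
  structure(
    list(
      masked_image = apply_mask(masked, new_mask),
      mask = new_mask,
      bbox = as.integer(bbox) |> setNames(names(bbox)),
      contour = contour,
      n_foreground = sum(new_mask)
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d foreground px, bbox (%d,%d)-(%d,%d) [0-based, half-open]\n",
    x$n_foreground, x$bbox["row_min"], x$bbox["col_min"],
    x$bbox["row_max"], x$bbox["col_max"]
  ))
  invisible(x)
}

#' Segment a garlic bulb from a dark background
#'
#' The full threshold-based segmentation pipeline: grayscale conversion,
#' fixed-threshold binarization, pixelwise masking of the original image, and
#' extraction of the largest 8-connected foreground component with its contour
#' and bounding box.
#'
#' @param image H x W x 3 numeric array in \[0, 1\].
#' @param threshold Binarization cutoff, default 0.3.
#' @return A `segmentation_result` (see [extract_target()]).
#' @examples
#' img <- generate_garlic_image(class_label = "normal", image_size = 64, seed = 1)
#' seg <- segment(img$image)
#' seg$bbox
#' @export
segment <- function(image, threshold = 0.3) {
  gray <- to_grayscale(image)
  mask <- binarize(gray, threshold)
  masked <- apply_mask(image, mask)
  extract_target(masked, mask)
}

#' Crop a segmentation result for the classifier
#'
#' By default returns the tight bounding-box crop of the masked image, resized
#' to `size` x `size`; with `use_bbox = FALSE` the masked full frame is
#' resized instead.
#'
#' @param result A `segmentation_result` from [segment()].
#' @param size Output side in pixels, default 224.
#' @param use_bbox Crop to the bounding box before resizing (default `TRUE`).
#' @return `size` x `size` x 3 array in \[0, 1\].
#' @export
segment_crop <- function(result, size = 224L, use_bbox = TRUE) {
  stopifnot(inherits(result, "segmentation_result"))
  img <- result$masked_image
  if (use_bbox) {
    b <- result$bbox
    img <- img[(b["row_min"] + 1L):b["row_max"],
               (b["col_min"] + 1L):b["col_max"], , drop = FALSE]
  }
  out <- EBImage::resize(img, w = size, h = size)
  out <- pmin(pmax(as.numeric(out), 0), 1)
  dim(out) <- c(size, size, 3L)
  out
}
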