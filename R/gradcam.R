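#' Grad-CAM heatmap for one image
#'
#' Gradient-weighted class-activation mapping over the final convolutional
#' stage. The gradient of the target-class logit with respect to the feature
#' maps of the last residual block is spatially averaged into per-channel
#' weights (for the global-average-pool + linear head this gradient is the
#' head weight row divided by the feature map area); the rectified weighted
#' channel sum is bilinearly upsampled to the input size and min-max
#' normalized to \[0, 1\]. An identically-zero map is returned as zeros with a
#' warning.
#'
#' @param network A `garlic_network`.
#' @param image H x W x 3 array in \[0, 1\] (resized to the network input size
#'   internally).
#' @param target_class Integer class index in 1..num_classes, or a class name
#'   if the network carries `class_names`.
#' @param input_size Optional evaluation resolution. The network is fully
#'   convolutional up to its pooled head, so a model trained at one size can
#'   be evaluated at a larger one to obtain a finer attention map (e.g. 224
#'   gives a 7x7 map where 64 gives 2x2). Defaults to the network's training
#'   input size.
#' @return A `garlic_heatmap`: list with `values` (H x W in \[0, 1\], H = W =
#'   network input size), `weights` (per-channel), `target_class`, `image`
#'   (the resized input).
#' @export
grad_cam <- function(network, image, target_class = 1L, input_size = NULL) {
  if (is.character(target_class)) {
    if (is.null(network$class_names)) {
      abort("Network has no class names; give an integer `target_class`.",
            class = "garlicnet_error_param")
    }
    target_class <- match(target_class, network$class_names)
  }
  k <- network$spec$num_classes
  if (is.na(target_class) || target_class < 1 || target_class > k) {
    abort("`target_class` must be in 1..num_classes.",
          class = "garlicnet_error_param")
  }
  sz <- as.integer(input_size %||% network$spec$input_size)
  if (sz < 32) abort("`input_size` must be >= 32.", class = "garlicnet_error_param")
  x <- as_batch(list(image), sz)
  fw <- network_forward(network, x, train = FALSE)
  feats <- fw$features[, , , 1, drop = FALSE]       # h x w x C
  fd <- dim(feats)[1:3]
  dim(feats) <- fd
  # d logit / d feature, spatially averaged: head weight row / (h*w)
  weights <- network$params$fc$w[target_class, ] / (fd[1] * fd[2])
  fm <- feats
  dim(fm) <- c(fd[1] * fd[2], fd[3])
  cam <- matrix(pmax(fm %*% weights, 0), fd[1], fd[2])
  up <- EBImage::resize(cam, w = sz, h = sz)
  up <- matrix(pmax(as.numeric(up), 0), sz, sz)
  mx <- max(up)
  if (mx == 0) {
    warn("Grad-CAM map is identically zero for this class/input.")
  } else {
    up <- up / mx
  }
  structure(
    list(values = up, weights = weights, target_class = target_class,
         image = x[, , , 1]),
    class = "garlic_heatmap"
  )
}

#' Blend a heatmap over its source image
#'
#' Maps attention linearly from blue (low) to red (high) and alpha-blends it
#' over the resized input.
#'
#' @param heatmap A `garlic_heatmap` from [grad_cam()].
#' @param alpha Blend weight of the colormap, default 0.5.
#' @return H x W x 3 array in \[0, 1\].
#' @export
heatmap_overlay <- function(heatmap, alpha = 0.5) {
  v <- heatmap$values
  colmap <- array(0, dim = c(dim(v), 3L))
  colmap[, , 1] <- v          # red rises with attention
  colmap[, , 3] <- 1 - v      # blue falls with attention
  (1 - alpha) * heatmap$image + alpha * colmap
}

#' @export
print.garlic_heatmap <- function(x, ...) {
  cat(sprintf("<garlic_heatmap> %dx%d, target class %d, max %.3f\n",
              nrow(x$values), ncol(x$values), x$target_class, max(x$values)))
  invisible(x)
}

#' @describeIn grad_cam Raster plot of heatmap and overlay.
#' @param object A `garlic_heatmap`.
#' @param ... Unused.
#' @export
autoplot.garlic_heatmap <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$values)),
                    col = seq_len(ncol(object$values)))
  df$attention <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$attention)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Grad-CAM attention") +
    ggplot2::theme_minimal()
}

# Centroid (row, col) of the top-q fraction of heatmap mass; used to check
# that attention localizes on the known damage site of synthetic fixtures.
heatmap_top_centroid <- function(heatmap, q = 0.95) {
  v <- heatmap$values
  thr <- stats::quantile(v, q)
  sel <- v >= thr
  idx <- which(sel, arr.ind = TRUE)
  w <- v[sel]
  c(row = sum(idx[, 1] * w) / sum(w), col = sum(idx[, 2] * w) / sum(w))
}
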