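#' Build a runnable garlic classifier network
#'
#' Instantiates the architecture described by an [arch_spec()] (or variant
#' name) with freshly initialized weights: Kaiming fan-out normal for
#' convolutions, unit-gamma / zero-beta batch normalization and small-normal
#' linear layers. `zero_init_residual = TRUE` instead zero-initializes the
#' second batch-norm gamma of every block so each block starts as an identity
#' -- helpful for very long schedules, but it slows learning over the short
#' CPU-scale schedules this engine targets, so it is off by default.
#'
#' @param variant An [arch_spec()] or one of `"resnet34"`,
#'   `"resnet34_dwconv"`, `"dh_garlicnet"`.
#' @param num_classes Number of classes (used when `variant` is a name).
#' @param width Stem width (when `variant` is a name), default 64.
#' @param input_size Input side in pixels (when `variant` is a name).
#' @param seed Integer seed for weight initialization.
#' @param class_names Optional character vector of class labels attached to
#'   the network for prediction.
#' @param zero_init_residual Zero-initialize each block's second batch-norm
#'   gamma, default `FALSE`.
#' @return A `garlic_network`: list with `spec`, `params`, `state` (batch-norm
#'   running statistics) and `class_names`.
#' @examples
#' net <- build_model("dh_garlicnet", num_classes = 3, width = 8, input_size = 64)
#' @export
build_model <- function(variant = "resnet34", num_classes = 1000L,
                        width = 64L, input_size = 224L, seed = 1L,
                        class_names = NULL, zero_init_residual = FALSE) {
  spec <- if (inherits(variant, "arch_spec")) variant else {
    arch_spec(variant, num_classes = num_classes, width = width,
              input_size = input_size)
  }
  set.seed(seed)
  blocks <- arch_blocks(spec)

  kaiming <- function(c_out, fan_elems) {
    matrix(rnorm(c_out * fan_elems, 0, sqrt(2 / (fan_elems))), c_out, fan_elems)
  }
  init_conv <- function(cs) {
    if (cs$depthwise) {
      matrix(rnorm(cs$c_in * cs$k^2, 0, sqrt(2 / cs$k^2)), cs$c_in, cs$k^2)
    } else {
      # fan-out = K^2 * C_out
      matrix(rnorm(cs$c_out * cs$k^2 * cs$c_in, 0, sqrt(2 / (cs$k^2 * cs$c_out))),
             cs$c_out, cs$k^2 * cs$c_in)
    }
  }
  init_bn <- function(c, zero_gamma = FALSE) {
    list(gamma = if (zero_gamma) numeric(c) else rep(1, c), beta = numeric(c))
  }
  bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

  params <- list(
    stem = list(conv = init_conv(conv_spec(7L, 3L, spec$width, stride = 2L)),
                bn = init_bn(spec$width)),
    blocks = list(),
    fc = list(
      w = matrix(rnorm(spec$num_classes * spec$width * 8, 0,
                       sqrt(1 / (spec$width * 8))),
                 spec$num_classes, spec$width * 8),
      b = numeric(spec$num_classes)
    )
  )
  state <- list(stem_bn = bn_state(spec$width), blocks = list())
  flat_blocks <- unlist(blocks, recursive = FALSE)
  for (i in seq_along(flat_blocks)) {
    bs <- flat_blocks[[i]]
    c_out <- bs$conv1$c_out
    bp <- list(
      conv1 = init_conv(bs$conv1), bn1 = init_bn(c_out),
      conv2 = init_conv(bs$conv2),
      bn2 = init_bn(c_out, zero_gamma = zero_init_residual),
      proj = if (!is.null(bs$projection)) init_conv(bs$projection),
      proj_bn = if (!is.null(bs$projection)) init_bn(c_out),
      se = NULL
    )
    bst <- list(bn1 = bn_state(c_out), bn2 = bn_state(c_out),
                proj_bn = if (!is.null(bs$projection)) bn_state(c_out))
    if (bs$use_se) {
      hid <- se_hidden(c_out, bs$se_reduction)
      bp$se <- list(
        w1 = matrix(rnorm(hid * c_out, 0, sqrt(1 / c_out)), hid, c_out),
        b1 = numeric(hid),
        w2 = matrix(rnorm(c_out * hid, 0, sqrt(1 / hid)), c_out, hid),
        b2 = numeric(c_out)
      )
    }
    params$blocks[[i]] <- bp
    state$blocks[[i]] <- bst
  }
  structure(
    list(spec = spec, block_specs = flat_blocks, params = params,
         state = state, class_names = class_names),
    class = "garlic_network"
  )
}

#' @export
print.garlic_network <- function(x, ...) {
  cat(sprintf("<garlic_network> %s, %d classes, width %d, input %dx%d\n",
              x$spec$variant, x$spec$num_classes, x$spec$width,
              x$spec$input_size, x$spec$input_size))
  cat(sprintf("  %s trainable parameters\n",
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Count the trainable parameters of a built network
#'
#' Walks the instantiated weight tree and sums element counts; used to check
#' the closed-form accounting of [profile_arch()] against the real network.
#'
#' @param network A `garlic_network`.
#' @return Parameter count (double).
#' @export
count_params <- function(network) {
  total <- 0
  walk <- function(x) {
    if (is.numeric(x)) total <<- total + length(x)
    else if (is.list(x)) for (el in x) if (!is.null(el)) walk(el)
  }
  walk(network$params)
  total
}

#' Forward pass through a garlic network
#'
#' @param network A `garlic_network`.
#' @param x Input batch, array of shape (H, W, 3, N) with values in \[0, 1\].
#' @param train Logical; batch-norm uses batch statistics (and running
#'   statistics are updated) when `TRUE`, running statistics when `FALSE`.
#' @param keep_cache Logical; retain per-layer caches for a backward pass.
#' @return List with `logits` (num_classes x N), `features` (the pre-pooling
#'   output of the last residual block, H x W x C x N), updated `network`
#'   (running statistics), and `cache` when requested.
#' @export
network_forward <- function(network, x, train = FALSE, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != 3L) {
    abort("Input must have 3 channels.", class = "garlicnet_error_dims")
  }
  spec <- network$spec
  p <- network$params
  st <- network$state
  act <- get_activation(block_activation(spec))

  stem_spec <- conv_spec(7L, 3L, spec$width, stride = 2L)
  c0 <- conv_forward(x, p$stem$conv, stem_spec)
  b0 <- bn_forward(c0$out, p$stem$bn$gamma, p$stem$bn$beta, st$stem_bn, train)
  a0 <- act$f(b0$out)
  mp <- maxpool_forward(a0)
  h <- mp$out
  st$stem_bn <- b0$state

  caches <- if (keep_cache) list(stem_conv = c0$cache, stem_bn = b0$cache,
                                 stem_bnout = b0$out, maxpool = mp$cache)
  block_caches <- vector("list", length(network$block_specs))
  for (i in seq_along(network$block_specs)) {
    bf <- block_forward(h, p$blocks[[i]], st$blocks[[i]],
                        network$block_specs[[i]], train)
    h <- bf$out
    st$blocks[[i]] <- bf$state
    if (keep_cache) block_caches[[i]] <- bf$cache
  }
  features <- h
  g <- gap_forward(h)
  logits <- p$fc$w %*% g$out + p$fc$b
  network$state <- st
  out <- list(logits = logits, features = features, network = network)
  if (keep_cache) {
    caches$blocks <- block_caches
    caches$gap_dim <- g$cache
    caches$feat <- g$out
    out$cache <- caches
  }
  out
}

# Backward pass from dlogits; returns gradient tree mirroring params.
network_backward <- function(network, cache, dlogits) {
  p <- network$params
  spec <- network$spec
  act <- get_activation(block_activation(spec))
  grads <- list(fc = list(w = dlogits %*% t(cache$feat),
                          b = rowSums(dlogits)))
  dfeat <- crossprod(p$fc$w, dlogits)
  dh <- gap_backward(dfeat, cache$gap_dim)
  gblocks <- vector("list", length(network$block_specs))
  for (i in rev(seq_along(network$block_specs))) {
    bb <- block_backward(dh, p$blocks[[i]], network$block_specs[[i]],
                         cache$blocks[[i]])
    gblocks[[i]] <- bb$grads
    dh <- bb$dx
  }
  grads$blocks <- gblocks
  dmp <- maxpool_backward(dh, cache$maxpool)
  da0 <- dmp * act$grad(cache$stem_bnout)
  bb0 <- bn_backward(da0, p$stem$bn$gamma, cache$stem_bn)
  cb0 <- conv_backward(bb0$dx, p$stem$conv, cache$stem_conv)
  grads$stem <- list(conv = cb0$dw,
                     bn = list(gamma = bb0$dgamma, beta = bb0$dbeta))
  grads
}

# Softmax cross-entropy; truth is an integer vector in 1..K.
softmax_ce <- function(logits, truth) {
  n <- ncol(logits)
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  ez <- exp(z)
  sm <- ez / rep(colSums(ez), each = nrow(logits))
  picked <- sm[cbind(truth, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- sm
  dlogits[cbind(truth, seq_len(n))] <- dlogits[cbind(truth, seq_len(n))] - 1
  list(loss = loss, dlogits = dlogits / n, probs = sm)
}

# SGD with momentum over the parameter tree.
sgd_step <- function(params, grads, velocity, lr, momentum) {
  walk <- function(p, g, v) {
    if (is.numeric(p)) {
      if (is.null(v)) v <- 0 * p
      v <- momentum * v - lr * g
      list(p = p + v, v = v)
    } else if (is.list(p)) {
      vnew <- if (is.null(v)) vector("list", length(p)) else v
      nm <- names(p)
      for (k in seq_along(p)) {
        if (is.null(p[[k]])) next
        # match gradients by name where available (lists may differ in order)
        gk <- if (!is.null(nm) && nzchar(nm[k])) g[[nm[k]]] else g[[k]]
        if (is.null(gk)) next
        r <- walk(p[[k]], gk, if (length(vnew) >= k) vnew[[k]])
        p[[k]] <- r$p
        vnew[[k]] <- r$v
      }
      list(p = p, v = vnew)
    } else {
      list(p = p, v = v)
    }
  }
  walk(params, grads, velocity)
}

#' Predict classes or probabilities for images
#'
#' @param object A `garlic_network` (typically from [garlic_train()]).
#' @param newdata A dataset tibble with an `image` list-column, a single
#'   H x W x 3 array, or an (H, W, 3, N) batch array.
#' @param type `"class"`, `"prob"` or `"logits"`.
#' @param ... Unused.
#' @return Factor of classes, or a matrix (N x K) of probabilities / logits.
#' @export
predict.garlic_network <- function(object, newdata,
                                   type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  x <- as_batch(newdata, object$spec$input_size)
  fw <- network_forward(object, x, train = FALSE)
  logits <- t(fw$logits)
  cn <- object$class_names %||% paste0("class", seq_len(ncol(logits)))
  colnames(logits) <- cn
  if (type == "logits") return(logits)
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  if (type == "prob") return(probs)
  factor(cn[max.col(probs, ties.method = "first")], levels = cn)
}

# Convert datasets / arrays into an (H, W, 3, N) batch at the network's input
# size, resizing when needed.
as_batch <- function(newdata, input_size) {
  imgs <- if (is.data.frame(newdata)) newdata$image
          else if (is.list(newdata)) newdata
          else list(newdata)
  if (is.array(newdata) && length(dim(newdata)) == 4L) {
    imgs <- purrr::map(seq_len(dim(newdata)[4]), function(i) newdata[, , , i])
  }
  imgs <- purrr::map(imgs, function(im) {
    if (dim(im)[1] != input_size || dim(im)[2] != input_size) {
      out <- EBImage::resize(im, w = input_size, h = input_size)
      out <- pmin(pmax(as.numeric(out), 0), 1)
      dim(out) <- c(input_size, input_size, 3L)
      out
    } else im
  })
  x <- array(0, dim = c(input_size, input_size, 3L, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}
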