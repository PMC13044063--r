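#' Architecture specification for the garlic classifier family
#'
#' Describes a full network: a 7x7 stride-2 stem convolution with 3x3 stride-2
#' max pooling, four stages of basic residual blocks with the classic
#' (3, 4, 6, 3) plan at (1x, 2x, 4x, 8x) the stem width, then global average
#' pooling and a fully connected head. Four independent toggles select the
#' variants studied in the ablation grid:
#'
#' * `use_dwconv` -- the second 3x3 convolution of every basic block becomes
#'   depthwise (the lightweight substitution that halves parameters and MACs);
#' * `use_se` -- squeeze-and-excitation channel attention in every block;
#' * `use_silu` -- SiLU activation instead of ReLU throughout;
#' * `use_nested` -- parameter-free nested inner residual skip.
#'
#' Named variants: `"resnet34"` (all toggles off), `"resnet34_dwconv"`
#' (depthwise only; the profiling comparison pair), `"dh_garlicnet"` (all four
#' on), and `"custom"` (toggles taken as given).
#'
#' @param variant One of `"resnet34"`, `"resnet34_dwconv"`, `"dh_garlicnet"`,
#'   `"custom"`.
#' @param num_classes Number of output classes (>= 2). Profiling comparisons
#'   use the conventional 1000-way head; garlic training uses 3.
#' @param use_dwconv,use_se,use_silu,use_nested Logical toggles; ignored (and
#'   overridden) unless `variant = "custom"`.
#' @param width Stem width (channels out of the first convolution). 64 is the
#'   full-size network; smaller values give reduced-width networks for
#'   CPU-scale training.
#' @param input_size Input image side in pixels (square input), default 224.
#' @param se_reduction SE bottleneck reduction ratio, default 16.
#' @return An `arch_spec` object.
#' @examples
#' arch_spec("resnet34")
#' arch_spec("dh_garlicnet", num_classes = 3, width = 8, input_size = 64)
#' @export
arch_spec <- function(variant = c("resnet34", "resnet34_dwconv", "dh_garlicnet", "custom"),
                      num_classes = 1000L,
                      use_dwconv = FALSE, use_se = FALSE,
                      use_silu = FALSE, use_nested = FALSE,
                      width = 64L, input_size = 224L, se_reduction = 16L) {
  variant <- match.arg(variant)
  if (num_classes < 2) abort("`num_classes` must be at least 2.")
  if (width < 1 || input_size < 32) {
    abort("`width` must be >= 1 and `input_size` >= 32.")
  }
  toggles <- switch(variant,
    resnet34        = list(dw = FALSE, se = FALSE, silu = FALSE, nested = FALSE),
    resnet34_dwconv = list(dw = TRUE,  se = FALSE, silu = FALSE, nested = FALSE),
    dh_garlicnet    = list(dw = TRUE,  se = TRUE,  silu = TRUE,  nested = TRUE),
    custom          = list(dw = isTRUE(use_dwconv), se = isTRUE(use_se),
                           silu = isTRUE(use_silu), nested = isTRUE(use_nested))
  )
  structure(
    list(
      variant = variant,
      num_classes = as.integer(num_classes),
      use_dwconv = toggles$dw, use_se = toggles$se,
      use_silu = toggles$silu, use_nested = toggles$nested,
      width = as.integer(width), input_size = as.integer(input_size),
      se_reduction = as.integer(se_reduction),
      stage_blocks = c(3L, 4L, 6L, 3L),
      stage_mult = c(1L, 2L, 4L, 8L)
    ),
    class = "arch_spec"
  )
}

#' @export
print.arch_spec <- function(x, ...) {
  on <- c(dwconv = x$use_dwconv, se = x$use_se, silu = x$use_silu,
          nested = x$use_nested)
  cat(sprintf(
    "<arch_spec> %s: stem %d, stages (%s) blocks at (%s) channels, %d classes, input %dx%d\n",
    x$variant, x$width,
    paste(x$stage_blocks, collapse = ","),
    paste(x$width * x$stage_mult, collapse = ","),
    x$num_classes, x$input_size, x$input_size
  ))
  cat("  toggles on:", if (any(on)) paste(names(on)[on], collapse = ", ") else "none", "\n")
  invisible(x)
}

# Output side of a square conv/pool with 'same'-style odd-kernel padding.
conv_out_dim <- function(h, k, stride, pad = (k - 1L) %/% 2L) {
  as.integer((h + 2L * pad - k) %/% stride + 1L)
}

block_activation <- function(spec) if (spec$use_silu) "silu" else "relu"

# Per-stage block_spec lists implied by an arch_spec.
arch_blocks <- function(spec) {
  act <- block_activation(spec)
  chans <- spec$width * spec$stage_mult
  out <- list()
  c_in <- spec$width
  for (s in seq_along(spec$stage_blocks)) {
    stage <- list()
    for (b in seq_len(spec$stage_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      stage[[b]] <- block_spec(
        c_in = c_in, c_out = chans[s], stride = stride,
        dw_conv2 = spec$use_dwconv, use_se = spec$use_se,
        se_reduction = spec$se_reduction,
        activation = act, nested = spec$use_nested
      )
      c_in <- chans[s]
    }
    out[[s]] <- stage
  }
  out
}

#' Enumerate every parameterized layer of an architecture
#'
#' Flattens an [arch_spec()] into a tibble with one row per layer (stem
#' convolution, max pool, every block convolution, every batch normalization,
#' SE bottleneck linears, the classifier head), tracking output spatial
#' dimensions through the network and attaching the closed-form parameter and
#' multiply-accumulate count of each row. Convolutions are bias-free; batch
#' normalization contributes 2C affine parameters and no MACs; pooling and
#' activations contribute neither; linear layers (SE and head) count
#' `in * out` MACs and `in * out + out` parameters.
#'
#' @param spec An [arch_spec()].
#' @return A tibble with columns `layer`, `type`, `k`, `c_in`, `c_out`,
#'   `stride`, `depthwise`, `h_out`, `w_out`, `params`, `macs`.
#' @examples
#' layers <- arch_layers(arch_spec("resnet34"))
#' sum(layers$params)  # 21797672
#' @export
arch_layers <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  rows <- list()
  add <- function(layer, type, k = NA_integer_, c_in = NA_integer_,
                  c_out = NA_integer_, stride = NA_integer_,
                  depthwise = FALSE, h = NA_integer_, w = NA_integer_,
                  params = 0, macs = 0) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer = layer, type = type, k = k, c_in = c_in, c_out = c_out,
      stride = stride, depthwise = depthwise, h_out = h, w_out = w,
      params = params, macs = macs
    )
  }
  add_conv <- function(layer, cs, h, w) {
    add(layer, "conv", cs$k, cs$c_in, cs$c_out, cs$stride, cs$depthwise,
        h, w, conv_params(cs), conv_macs(cs, h, w))
  }
  add_bn <- function(layer, c, h, w) {
    add(layer, "batchnorm", c_in = c, c_out = c, h = h, w = w, params = 2 * c)
  }

  h <- spec$input_size
  stem <- conv_spec(7L, 3L, spec$width, stride = 2L)
  h <- conv_out_dim(h, 7L, 2L)
  add_conv("stem.conv", stem, h, h)
  add_bn("stem.bn", spec$width, h, h)
  h <- conv_out_dim(h, 3L, 2L, pad = 1L)
  add("stem.maxpool", "maxpool", k = 3L, c_in = spec$width,
      c_out = spec$width, stride = 2L, h = h, w = h)

  blocks <- arch_blocks(spec)
  for (s in seq_along(blocks)) {
    for (b in seq_along(blocks[[s]])) {
      bs <- blocks[[s]][[b]]
      nm <- sprintf("stage%d.block%d", s, b)
      h1 <- conv_out_dim(h, 3L, bs$conv1$stride)
      add_conv(paste0(nm, ".conv1"), bs$conv1, h1, h1)
      add_bn(paste0(nm, ".bn1"), bs$conv1$c_out, h1, h1)
      add_conv(paste0(nm, ".conv2"), bs$conv2, h1, h1)
      add_bn(paste0(nm, ".bn2"), bs$conv2$c_out, h1, h1)
      if (!is.null(bs$projection)) {
        add_conv(paste0(nm, ".proj"), bs$projection, h1, h1)
        add_bn(paste0(nm, ".proj_bn"), bs$projection$c_out, h1, h1)
      }
      if (bs$use_se) {
        c <- bs$conv2$c_out
        hid <- se_hidden(c, bs$se_reduction)
        add(paste0(nm, ".se.fc1"), "linear", c_in = c, c_out = hid, h = h1, w = h1,
            params = c * hid + hid, macs = c * hid)
        add(paste0(nm, ".se.fc2"), "linear", c_in = hid, c_out = c, h = h1, w = h1,
            params = hid * c + c, macs = hid * c)
      }
      h <- h1
    }
  }
  c_last <- spec$width * tail(spec$stage_mult, 1)
  add("head.gap", "avgpool", c_in = c_last, c_out = c_last, h = 1L, w = 1L)
  add("head.fc", "linear", c_in = c_last, c_out = spec$num_classes, h = 1L, w = 1L,
      params = c_last * spec$num_classes + spec$num_classes,
      macs = c_last * spec$num_classes)
  dplyr::bind_rows(rows)
}

#' Write / read an architecture specification as YAML
#'
#' @param spec An [arch_spec()].
#' @param path File path for the YAML document.
#' @return `arch_to_yaml()` returns `path` invisibly; `arch_from_yaml()`
#'   returns the reconstructed [arch_spec()].
#' @export
arch_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "arch_spec"))
  fields <- spec[c("variant", "num_classes", "use_dwconv", "use_se",
                   "use_silu", "use_nested", "width", "input_size",
                   "se_reduction")]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname arch_to_yaml
#' @export
arch_from_yaml <- function(path) {
  f <- yaml::read_yaml(path)
  arch_spec(
    variant = "custom",
    num_classes = f$num_classes,
    use_dwconv = f$use_dwconv, use_se = f$use_se,
    use_silu = f$use_silu, use_nested = f$use_nested,
    width = f$width, input_size = f$input_size,
    se_reduction = f$se_reduction
  )
}
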