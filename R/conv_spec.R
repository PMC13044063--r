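#' Declarative convolution specification
#'
#' Describes one square convolution: kernel size, channel fan-in/out, stride
#' and whether it is depthwise (one kernel per input channel, no cross-channel
#' mixing, so `c_out` must equal `c_in`). A `conv_spec` carries everything the
#' closed-form parameter and multiply-accumulate formulas need; it is the unit
#' the architecture table ([arch_layers()]) and profiler ([profile_arch()])
#' are built from.
#'
#' @param k Kernel size (square), positive integer.
#' @param c_in Input channels.
#' @param c_out Output channels. For depthwise convolutions this must equal
#'   `c_in`; it defaults to `c_in` when `depthwise = TRUE`.
#' @param stride Stride, positive integer.
#' @param depthwise Logical; one kernel per input channel.
#' @return A `conv_spec` object (named list).
#' @examples
#' conv_spec(3, 64, 64)                   # standard 3x3
#' conv_spec(3, 64, depthwise = TRUE)     # depthwise 3x3
#' @export
conv_spec <- function(k, c_in, c_out = if (depthwise) c_in else NULL,
                      stride = 1L, depthwise = FALSE) {
  if (is.null(c_out)) abort("`c_out` is required for a standard convolution.")
  vals <- c(k = k, c_in = c_in, c_out = c_out, stride = stride)
  if (any(vals < 1) || any(vals != round(vals))) {
    abort("`k`, `c_in`, `c_out` and `stride` must be positive integers.")
  }
  if (depthwise && c_out != c_in) {
    abort("Depthwise convolution requires `c_out == c_in` (one kernel per input channel).")
  }
  structure(
    list(k = as.integer(k), c_in = as.integer(c_in), c_out = as.integer(c_out),
         stride = as.integer(stride), depthwise = isTRUE(depthwise)),
    class = "conv_spec"
  )
}

#' @export
print.conv_spec <- function(x, ...) {
  cat(sprintf(
    "<conv_spec> %dx%d %s, %d -> %d channels, stride %d\n",
    x$k, x$k, if (x$depthwise) "depthwise" else "standard",
    x$c_in, x$c_out, x$stride
  ))
  invisible(x)
}

#' Closed-form parameter count of one convolution
#'
#' Standard convolution: \eqn{K^2 C_{in} C_{out}}; depthwise convolution:
#' \eqn{K^2 C_{in}} (one K-by-K kernel per input channel). Convolutions are
#' counted bias-free, the standard arrangement when each is followed by batch
#' normalization (the 2C affine BN parameters are accounted separately by the
#' profiler).
#'
#' @param spec A [conv_spec()].
#' @return Integer-valued parameter count (as a double, to avoid 32-bit
#'   overflow on large layers).
#' @examples
#' conv_params(conv_spec(3, 64, 64))                 # 36864
#' conv_params(conv_spec(3, 64, depthwise = TRUE))   # 576
#' @export
conv_params <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  if (spec$depthwise) spec$k^2 * spec$c_in else spec$k^2 * spec$c_in * spec$c_out
}

#' Closed-form multiply-accumulate count of one convolution
#'
#' One multiply-accumulate (MAC) per kernel weight per output position.
#' Standard convolution: \eqn{K^2 C_{in} H W C_{out}}; depthwise:
#' \eqn{K^2 C_{in} H W}. `h_out` and `w_out` are the *output* spatial
#' dimensions of the convolution.
#'
#' @param spec A [conv_spec()].
#' @param h_out,w_out Output height and width.
#' @return MAC count (double).
#' @examples
#' conv_macs(conv_spec(3, 64, 64), 56, 56)                # 115605504
#' conv_macs(conv_spec(3, 64, depthwise = TRUE), 56, 56)  # 1806336
#' @export
conv_macs <- function(spec, h_out, w_out) {
  stopifnot(inherits(spec, "conv_spec"), h_out >= 1, w_out >= 1)
  conv_params(spec) * h_out * w_out
}

#' Residual block specification
#'
#' A basic residual block: two stacked convolutions (each followed by batch
#' normalization), an identity shortcut -- or a 1x1 projection when the block
#' changes stride or channel count -- optional squeeze-and-excitation gating of
#' the branch before the summation, and an optional parameter-free nested
#' inner skip around the first conv-BN-activation sub-unit.
#'
#' @param c_in Channels entering the block.
#' @param c_out Channels produced by the block.
#' @param stride Stride of the first convolution (1 keeps spatial dims, 2
#'   halves them).
#' @param dw_conv2 Logical; make the second 3x3 convolution depthwise.
#' @param use_se Logical; apply squeeze-and-excitation to the branch.
#' @param se_reduction Bottleneck reduction ratio of the SE block.
#' @param activation Activation name (see [silu()]; any key of the activation
#'   registry: relu, relu6, leaky_relu, elu, silu, sigmoid, gelu, mish,
#'   hardsigmoid, hardswish).
#' @param nested Logical; add the parameter-free inner identity skip. The
#'   inner skip is only active when the first sub-unit preserves shape
#'   (stride 1 and `c_in == c_out`); projection blocks omit it.
#' @return A `block_spec` object.
#' @export
block_spec <- function(c_in, c_out, stride = 1L, dw_conv2 = FALSE,
                       use_se = FALSE, se_reduction = 16L,
                       activation = "relu", nested = FALSE) {
  get_activation(activation)  # validates the name
  conv1 <- conv_spec(3L, c_in, c_out, stride = stride)
  conv2 <- conv_spec(3L, c_out, c_out, depthwise = dw_conv2)
  projection <- NULL
  if (stride > 1L || c_in != c_out) {
    projection <- conv_spec(1L, c_in, c_out, stride = stride)
  }
  structure(
    list(conv1 = conv1, conv2 = conv2, projection = projection,
         use_se = isTRUE(use_se), se_reduction = as.integer(se_reduction),
         activation = activation, nested = isTRUE(nested)),
    class = "block_spec"
  )
}

# Hidden width of an SE bottleneck: floor(C / r), never below 1.
se_hidden <- function(c, reduction) max(1L, c %/% reduction)
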