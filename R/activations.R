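#' Sigmoid activation
#'
#' The logistic function \eqn{\sigma(x) = 1 / (1 + e^{-x})}, mapping any real
#' input into (0, 1). It is the gating half of [silu()] and the final squash of
#' the squeeze-and-excitation channel gates.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x` with values in (0, 1).
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(1)    # 0.7310586
#' @export
sigmoid <- function(x) {
  # plogis is the numerically safe logistic (no overflow for large |x|)
  out <- stats::plogis(x)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' SiLU activation
#'
#' The sigmoid-weighted linear unit \eqn{\mathrm{SiLU}(x) = x\,\sigma(x)}
#' (also called swish). Smooth and everywhere differentiable: it behaves like
#' the identity for large positive inputs, tends to 0 for large negative
#' inputs, and keeps a small non-zero response on the negative side, avoiding
#' dead units while preserving ReLU-like sparsity.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @examples
#' silu(0)   # 0
#' silu(1)   # 0.7310586
#' silu(-1)  # -0.2689414
#' @export
silu <- function(x) x * sigmoid(x)

#' Derivative of SiLU
#'
#' \eqn{\sigma(x) + x\,\sigma(x)(1 - \sigma(x))}, used by the training engine
#' and exposed for gradient checks.
#'
#' @param x Numeric vector, matrix or array.
#' @return Derivative values, same shape as `x`.
#' @export
silu_grad <- function(x) {
  s <- sigmoid(x)
  s + x * s * (1 - s)
}

# Registry of pointwise activations: each entry has f(x) and grad(x).
# Everything beyond relu/silu delegates to the standard textbook definitions;
# they exist so alternative-activation variants are constructible.
activation_registry <- function() {
  list(
    relu = list(
      f = function(x) pmax(x, 0),
      grad = function(x) as.numeric(x > 0)
    ),
    relu6 = list(
      f = function(x) pmin(pmax(x, 0), 6),
      grad = function(x) as.numeric(x > 0 & x < 6)
    ),
    leaky_relu = list(
      f = function(x) ifelse(x > 0, x, 0.01 * x),
      grad = function(x) ifelse(x > 0, 1, 0.01)
    ),
    elu = list(
      f = function(x) ifelse(x > 0, x, expm1(x)),
      grad = function(x) ifelse(x > 0, 1, exp(x))
    ),
    silu = list(f = silu, grad = silu_grad),
    sigmoid = list(
      f = sigmoid,
      grad = function(x) { s <- sigmoid(x); s * (1 - s) }
    ),
    gelu = list(
      f = function(x) x * stats::pnorm(x),
      grad = function(x) stats::pnorm(x) + x * stats::dnorm(x)
    ),
    mish = list(
      f = function(x) x * tanh(log1p(exp(pmin(x, 30)))),
      grad = function(x) {
        sp <- log1p(exp(pmin(x, 30)))
        t <- tanh(sp)
        t + x * (1 - t^2) * sigmoid(x)
      }
    ),
    hardsigmoid = list(
      f = function(x) pmin(pmax(x / 6 + 0.5, 0), 1),
      grad = function(x) as.numeric(x > -3 & x < 3) / 6
    ),
    hardswish = list(
      f = function(x) x * pmin(pmax(x / 6 + 0.5, 0), 1),
      grad = function(x) {
        ifelse(x <= -3, 0, ifelse(x >= 3, 1, x / 3 + 0.5))
      }
    )
  )
}

get_activation <- function(name) {
  reg <- activation_registry()
  if (!name %in% names(reg)) {
    abort(paste0(
      "Unknown activation '", name, "'. Available: ",
      paste(names(reg), collapse = ", ")
    ))
  }
  reg[[name]]
}
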