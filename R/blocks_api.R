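# Standalone, functional views of the network building blocks, operating on
# single feature maps (H x W x C arrays). The training engine uses the same
# kernels on (H, W, C, N) batches.

#' Initialize the parameters of one residual block
#'
#' @param spec A [block_spec()].
#' @param seed Integer seed.
#' @param zero_gamma2 Zero-initialize the second batch-norm gamma (the
#'   residual-friendly start used by [build_model()]); default `FALSE` here so
#'   a standalone block transforms its input.
#' @return Parameter list matching the block structure (conv1/bn1/conv2/bn2,
#'   optional proj/proj_bn, optional se).
#' @export
init_block_params <- function(spec, seed = 1L, zero_gamma2 = FALSE) {
  stopifnot(inherits(spec, "block_spec"))
  set.seed(seed)
  init_conv <- function(cs) {
    if (cs$depthwise) {
      matrix(rnorm(cs$c_in * cs$k^2, 0, sqrt(2 / cs$k^2)), cs$c_in, cs$k^2)
    } else {
      matrix(rnorm(cs$c_out * cs$k^2 * cs$c_in, 0, sqrt(2 / (cs$k^2 * cs$c_out))),
             cs$c_out, cs$k^2 * cs$c_in)
    }
  }
  c_out <- spec$conv1$c_out
  p <- list(
    conv1 = init_conv(spec$conv1),
    bn1 = list(gamma = rep(1, c_out), beta = numeric(c_out)),
    conv2 = init_conv(spec$conv2),
    bn2 = list(gamma = if (zero_gamma2) numeric(c_out) else rep(1, c_out),
               beta = numeric(c_out)),
    proj = if (!is.null(spec$projection)) init_conv(spec$projection),
    proj_bn = if (!is.null(spec$projection))
      list(gamma = rep(1, c_out), beta = numeric(c_out)),
    se = NULL
  )
  if (spec$use_se) {
    hid <- se_hidden(c_out, spec$se_reduction)
    p$se <- list(w1 = matrix(rnorm(hid * c_out, 0, sqrt(1 / c_out)), hid, c_out),
                 b1 = numeric(hid),
                 w2 = matrix(rnorm(c_out * hid, 0, sqrt(1 / hid)), c_out, hid),
                 b2 = numeric(c_out))
  }
  p
}

#' Apply one residual block to a feature map
#'
#' Runs branch = BN(conv2(act(BN(conv1(x))))), adds the identity (or 1x1
#' projected) shortcut, optionally gates the branch with
#' squeeze-and-excitation before the summation, applies the final activation,
#' and -- when the block is nested and its first sub-unit preserves shape --
#' adds the parameter-free inner identity skip around that sub-unit.
#' Batch normalization runs in inference mode (zero mean, unit variance
#' running statistics) unless `train = TRUE`.
#'
#' @param x H x W x C array with `C == spec$conv1$c_in`.
#' @param spec A [block_spec()].
#' @param params Parameters from [init_block_params()] (generated from `seed`
#'   when omitted).
#' @param seed Seed for parameter generation when `params` is `NULL`.
#' @param train Use batch statistics in batch norm.
#' @return H x W' x C' feature map (spatial dims halved when stride 2).
#' @export
residual_block <- function(x, spec, params = NULL, seed = 1L, train = FALSE) {
  stopifnot(inherits(spec, "block_spec"))
  if (length(dim(x)) != 3L) {
    abort("`x` must be an H x W x C array.", class = "garlicnet_error_dims")
  }
  if (dim(x)[3] != spec$conv1$c_in) {
    abort(sprintf("Block expects %d input channels, got %d.",
                  spec$conv1$c_in, dim(x)[3]),
          class = "garlicnet_error_spec")
  }
  params <- params %||% init_block_params(spec, seed)
  dim(x) <- c(dim(x), 1L)
  c_out <- spec$conv1$c_out
  bstate <- list(bn1 = list(mean = numeric(c_out), var = rep(1, c_out)),
                 bn2 = list(mean = numeric(c_out), var = rep(1, c_out)),
                 proj_bn = if (!is.null(spec$projection))
                   list(mean = numeric(c_out), var = rep(1, c_out)))
  out <- block_forward(x, params, bstate, spec, train)$out
  array(out, dim = dim(out)[1:3])
}

#' Squeeze-and-excitation channel gating
#'
#' Global average pool, bottleneck linear (C to floor(C/r), minimum 1), ReLU,
#' linear back to C, sigmoid: the resulting per-channel gates in (0, 1)
#' rescale the input channels. Shape is always preserved.
#'
#' @param fmap H x W x C array.
#' @param reduction Bottleneck reduction ratio, default 16.
#' @param params Optional list with `w1`, `b1`, `w2`, `b2`; random (seeded)
#'   when omitted.
#' @param seed Seed for parameter generation when `params` is `NULL`.
#' @return List with `out` (gated map, same shape) and `gates` (length-C
#'   vector in (0, 1)).
#' @export
se_block <- function(fmap, reduction = 16L, params = NULL, seed = 1L) {
  if (length(dim(fmap)) != 3L) {
    abort("`fmap` must be an H x W x C array.", class = "garlicnet_error_dims")
  }
  c <- dim(fmap)[3]
  if (is.null(params)) {
    set.seed(seed)
    hid <- se_hidden(c, reduction)
    params <- list(w1 = matrix(rnorm(hid * c, 0, sqrt(1 / c)), hid, c),
                   b1 = numeric(hid),
                   w2 = matrix(rnorm(c * hid, 0, sqrt(1 / hid)), c, hid),
                   b2 = numeric(c))
  }
  x <- fmap
  dim(x) <- c(dim(fmap), 1L)
  sf <- se_forward(x, params)
  list(out = array(sf$out, dim = dim(fmap)), gates = as.vector(sf$cache$g))
}
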