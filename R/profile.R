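#' Closed-form profile of an architecture
#'
#' Sums the per-layer parameter and multiply-accumulate (MAC) counts of
#' [arch_layers()] into a profile report. Conventions: convolutions are
#' bias-free, batch normalization contributes 2C parameters per layer,
#' pooling / activations / elementwise additions contribute zero MACs, and
#' linear layers count `in * out` MACs. The headline "GFLOPs" figure follows
#' the widespread profiler habit of reporting MACs in units of 1e9;
#' `params_M` is rounded to one decimal while `gflops` is truncated to two
#' decimals (the display convention the reference figures for this
#' architecture family follow).
#'
#' @param spec An [arch_spec()], or a variant name understood by
#'   [arch_spec()] (profiled with the conventional 1000-way head at 224x224).
#' @param se_in_count Logical; include SE bottleneck parameters/MACs when the
#'   spec enables SE. Default `TRUE`.
#' @return A `garlic_profile` object: list with `layers` (tibble), `params`,
#'   `params_M`, `macs`, `gflops`, `weight_bytes` and the originating spec.
#' @examples
#' profile_arch("resnet34")$params_M          # 21.8
#' profile_arch("resnet34_dwconv")$gflops     # 1.82
#' @export
profile_arch <- function(spec, se_in_count = TRUE) {
  if (is.character(spec)) spec <- arch_spec(spec)
  stopifnot(inherits(spec, "arch_spec"))
  layers <- arch_layers(spec)
  if (!se_in_count) {
    layers <- dplyr::filter(layers, !grepl("\\.se\\.", .data$layer))
  }
  params <- sum(layers$params)
  macs <- sum(layers$macs)
  structure(
    list(
      spec = spec,
      layers = layers,
      params = params,
      params_M = round(params / 1e6, 1),
      macs = macs,
      gflops = trunc(macs / 1e7) / 100,
      weight_bytes = 4 * params
    ),
    class = "garlic_profile"
  )
}

#' @export
print.garlic_profile <- function(x, ...) {
  cat(sprintf("<garlic_profile> %s @ %dx%d, %d classes\n",
              x$spec$variant, x$spec$input_size, x$spec$input_size,
              x$spec$num_classes))
  cat(sprintf("  parameters: %s (%.1f M)\n",
              format(x$params, big.mark = ","), x$params_M))
  cat(sprintf("  MACs:       %s (%.2f G)\n",
              format(x$macs, big.mark = ","), x$gflops))
  cat(sprintf("  weights:    %s bytes at fp32\n",
              format(x$weight_bytes, big.mark = ",")))
  invisible(x)
}

#' @describeIn profile_arch Per-layer tibble of the profile.
#' @param x A `garlic_profile`.
#' @param ... Unused.
#' @export
tidy.garlic_profile <- function(x, ...) x$layers

#' @describeIn profile_arch One-row summary tibble.
#' @export
glance.garlic_profile <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    input_size = x$spec$input_size,
    num_classes = x$spec$num_classes,
    params = x$params,
    params_M = x$params_M,
    macs = x$macs,
    gflops = x$gflops,
    weight_bytes = x$weight_bytes
  )
}

#' Empirical forward-pass latency
#'
#' Median wall-clock time of a single-image forward pass through a built
#' network, with warm-up repetitions discarded. Informational only: latency is
#' hardware- and implementation-dependent, and depthwise convolutions in
#' particular are not asserted to be faster than standard ones.
#'
#' @param network A network built by [build_model()].
#' @param batch Batch size, default 1.
#' @param reps Timed repetitions (>= 1), default 5.
#' @param warmup Untimed warm-up repetitions, default 1.
#' @return A tibble with `latency_ms` (median per forward) and `fps`
#'   (`1000 * batch / latency_ms`).
#' @export
measure_latency <- function(network, batch = 1L, reps = 5L, warmup = 1L) {
  stopifnot(reps >= 1)
  sz <- network$spec$input_size
  x <- array(0.5, dim = c(sz, sz, 3L, batch))
  for (i in seq_len(warmup)) network_forward(network, x, train = FALSE)
  times <- vapply(seq_len(reps), function(i) {
    t0 <- proc.time()[["elapsed"]]
    network_forward(network, x, train = FALSE)
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  ms <- stats::median(times) * 1000
  tibble::tibble(latency_ms = ms, fps = 1000 * batch / ms)
}
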