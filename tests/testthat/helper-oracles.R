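# Independent oracles used by the tests. Deliberately naive implementations:
# they must not share code paths with the package internals they check.

# 8-connected component labeling by breadth-first flood fill.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask > 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      px <- queue[1]; queue <- queue[-1]
      r <- (px - 1L) %% h + 1L
      c <- (px - 1L) %/% h + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] > 0 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- c(queue, (cc - 1L) * h + rr)
        }
      }
    }
  }
  lab
}

# Direct sliding-window convolution (zero padding), returning both the output
# and a tally of multiply-accumulate operations actually performed.
naive_conv <- function(x, w4, stride = 1L, pad = NULL) {
  k <- dim(w4)[1]; c_in <- dim(w4)[3]; c_out <- dim(w4)[4]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  h <- dim(x)[1]; w <- dim(x)[2]
  xp <- array(0, dim = c(h + 2 * pad, w + 2 * pad, c_in))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  ho <- (h + 2 * pad - k) %/% stride + 1L
  wo <- (w + 2 * pad - k) %/% stride + 1L
  out <- array(0, dim = c(ho, wo, c_out))
  macs <- 0
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      patch <- xp[(i - 1) * stride + seq_len(k), (j - 1) * stride + seq_len(k), ,
                  drop = FALSE]
      for (co in seq_len(c_out)) {
        out[i, j, co] <- sum(as.vector(patch) * as.vector(w4[, , , co]))
        macs <- macs + length(patch)
      }
    }
  }
  list(out = out, macs = macs, ho = ho, wo = wo)
}

# Depthwise counterpart: one k x k kernel per channel.
naive_dwconv <- function(x, w3, stride = 1L, pad = NULL) {
  k <- dim(w3)[1]; c_in <- dim(w3)[3]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  h <- dim(x)[1]; w <- dim(x)[2]
  xp <- array(0, dim = c(h + 2 * pad, w + 2 * pad, c_in))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  ho <- (h + 2 * pad - k) %/% stride + 1L
  wo <- (w + 2 * pad - k) %/% stride + 1L
  out <- array(0, dim = c(ho, wo, c_in))
  macs <- 0
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      for (ch in seq_len(c_in)) {
        patch <- xp[(i - 1) * stride + seq_len(k), (j - 1) * stride + seq_len(k), ch]
        out[i, j, ch] <- sum(as.vector(patch) * as.vector(w3[, , ch]))
        macs <- macs + length(patch)
      }
    }
  }
  list(out = out, macs = macs, ho = ho, wo = wo)
}

# Per-definition one-vs-rest metrics straight from the published formulas.
brute_metrics <- function(cm) {
  total <- sum(cm)
  k <- nrow(cm)
  res <- data.frame(precision = numeric(k), recall = numeric(k), f1 = numeric(k))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    res$precision[i] <- p
    res$recall[i] <- r
    res$f1[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  res$acc <- sum(diag(cm)) / total
  res
}

# Hook-style MAC instrumentation: run a real forward pass, read every
# convolution's measured output dims out of the caches, and tally MACs from
# the measured dims (plus SE / head linear terms).
instrumented_macs <- function(network, input_size = NULL) {
  sz <- if (is.null(input_size)) network$spec$input_size else input_size
  x <- array(0.5, dim = c(sz, sz, 3L, 1L))
  fw <- garlicnet:::network_forward(network, x, train = FALSE, keep_cache = TRUE)
  conv_count <- function(cache) {
    sp <- cache$spec
    per_pos <- if (sp$depthwise) sp$k^2 * sp$c_in else sp$k^2 * sp$c_in * sp$c_out
    per_pos * cache$ii$ho * cache$ii$wo
  }
  total <- conv_count(fw$cache$stem_conv)
  for (bc in fw$cache$blocks) {
    total <- total + conv_count(bc$c1) + conv_count(bc$c2)
    if (!is.null(bc$pc)) total <- total + conv_count(bc$pc)
    if (!is.null(bc$se)) {
      c <- bc$se$d[3]
      hid <- nrow(bc$se$a1)   # measured bottleneck width
      total <- total + c * hid + hid * c
    }
  }
  total + nrow(fw$logits) * length(fw$cache$feat)
}

# Intersection-over-union of two 0-based half-open bounding boxes.
bbox_iou <- function(a, b) {
  ri <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ci <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ri * ci
  a_area <- (a[3] - a[1]) * (a[4] - a[2])
  b_area <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (a_area + b_area - inter)
}
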