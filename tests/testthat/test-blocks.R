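test_that("SE gating preserves shape and scales channels by gates in (0,1)", {
  set.seed(2)
  fmap <- array(rnorm(8 * 8 * 6), dim = c(8, 8, 6))
  res <- se_block(fmap, reduction = 2, seed = 2)
  expect_equal(dim(res$out), dim(fmap))
  expect_true(all(res$gates > 0 & res$gates < 1))
  for (ch in 1:6) {
    expect_equal(res$out[, , ch], fmap[, , ch] * res$gates[ch])
  }
  # zero input stays zero regardless of the gates
  z <- se_block(array(0, dim = c(4, 4, 3)), seed = 5)
  expect_equal(z$out, array(0, dim = c(4, 4, 3)))
})

test_that("SE gates forced open reproduce the input exactly", {
  fmap <- array(runif(5 * 5 * 4), dim = c(5, 5, 4))
  params <- list(w1 = matrix(0, 1, 4), b1 = 0,
                 w2 = matrix(0, 4, 1), b2 = rep(50, 4))   # sigmoid(50) ~ 1
  res <- se_block(fmap, params = params)
  expect_equal(res$out, fmap, tolerance = 1e-12)
})

test_that("SE bottleneck width floors at one unit", {
  expect_equal(garlicnet:::se_hidden(8L, 16L), 1L)
  expect_equal(garlicnet:::se_hidden(64L, 16L), 4L)
  expect_equal(garlicnet:::se_hidden(33L, 16L), 2L)
})

test_that("a zero-weight block reduces to the activated shortcut", {
  spec <- block_spec(4, 4, activation = "relu")
  params <- init_block_params(spec, seed = 1)
  params$conv1[] <- 0; params$conv2[] <- 0
  x <- array(abs(rnorm(6 * 6 * 4)), dim = c(6, 6, 4))   # non-negative input
  out <- residual_block(x, spec, params)
  # branch is 0 (convs zero, BN maps 0 to 0), shortcut is x, ReLU(x) = x
  expect_equal(out, x, tolerance = 1e-10)
  # nested and non-nested coincide when the branch is zero
  spec_n <- block_spec(4, 4, activation = "relu", nested = TRUE)
  out_n <- residual_block(x, spec_n, params)
  expect_equal(out_n, out, tolerance = 1e-10)
})

test_that("projection blocks halve spatial dims and remap channels", {
  spec <- block_spec(8, 16, stride = 2, activation = "silu")
  x <- array(rnorm(12 * 12 * 8), dim = c(12, 12, 8))
  out <- residual_block(x, spec, seed = 3)
  expect_equal(dim(out), c(6L, 6L, 16L))
  # odd inputs round up (ceil division)
  x9 <- array(rnorm(9 * 9 * 8), dim = c(9, 9, 8))
  expect_equal(dim(residual_block(x9, spec, seed = 3))[1:2], c(5L, 5L))
  # stride-1 same-channel blocks preserve shape, with or without SE/nesting
  for (use_se in c(FALSE, TRUE)) {
    sp1 <- block_spec(8, 8, use_se = use_se, nested = TRUE, dw_conv2 = TRUE)
    expect_equal(dim(residual_block(x, sp1, seed = 4)), dim(x))
  }
  expect_error(residual_block(array(0, dim = c(4, 4, 3)), spec),
               class = "garlicnet_error_spec")
})

test_that("the plain block matches a from-scratch basic-block reference", {
  # reference: direct sliding-window convs + the same inference-mode BN
  set.seed(8)
  c <- 4L
  spec <- block_spec(c, c, activation = "relu")
  params <- init_block_params(spec, seed = 8)
  x <- array(rnorm(7 * 7 * c), dim = c(7, 7, c))

  to_w4 <- function(wm, k, c_in) {
    # engine layout (C_out x K^2*C_in), kernel row fastest -> 4-d array
    array(t(wm), dim = c(k, k, c_in, nrow(wm)))
  }
  bn_ref <- function(z, gamma, beta, eps = 1e-5) {
    # inference mode: running mean 0, running var 1
    sweep(sweep(z / sqrt(1 + eps), 3, gamma, "*"), 3, beta, "+")
  }
  h1 <- naive_conv(x, to_w4(params$conv1, 3L, c))$out
  a1 <- pmax(bn_ref(h1, params$bn1$gamma, params$bn1$beta), 0)
  h2 <- naive_conv(a1, to_w4(params$conv2, 3L, c))$out
  b2 <- bn_ref(h2, params$bn2$gamma, params$bn2$beta)
  ref <- pmax(b2 + x, 0)

  got <- residual_block(x, spec, params)
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("nested blocks add a parameter-free inner skip", {
  set.seed(9)
  c <- 4L
  x <- array(rnorm(6 * 6 * c), dim = c(6, 6, c))
  spec_flat <- block_spec(c, c, activation = "silu")
  spec_nest <- block_spec(c, c, activation = "silu", nested = TRUE)
  params <- init_block_params(spec_flat, seed = 9)
  out_flat <- residual_block(x, spec_flat, params)
  out_nest <- residual_block(x, spec_nest, params)
  # same parameters, different outputs: the inner skip is active
  expect_false(isTRUE(all.equal(out_flat, out_nest)))
  # manual reference: inner skip adds x after the first activation
  bn_ref <- function(z, gamma, beta, eps = 1e-5) {
    sweep(sweep(z / sqrt(1 + eps), 3, gamma, "*"), 3, beta, "+")
  }
  to_w4 <- function(wm, k, c_in) array(t(wm), dim = c(k, k, c_in, nrow(wm)))
  sg <- function(z) z * (1 / (1 + exp(-z)))
  u <- sg(bn_ref(naive_conv(x, to_w4(params$conv1, 3L, c))$out,
                 params$bn1$gamma, params$bn1$beta)) + x
  b2 <- bn_ref(naive_conv(u, to_w4(params$conv2, 3L, c))$out,
               params$bn2$gamma, params$bn2$beta)
  expect_equal(out_nest, sg(b2 + x), tolerance = 1e-8)
})
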