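test_that("named variants set the published toggle combinations", {
  base <- arch_spec("resnet34")
  expect_false(any(c(base$use_dwconv, base$use_se, base$use_silu, base$use_nested)))
  dw <- arch_spec("resnet34_dwconv")
  expect_true(dw$use_dwconv)
  expect_false(any(c(dw$use_se, dw$use_silu, dw$use_nested)))
  dh <- arch_spec("dh_garlicnet")
  expect_true(all(c(dh$use_dwconv, dh$use_se, dh$use_silu, dh$use_nested)))
  expect_equal(dh$stage_blocks, c(3L, 4L, 6L, 3L))
  expect_error(arch_spec("resnet34", num_classes = 1), "at least 2")
})

test_that("the layer table tracks the published stage geometry", {
  layers <- arch_layers(arch_spec("resnet34"))
  # stem downsamples 224 -> 56 at 64 channels
  stem <- layers[layers$layer == "stem.maxpool", ]
  expect_equal(c(stem$h_out, stem$c_out), c(56L, 64L))
  # stage outputs 56/28/14/7 at 64/128/256/512
  for (s in 1:4) {
    last <- layers[grepl(sprintf("^stage%d", s), layers$layer), ]
    last <- last[nrow(last), ]
    expect_equal(last$h_out, c(56L, 28L, 14L, 7L)[s])
    expect_equal(last$c_out, c(64L, 128L, 256L, 512L)[s])
  }
  # the head sees 512 channels
  fc <- layers[layers$layer == "head.fc", ]
  expect_equal(fc$c_in, 512L)
  expect_equal(fc$c_out, 1000L)
})

test_that("all eight ablation variants build and run a forward pass", {
  grid <- expand.grid(dw = c(FALSE, TRUE), se = c(FALSE, TRUE),
                      silu = c(FALSE, TRUE))
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  for (i in seq_len(nrow(grid))) {
    spec <- arch_spec("custom", num_classes = 3,
                      use_dwconv = grid$dw[i], use_se = grid$se[i],
                      use_silu = grid$silu[i], use_nested = FALSE,
                      width = 4, input_size = 32)
    net <- build_model(spec, seed = i)
    fw <- network_forward(net, x)
    expect_equal(dim(fw$logits), c(3L, 2L))
    expect_true(all(is.finite(fw$logits)))
    # instantiated parameter count equals the closed-form total
    expect_equal(count_params(net), profile_arch(spec)$params)
  }
})

test_that("eval-mode forwards are deterministic and shape-correct", {
  net <- build_model("dh_garlicnet", num_classes = 3, width = 4,
                     input_size = 32, seed = 11)
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  f1 <- network_forward(net, x)
  f2 <- network_forward(net, x)
  expect_identical(f1$logits, f2$logits)
  expect_error(network_forward(net, array(0, dim = c(32, 32, 2, 1))),
               class = "garlicnet_error_dims")
  # zero image through a zero head gives zero logits
  net$params$fc$w[] <- 0
  net$params$fc$b[] <- 0
  fz <- network_forward(net, array(0, dim = c(32, 32, 3, 1)))
  expect_equal(as.numeric(fz$logits), c(0, 0, 0))
})

test_that("the nested toggle never changes parameter counts", {
  for (v in list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                 c(TRUE, TRUE, TRUE))) {
    flat <- arch_spec("custom", num_classes = 3, use_dwconv = v[1],
                      use_se = v[2], use_silu = v[3], use_nested = FALSE,
                      width = 8, input_size = 64)
    nest <- arch_spec("custom", num_classes = 3, use_dwconv = v[1],
                      use_se = v[2], use_silu = v[3], use_nested = TRUE,
                      width = 8, input_size = 64)
    expect_equal(profile_arch(flat)$params, profile_arch(nest)$params)
    expect_equal(count_params(build_model(flat, seed = 1)),
                 count_params(build_model(nest, seed = 1)))
  }
})

test_that("architecture specs round-trip through YAML", {
  spec <- arch_spec("custom", num_classes = 3, use_dwconv = TRUE,
                    use_se = TRUE, use_silu = FALSE, use_nested = TRUE,
                    width = 16, input_size = 64)
  path <- withr::local_tempfile(fileext = ".yaml")
  arch_to_yaml(spec, path)
  back <- arch_from_yaml(path)
  for (f in c("num_classes", "use_dwconv", "use_se", "use_silu",
              "use_nested", "width", "input_size", "se_reduction")) {
    expect_identical(back[[f]], spec[[f]])
  }
})
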