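make_rgb <- function(h, w, r = 0, g = 0, b = 0) {
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

test_that("grayscale conversion uses Rec.601 luma weights", {
  expect_equal(to_grayscale(make_rgb(4, 4)), matrix(0, 4, 4))
  expect_equal(to_grayscale(make_rgb(4, 4, 1, 1, 1)), matrix(1, 4, 4))
  expect_equal(to_grayscale(make_rgb(2, 2, r = 1))[1, 1], 0.299)
  expect_equal(to_grayscale(make_rgb(2, 2, g = 1))[1, 1], 0.587)
  expect_equal(to_grayscale(make_rgb(2, 2, b = 1))[1, 1], 0.114)
  expect_error(to_grayscale(matrix(0, 4, 4)), class = "garlicnet_error_dims")
})

test_that("binarization respects the threshold with >= going to foreground", {
  g <- matrix(c(0.2, 0.5, 0.3, 0), 2, 2)
  m <- binarize(g, 0.3)
  expect_equal(m, matrix(c(0, 1, 1, 0), 2, 2))   # 0.2 -> 0, 0.5 -> 1, 0.3 -> 1
  expect_equal(binarize(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_true(all(binarize(matrix(runif(100), 10)) %in% c(0, 1)))
  expect_error(binarize(g, 0), class = "garlicnet_error_param")
  expect_error(binarize(g, 1.2), class = "garlicnet_error_param")
})

test_that("masking keeps foreground values and blacks out background", {
  set.seed(1)
  img <- array(runif(48), dim = c(4, 4, 3))
  expect_equal(apply_mask(img, matrix(1, 4, 4)), img)
  expect_equal(apply_mask(img, matrix(0, 4, 4)), array(0, dim = c(4, 4, 3)))
  m <- matrix(0, 4, 4); m[2, 3] <- 1
  out <- apply_mask(img, m)
  expect_equal(out[2, 3, ], img[2, 3, ])
  expect_true(all(out[-2, , ] == 0))
  expect_error(apply_mask(img, matrix(1, 3, 3)), class = "garlicnet_error_dims")
})

test_that("largest-component extraction returns tight half-open boxes", {
  # single 10x10 square at rows/cols 6..15 (1-based) = 5..14 (0-based)
  m <- matrix(0, 32, 32)
  m[6:15, 6:15] <- 1
  img <- array(rep(m, 3), dim = c(32, 32, 3))
  res <- extract_target(img, m)
  expect_equal(unname(res$bbox), c(5L, 5L, 15L, 15L))
  expect_equal(res$n_foreground, 100)
  # two components: only the larger survives
  m2 <- m
  m2[25:27, 25:27] <- 1
  res2 <- extract_target(array(rep(m2, 3), dim = c(32, 32, 3)), m2)
  expect_equal(res2$n_foreground, 100)
  expect_true(all(res2$mask[25:27, 25:27] == 0))
  expect_true(all(res2$masked_image[25:27, 25:27, ] == 0))
  # full-foreground mask spans the whole image
  full <- matrix(1, 8, 8)
  res3 <- extract_target(array(1, dim = c(8, 8, 3)), full)
  expect_equal(unname(res3$bbox), c(0L, 0L, 8L, 8L))
  expect_error(extract_target(img, matrix(0, 32, 32)),
               class = "garlicnet_error_no_foreground")
})

test_that("segment recovers the generator's bulb geometry", {
  fx <- generate_garlic_image("normal", image_size = 64, seed = 3)
  seg <- segment(fx$image)
  expect_true(all(abs(seg$bbox - fx$bulb_bbox) <= 1))
  expect_error(segment(array(0.1, dim = c(64, 64, 3))),
               class = "garlicnet_error_no_foreground")
  seg_full <- segment(array(0.9, dim = c(64, 64, 3)))
  expect_equal(unname(seg_full$bbox), c(0L, 0L, 64L, 64L))
})

test_that("segmentation is idempotent and mask-consistent", {
  for (s in 1:5) {
    fx <- generate_garlic_image(c("normal", "local_damage", "root_damage")[s %% 3 + 1],
                                image_size = 64, seed = s)
    seg <- segment(fx$image)
    expect_true(all(seg$masked_image[array(seg$mask == 0, dim(fx$image))] == 0))
    seg2 <- segment(seg$masked_image)
    expect_equal(seg2$mask, seg$mask)
    expect_equal(seg2$bbox, seg$bbox)
  }
})

test_that("raising the threshold never grows the foreground", {
  set.seed(7)
  for (i in 1:20) {
    g <- matrix(runif(256), 16, 16)
    thresholds <- sort(runif(5, 0.05, 0.95))
    sizes <- vapply(thresholds, function(t) sum(binarize(g, t)), numeric(1))
    expect_true(all(diff(sizes) <= 0))
    # foreground sets are nested, not merely shrinking
    m_lo <- binarize(g, thresholds[1])
    m_hi <- binarize(g, thresholds[5])
    expect_true(all(m_lo[m_hi == 1] == 1))
  }
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(99)
  for (i in 1:200) {
    m <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    if (!any(m == 1)) next
    lab_pkg <- garlicnet:::label_components(m)
    lab_ref <- flood_fill_label(m)
    # same number of components, same size multiset, same largest membership
    expect_equal(max(lab_pkg), max(lab_ref))
    expect_equal(sort(tabulate(lab_pkg[lab_pkg > 0])),
                 sort(tabulate(lab_ref[lab_ref > 0])))
    sizes <- tabulate(lab_ref[lab_ref > 0])
    if (sum(sizes == max(sizes)) == 1) {
      # unique largest component: memberships must coincide exactly
      big_pkg <- lab_pkg == which.max(tabulate(lab_pkg[lab_pkg > 0]))
      big_ref <- lab_ref == which.max(sizes)
      expect_identical(big_pkg, big_ref)
    }
  }
})

test_that("contours are ordered boundary pixels of the kept component", {
  fx <- generate_garlic_image("normal", image_size = 64, seed = 12)
  seg <- segment(fx$image)
  ct <- seg$contour
  expect_true(is.matrix(ct) && ncol(ct) == 2)
  # contour pixels are foreground (coordinates are 0-based)
  for (r in seq_len(min(20, nrow(ct)))) {
    expect_equal(seg$mask[ct[r, 1] + 1, ct[r, 2] + 1], 1)
  }
  # consecutive contour pixels are 8-neighbours
  steps <- abs(diff(ct))
  expect_true(all(steps <= 1))
})
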