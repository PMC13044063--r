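test_that("confusion matrices follow the rows-actual, columns-predicted layout", {
  cm <- confusion(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(unname(diag(cm)), c(2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # binary enumeration: preds (+,+,-,-) vs truths (+,-,+,-)
  cm2 <- confusion(c("pos", "pos", "neg", "neg"),
                   c("pos", "neg", "pos", "neg"),
                   levels = c("pos", "neg"))
  expect_equal(cm2["pos", "pos"], 1L)   # TP
  expect_equal(cm2["neg", "pos"], 1L)   # FP (actual neg predicted pos)
  expect_equal(cm2["pos", "neg"], 1L)   # FN
  expect_equal(cm2["neg", "neg"], 1L)   # TN
  cm0 <- confusion(character(), character(), levels = c("a", "b"))
  expect_equal(sum(cm0), 0)
  expect_error(confusion(c("a"), c("a", "b")), class = "garlicnet_error_param")
})

test_that("metric formulas reproduce published per-class values", {
  # a class with P = 1.000 and R = 16/17 = 0.941 must give F1 = 0.970
  cm <- matrix(c(16, 1, 0,
                  0, 18, 0,
                  0, 0, 20), 3, 3, byrow = TRUE,
               dimnames = list(actual = c("local", "root", "whole"),
                               predicted = c("local", "root", "whole")))
  m <- classification_metrics(cm)
  local <- m$per_class[m$per_class$class == "local", ]
  expect_equal(local$precision, 1.000)
  expect_equal(round(local$recall, 3), 0.941)
  expect_equal(round(local$f1, 3), 0.970)
})

test_that("degenerate and symmetric confusion matrices behave as defined", {
  perfect <- diag(c(5, 7, 9))
  rownames(perfect) <- colnames(perfect) <- c("a", "b", "c")
  m <- classification_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  sym <- matrix(c(1, 1, 1, 1), 2, 2,
                dimnames = list(c("p", "n"), c("p", "n")))
  ms <- classification_metrics(sym)
  expect_equal(ms$accuracy, 0.5)
  expect_equal(ms$per_class$precision, c(0.5, 0.5))
  expect_equal(ms$per_class$f1, c(0.5, 0.5))
  # zero predicted positives: precision defined as 0, with a warning
  never <- matrix(c(0, 0, 3, 5), 2, 2,
                  dimnames = list(c("p", "n"), c("p", "n")))
  expect_warning(mz <- classification_metrics(never), "Zero denominator")
  expect_equal(mz$per_class$precision[1], 0)
})

test_that("metrics match a per-definition oracle on random matrices", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 4), k, k)
    rownames(cm) <- colnames(cm) <- paste0("c", seq_len(k))
    if (sum(cm) == 0) next
    got <- suppressWarnings(classification_metrics(cm))
    ref <- brute_metrics(cm)
    expect_equal(got$per_class$precision, ref$precision)
    expect_equal(got$per_class$recall, ref$recall)
    expect_equal(got$per_class$f1, ref$f1)
    expect_equal(got$accuracy, ref$acc[1])
  }
})

test_that("macro F1 is invariant under class relabeling", {
  set.seed(23)
  cm <- matrix(rpois(9, 5), 3, 3)
  rownames(cm) <- colnames(cm) <- c("a", "b", "c")
  m0 <- suppressWarnings(classification_metrics(cm))
  perm <- c(3, 1, 2)
  cmp <- cm[perm, perm]
  mp <- suppressWarnings(classification_metrics(cmp))
  expect_equal(mp$macro_f1, m0$macro_f1)
  expect_equal(mp$macro_precision, m0$macro_precision)
  expect_equal(mp$accuracy, m0$accuracy)
})

test_that("a zero learning rate leaves the weights untouched", {
  plan <- smoke_dataset()
  # three images per class keep this fast while covering every class
  tr <- dplyr::bind_rows(lapply(split(plan[plan$partition == "train", ],
                                      plan$class[plan$partition == "train"]),
                                head, 3))
  va <- plan[plan$partition == "val", ][1:6, ]
  net <- build_model("dh_garlicnet", num_classes = 3, width = 4,
                     input_size = 32, seed = 5)
  cfg <- train_config(input_size = 32, batch_size = 4, lr = 0, epochs = 1,
                      seed = 5)
  fit <- suppressWarnings(garlic_train(net, tr, va, cfg))
  expect_equal(fit$network$params$fc$w, net$params$fc$w)
  expect_equal(fit$network$params$stem$conv, net$params$stem$conv)
  expect_equal(nrow(fit$history), 1)
})

test_that("evaluation is deterministic and a constant predictor scores 1/3", {
  plan <- smoke_dataset()
  va <- plan[plan$partition == "val", ]
  net <- build_model("dh_garlicnet", num_classes = 3, width = 4,
                     input_size = 32, seed = 7)
  # force the head to always prefer class 1
  net$params$fc$w[] <- 0
  net$params$fc$b <- c(10, 0, 0)
  ev <- suppressWarnings(garlic_evaluate(net, va))
  expect_equal(ev$metrics$accuracy, 1 / 3, tolerance = 1e-9)
  ev2 <- suppressWarnings(garlic_evaluate(net, va))
  expect_identical(ev$confusion, ev2$confusion)
  expect_identical(ev$loss, ev2$loss)
  expect_error(garlic_evaluate(net, va[0, ]), class = "garlicnet_error_param")
})

test_that("smoke training converges on the separable synthetic classes", {
  fit <- smoke_fit()
  expect_equal(nrow(fit$history), 5)
  expect_gte(max(fit$history$val_acc), 0.95)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # held-out test partition: both metrics finite and within range
  plan <- smoke_dataset()
  te <- plan[plan$partition == "test", ]
  ev <- suppressWarnings(garlic_evaluate(fit$network, te))
  expect_true(is.finite(ev$loss))
  expect_gte(ev$metrics$accuracy, 0.9)
  # broom-style accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
})
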