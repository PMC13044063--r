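#' Training configuration
#'
#' Defaults follow the published protocol for this task: 224x224 inputs,
#' batch size 8, base learning rate 0.01, 30 epochs of stochastic gradient
#' descent with cross-entropy loss. Momentum (0.9) and weight decay (0) are
#' recorded here for reproducibility.
#'
#' @param input_size Input side in pixels.
#' @param batch_size Minibatch size.
#' @param lr Learning rate (>= 0).
#' @param epochs Number of epochs (>= 1).
#' @param momentum SGD momentum.
#' @param seed Integer seed controlling shuffling (and nothing else).
#' @return A `train_config` list.
#' @export
train_config <- function(input_size = 224L, batch_size = 8L, lr = 0.01,
                         epochs = 30L, momentum = 0.9, seed = 1L) {
  if (lr < 0 || batch_size < 1 || epochs < 1) {
    abort("`lr` must be >= 0 and `batch_size`, `epochs` >= 1.",
          class = "garlicnet_error_param")
  }
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), momentum = momentum,
                 loss = "cross_entropy", optimizer = "sgd",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Confusion matrix
#'
#' Counts with rows = actual classes and columns = predicted classes:
#' `counts[a, p]` is the number of samples of true class `a` predicted as
#' `p`. For the one-vs-rest reduction of class k, TP is the diagonal entry,
#' FN the rest of row k, FP the rest of column k, and TN everything else.
#'
#' @param preds,truths Equal-length factors (or vectors coercible to factors
#'   over the same levels).
#' @param levels Optional explicit class levels.
#' @return A `confusion_matrix`: K x K integer matrix with class dimnames.
#' @export
confusion <- function(preds, truths, levels = NULL) {
  if (length(preds) != length(truths)) {
    abort("`preds` and `truths` must have equal length.",
          class = "garlicnet_error_param")
  }
  levels <- levels %||% sort(unique(c(as.character(preds), as.character(truths))))
  p <- factor(preds, levels = levels)
  t <- factor(truths, levels = levels)
  cm <- table(actual = t, predicted = p)
  out <- matrix(as.integer(cm), nrow = length(levels),
                dimnames = list(actual = levels, predicted = levels))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the diagonal fraction; per-class precision, recall and F1 use
#' the one-vs-rest reduction (P = TP/(TP+FP), R = TP/(TP+FN),
#' F1 = 2PR/(P+R)); macro values are unweighted class means. A zero
#' denominator (e.g. a class never predicted) yields 0 with a warning.
#'
#' @param cm A [confusion()] matrix.
#' @return A `garlic_metrics` object: list with `accuracy`, `per_class`
#'   tibble (class, tp, fp, fn, tn, precision, recall, f1), and macro
#'   averages.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") || (is.matrix(cm) && nrow(cm) == ncol(cm)))
  total <- sum(cm)
  if (total == 0) abort("Empty confusion matrix.", class = "garlicnet_error_param")
  k <- nrow(cm)
  classes <- rownames(cm) %||% as.character(seq_len(k))
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / pmax(den, 1), 0)
    if (any(den == 0)) {
      warn(paste0("Zero denominator in ", what, " for class(es): ",
                  paste(classes[den == 0], collapse = ", "), "; reported as 0."))
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(
    list(
      accuracy = sum(tp) / total,
      per_class = tibble::tibble(class = classes, tp = tp, fp = fp, fn = fn,
                                 tn = tn, precision = precision,
                                 recall = recall, f1 = f1),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1),
      n = total
    ),
    class = "garlic_metrics"
  )
}

#' @export
print.garlic_metrics <- function(x, ...) {
  cat(sprintf("<garlic_metrics> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  cat(sprintf("  macro P/R/F1 = %.4f / %.4f / %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class)
  invisible(x)
}

#' @describeIn classification_metrics Per-class metric tibble.
#' @param x A `garlic_metrics`.
#' @param ... Unused.
#' @export
tidy.garlic_metrics <- function(x, ...) x$per_class

#' @describeIn classification_metrics One-row macro summary.
#' @export
glance.garlic_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1, n = x$n)
}

#' Train a garlic classifier
#'
#' Minibatch SGD with cross-entropy loss. Images are resized to the network's
#' input size once up front; every epoch reshuffles the training set
#' deterministically from the config seed, and the checkpoint with the best
#' validation accuracy is returned (ties resolved toward the earlier epoch).
#'
#' @param network A `garlic_network` from [build_model()] whose
#'   `num_classes` matches the number of class levels in the data.
#' @param train_data,val_data Tibbles with `image` (list-column of H x W x 3
#'   arrays) and `class` (factor) columns.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `garlic_fit`: list with `network` (best checkpoint), `history`
#'   tibble (epoch, train_loss, val_loss, val_acc), `best_epoch`, `config`.
#' @export
garlic_train <- function(network, train_data, val_data,
                         config = train_config(), verbose = FALSE) {
  lv <- levels(train_data$class)
  if (length(lv) != network$spec$num_classes) {
    abort("Network `num_classes` must equal the number of class levels.",
          class = "garlicnet_error_param")
  }
  if (any(table(train_data$class) == 0)) {
    abort("Every class needs at least one training sample.",
          class = "garlicnet_error_param")
  }
  network$class_names <- lv
  sz <- network$spec$input_size
  xtr <- as_batch(train_data, sz)
  ytr <- as.integer(train_data$class)
  n <- length(ytr)
  velocity <- NULL
  hist <- vector("list", config$epochs)
  best <- list(acc = -Inf, network = network, epoch = 0L)

  for (ep in seq_len(config$epochs)) {
    set.seed(config$seed + ep)
    order <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order[start:min(start + config$batch_size - 1L, n)]
      xb <- xtr[, , , idx, drop = FALSE]
      fw <- network_forward(network, xb, train = TRUE, keep_cache = TRUE)
      network <- fw$network
      ce <- softmax_ce(fw$logits, ytr[idx])
      if (!is.finite(ce$loss)) {
        abort(sprintf("Non-finite loss at epoch %d (batch starting %d).",
                      ep, start),
              class = "garlicnet_error_training")
      }
      losses <- c(losses, ce$loss)
      grads <- network_backward(network, fw$cache, ce$dlogits)
      upd <- sgd_step(network$params, grads, velocity, config$lr,
                      config$momentum)
      network$params <- upd$p
      velocity <- upd$v
    }
    ev <- garlic_evaluate(network, val_data)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = mean(losses),
      val_loss = ev$loss, val_acc = ev$metrics$accuracy
    )
    if (ev$metrics$accuracy > best$acc) {
      best <- list(acc = ev$metrics$accuracy, network = network, epoch = ep)
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  train %.4f  val %.4f  acc %.3f",
                      ep, config$epochs, mean(losses), ev$loss,
                      ev$metrics$accuracy))
    }
  }
  structure(
    list(network = best$network, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch, config = config),
    class = "garlic_fit"
  )
}

#' Evaluate a network on a labeled dataset
#'
#' Deterministic eval-mode forward (batch norm uses running statistics),
#' argmax prediction, confusion matrix, one-vs-rest metrics and mean
#' cross-entropy loss.
#'
#' @param network A `garlic_network`.
#' @param data Tibble with `image` and `class` columns (non-empty).
#' @param batch_size Evaluation batch size (memory knob only), default 32.
#' @return List with `confusion` ([confusion()] matrix), `metrics`
#'   ([classification_metrics()]) and `loss`.
#' @export
garlic_evaluate <- function(network, data, batch_size = 32L) {
  if (nrow(data) == 0) {
    abort("Cannot evaluate on an empty dataset.",
          class = "garlicnet_error_param")
  }
  lv <- levels(data$class)
  sz <- network$spec$input_size
  truths <- as.integer(data$class)
  preds <- integer(nrow(data))
  losses <- numeric(0)
  for (start in seq(1L, nrow(data), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(data))
    xb <- as_batch(data[idx, ], sz)
    fw <- network_forward(network, xb, train = FALSE)
    ce <- softmax_ce(fw$logits, truths[idx])
    losses <- c(losses, ce$loss * length(idx))
    preds[idx] <- max.col(t(fw$logits), ties.method = "first")
  }
  cm <- confusion(factor(lv[preds], levels = lv),
                  factor(lv[truths], levels = lv), levels = lv)
  list(confusion = cm, metrics = classification_metrics(cm),
       loss = sum(losses) / nrow(data))
}

#' @describeIn garlic_train Per-epoch history tibble.
#' @param x A `garlic_fit`.
#' @param ... Unused.
#' @export
tidy.garlic_fit <- function(x, ...) x$history

#' @describeIn garlic_train One-row summary (best epoch and its metrics).
#' @export
glance.garlic_fit <- function(x, ...) {
  bh <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_acc = bh$val_acc, best_val_loss = bh$val_loss,
                 final_train_loss = tail(x$history$train_loss, 1))
}

#' @describeIn garlic_train Loss/accuracy curves.
#' @param object A `garlic_fit`.
#' @export
autoplot.garlic_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("actual", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(title = "Confusion matrix (rows = actual)") +
    ggplot2::theme_minimal()
}
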