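#' Shallow neural-network classifier presets
#'
#' The classifier family used on selected deep features: the shallow wide
#' network `SWNN` has one hidden layer of 10 neurons; `MN2` (medium) one of
#' 25; `N3` (narrow) one of 100; `BiN2` (bilayered) two of 100; `TiN2`
#' (trilayered) three of 100. Layouts can be overridden.
#'
#' @param name one of `"SWNN"`, `"MN2"`, `"N3"`, `"BiN2"`, `"TiN2"`.
#' @param hidden_layout optional integer vector overriding the hidden
#'   widths.
#' @return A list of class `shallow_preset`.
#' @export
shallow_preset <- function(name = c("SWNN", "MN2", "N3", "BiN2", "TiN2"),
                           hidden_layout = NULL) {
  name <- match.arg(toupper(name), c("SWNN", "MN2", "N3", "BIN2", "TIN2"))
  name <- c(SWNN = "SWNN", MN2 = "MN2", N3 = "N3", BIN2 = "BiN2",
            TIN2 = "TiN2")[[name]]
  layout <- hidden_layout %||% switch(name,
    SWNN = 10L, MN2 = 25L, N3 = 100L, BiN2 = c(100L, 100L),
    TiN2 = c(100L, 100L, 100L))
  structure(list(name = name, hidden_layout = as.integer(layout)),
            class = "shallow_preset")
}

#' Build a shallow fully-connected classifier
#'
#' Fully-connected network with the preset's hidden layout, ReLU
#' activations and a softmax output, with seeded He initialization. Inputs
#' are z-scored using statistics learned at fit time.
#'
#' @param preset a [shallow_preset()] (or preset name).
#' @param input_width number of input features (>= 1).
#' @param classes number of classes.
#' @param seed integer seed.
#' @return A list of class `shallow_net` (untrained).
#' @export
build_classifier <- function(preset, input_width, classes, seed = 1L) {
  if (is.character(preset)) preset <- shallow_preset(preset)
  stopifnot(inherits(preset, "shallow_preset"), input_width >= 1, classes >= 2)
  widths <- c(input_width, preset$hidden_layout, classes)
  layers <- vector("list", length(widths) - 1L)
  with_seed(seed, {
    for (l in seq_along(layers)) {
      din <- widths[l]; dout <- widths[l + 1L]
      layers[[l]] <- list(W = matrix(stats::rnorm(din * dout,
                                                  sd = sqrt(2 / din)),
                                     din, dout),
                          b = numeric(dout))
    }
  })
  structure(list(preset = preset, layers = layers, classes = classes,
                 input_width = input_width, scaler = NULL, seed = seed),
            class = "shallow_net")
}

shallow_forward <- function(net, x, keep = FALSE) {
  acts <- list(x)
  h <- x
  L <- length(net$layers)
  for (l in seq_len(L)) {
    h <- fc_fwd(h, net$layers[[l]]$W, net$layers[[l]]$b)
    if (l < L) {
      h <- relu_fwd(h)
      acts[[l + 1L]] <- h
    }
  }
  p <- softmax_rows(h)
  if (keep) list(p = p, acts = acts) else p
}

#' Fit a shallow classifier by full-batch gradient descent
#'
#' Cross-entropy training with momentum 0.9; stops after `max_epochs`
#' epochs or when the loss improvement drops below `tol`.
#'
#' @param net a [build_classifier()] result.
#' @param x `N x d` feature matrix.
#' @param labels 0-based integer labels.
#' @param learning_rate step size.
#' @param max_epochs epoch cap.
#' @param tol loss-delta stopping threshold.
#' @return The trained `shallow_net`.
#' @export
fit_classifier <- function(net, x, labels, learning_rate = 0.2,
                           max_epochs = 1000L, tol = 1e-6) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd); sd[sd < 1e-12] <- 1
  net$scaler <- list(mu = mu, sd = sd)
  xs <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
  y <- one_hot(as.integer(labels), net$classes)
  vel <- lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  last <- Inf
  L <- length(net$layers)
  for (ep in seq_len(max_epochs)) {
    fw <- shallow_forward(net, xs, keep = TRUE)
    loss <- cross_entropy(fw$p, y)
    if (!is.finite(loss)) stop("classifier training diverged", call. = FALSE)
    if (abs(last - loss) < tol) break
    last <- loss
    d <- (fw$p - y) / nrow(y)
    for (l in rev(seq_len(L))) {
      r <- fc_bwd(d, fw$acts[[l]], net$layers[[l]]$W)
      vel[[l]]$W <- 0.9 * vel[[l]]$W - learning_rate * r$dW
      vel[[l]]$b <- 0.9 * vel[[l]]$b - learning_rate * r$db
      net$layers[[l]]$W <- net$layers[[l]]$W + vel[[l]]$W
      net$layers[[l]]$b <- net$layers[[l]]$b + vel[[l]]$b
      if (l > 1L) d <- relu_bwd(r$dx, fw$acts[[l]])
    }
  }
  net
}

#' Predict class probabilities from a trained shallow classifier
#'
#' @param object a trained `shallow_net`.
#' @param newdata `N x d` matrix.
#' @param ... unused.
#' @return `N x K` probability matrix.
#' @export
predict.shallow_net <- function(object, newdata, ...) {
  if (is.null(object$scaler)) stop("classifier is not fitted", call. = FALSE)
  xs <- sweep(sweep(as.matrix(newdata), 2L, object$scaler$mu), 2L,
              object$scaler$sd, "/")
  shallow_forward(object, xs)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class true-positive rate (`diag / row sum`), positive predictive
#' value (`diag / column sum`), F1 (harmonic mean of the two) and
#' false-positive rate (off-diagonal column mass over the class's
#' negatives); macro values are unweighted class means; accuracy is
#' `trace / N`. Classes with a zero denominator contribute 0 with a
#' warning. Rows index the true class, columns the prediction.
#'
#' @param confusion `K x K` non-negative integer matrix.
#' @return A list with `confusion`, `per_class` (data frame), `accuracy`,
#'   `macro_tpr`, `macro_ppv`, `macro_f1`, `macro_fpr`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion entries must be non-negative integers", call. = FALSE)
  n <- sum(confusion)
  if (n == 0) stop("confusion matrix is all zero", call. = FALSE)
  k <- nrow(confusion)
  di <- diag(confusion)
  rs <- rowSums(confusion); cs <- colSums(confusion)
  warn0 <- function(x, d, what) {
    bad <- d == 0
    if (any(bad))
      warning("zero denominator for ", what, " in class(es) ",
              paste(which(bad), collapse = ", "), "; contributing 0",
              call. = FALSE)
    ifelse(bad, 0, x / ifelse(bad, 1, d))
  }
  tpr <- warn0(di, rs, "TPR")
  ppv <- warn0(di, cs, "PPV")
  f1den <- tpr + ppv
  f1 <- ifelse(f1den == 0, 0, 2 * tpr * ppv / ifelse(f1den == 0, 1, f1den))
  fp <- cs - di
  neg <- n - rs
  fpr <- warn0(fp, neg, "FPR")
  per_class <- data.frame(class = seq_len(k) - 1L, tpr = tpr, ppv = ppv,
                          f1 = f1, fpr = fpr)
  rownames(per_class) <- NULL
  list(confusion = confusion, per_class = per_class,
       accuracy = sum(di) / n,
       macro_tpr = mean(tpr), macro_ppv = mean(ppv),
       macro_f1 = mean(f1), macro_fpr = mean(fpr))
}

# one-vs-rest macro AUC on a score matrix (columns = classes)
macro_auc <- function(scores, labels) {
  k <- ncol(scores)
  aucs <- numeric(0)
  for (c in seq_len(k)) {
    truth <- as.integer(labels == (c - 1L))
    if (length(unique(truth)) < 2L) next
    r <- pROC::roc(truth, scores[, c], quiet = TRUE, direction = "<")
    aucs <- c(aucs, as.numeric(pROC::auc(r)))
  }
  if (!length(aucs)) NA_real_ else mean(aucs)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Splits samples into stratified folds, trains the preset classifier on
#' each training fold, pools the out-of-fold predictions into a single
#' confusion matrix, and reports the evaluation metrics plus a
#' macro-averaged one-vs-rest AUC computed from the pooled softmax scores.
#' Wall-clock time is recorded for information only.
#'
#' @param features a [feature_matrix()].
#' @param preset a [shallow_preset()] or preset name (default `"SWNN"`).
#' @param folds number of folds (default 10); `folds = N` gives
#'   leave-one-out.
#' @param seed integer seed (fold assignment and weight initialization).
#' @param ... passed to [fit_classifier()].
#' @return A list of class `eval_report`: fields of
#'   [metrics_from_confusion()] plus `auc`, `time_sec`, `preset`, `folds`,
#'   `predictions` and `scores`.
#' @export
fit_predict_cv <- function(features, preset = "SWNN", folds = 10L, seed = 1L,
                           ...) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.character(preset)) preset <- shallow_preset(preset)
  x <- features$values
  labels <- features$labels
  n <- nrow(x)
  folds <- as.integer(folds)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  k <- length(unique(labels))
  if (folds < n) {
    small <- table(labels) < folds
    if (any(small))
      stop("class ", names(which(small))[1], " has fewer than `folds` members",
           call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  scores <- matrix(0, n, k)
  for (f in seq_len(folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    net <- build_classifier(preset, ncol(x), k,
                            seed = derive_seed(seed, paste0("fold", f)))
    net <- fit_classifier(net, x[tr, , drop = FALSE], labels[tr], ...)
    scores[te, ] <- predict(net, x[te, , drop = FALSE])
  }
  pred <- max.col(scores, ties.method = "first") - 1L
  confusion <- matrix(0L, k, k)
  for (i in seq_len(n))
    confusion[labels[i] + 1L, pred[i] + 1L] <-
      confusion[labels[i] + 1L, pred[i] + 1L] + 1L
  rep_ <- metrics_from_confusion(confusion)
  rep_$auc <- macro_auc(scores, labels)
  rep_$time_sec <- proc.time()[["elapsed"]] - t0
  rep_$preset <- preset$name
  rep_$folds <- folds
  rep_$predictions <- pred
  rep_$scores <- scores
  class(rep_) <- "eval_report"
  rep_
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold CV: accuracy %.3f, macro F1 %.3f, AUC %.3f (%.1fs)\n",
              x$preset %||% "?", x$folds %||% NA_integer_, x$accuracy,
              x$macro_f1, x$auc %||% NA_real_, x$time_sec %||% NA_real_))
  invisible(x)
}

#' Tidy per-class metrics of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) tibble::as_tibble(x$per_class)

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(preset = x$preset %||% NA_character_,
                 accuracy = x$accuracy, macro_tpr = x$macro_tpr,
                 macro_ppv = x$macro_ppv, macro_f1 = x$macro_f1,
                 macro_fpr = x$macro_fpr, auc = x$auc %||% NA_real_,
                 time_sec = x$time_sec %||% NA_real_)
}

#' Serialize an evaluation report to JSON
#'
#' @param x an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(x, path) {
  out <- list(preset = x$preset, folds = x$folds, accuracy = x$accuracy,
              macro_tpr = x$macro_tpr, macro_ppv = x$macro_ppv,
              macro_f1 = x$macro_f1, macro_fpr = x$macro_fpr, auc = x$auc,
              time_sec = x$time_sec, confusion = x$confusion,
              per_class = x$per_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
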