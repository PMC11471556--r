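test_that("presets carry the published hidden layouts", {
  expect_identical(shallow_preset("SWNN")$hidden_layout, 10L)
  expect_identical(shallow_preset("MN2")$hidden_layout, 25L)
  expect_identical(shallow_preset("N3")$hidden_layout, 100L)
  expect_identical(shallow_preset("BiN2")$hidden_layout, c(100L, 100L))
  expect_identical(shallow_preset("TiN2")$hidden_layout, c(100L, 100L, 100L))
  expect_error(shallow_preset("XXL"))
  # layout override
  expect_identical(shallow_preset("SWNN", c(7L, 3L))$hidden_layout, c(7L, 3L))

  net <- build_classifier("TiN2", 20L, 4L)
  expect_length(net$layers, 4L) # three hidden + output
  expect_identical(dim(net$layers[[1]]$W), c(20L, 100L))
  expect_identical(dim(net$layers[[4]]$W), c(100L, 4L))
})

test_that("confusion metrics agree with hand arithmetic and symmetry", {
  m <- metrics_from_confusion(diag(c(10, 10)))
  expect_equal(m$macro_tpr, 1)
  expect_equal(m$macro_ppv, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$macro_fpr, 0)
  expect_equal(m$accuracy, 1)

  m2 <- metrics_from_confusion(matrix(c(9, 2, 1, 8), 2, 2))
  # rows = truth: class 1 has TPR 9/10, PPV 9/11
  expect_equal(m2$per_class$tpr[1], 0.9)
  expect_equal(m2$per_class$ppv[1], 9 / 11)
  expect_equal(m2$accuracy, 17 / 20)

  # permuting class order permutes per-class rows, macro values invariant
  cm <- matrix(c(5, 1, 0, 2, 7, 1, 0, 2, 9), 3, 3)
  perm <- c(3, 1, 2)
  mp <- metrics_from_confusion(cm[perm, perm])
  mo <- metrics_from_confusion(cm)
  expect_equal(mp$macro_tpr, mo$macro_tpr)
  expect_equal(mp$macro_f1, mo$macro_f1)
  expect_equal(mp$per_class$tpr, mo$per_class$tpr[perm])

  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "all zero")
  ws <- capture_warnings(metrics_from_confusion(matrix(c(3, 0, 1, 0), 2, 2)))
  expect_true(any(grepl("zero denominator", ws)))
})

test_that("confusion metrics match a brute-force per-sample recount", {
  set.seed(20)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    n <- sample(30:200, 1)
    truth <- sample(0:(k - 1), n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.7, truth, sample(0:(k - 1), n, TRUE))
    cm <- matrix(0L, k, k)
    for (i in seq_len(n)) cm[truth[i] + 1, pred[i] + 1] <- cm[truth[i] + 1, pred[i] + 1] + 1L
    got <- suppressWarnings(metrics_from_confusion(cm))
    want <- brute_metrics(truth, pred, k)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$per_class$tpr, want$per_class$tpr)
    expect_equal(got$per_class$ppv, want$per_class$ppv)
    expect_equal(got$per_class$f1, want$per_class$f1)
    expect_equal(got$per_class$fpr, want$per_class$fpr)
  }
})

test_that("cross-validation is perfect on separable blobs and chance on shuffled labels", {
  set.seed(21)
  n <- 120L
  x <- rbind(matrix(rnorm(n / 2 * 2, mean = -4), n / 2, 2),
             matrix(rnorm(n / 2 * 2, mean = 4), n / 2, 2))
  labels <- rep(0:1, each = n / 2)
  f <- feature_matrix(x, labels)
  rep_ <- fit_predict_cv(f, "SWNN", folds = 5L, seed = 1L)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$macro_fpr, 0)
  expect_equal(rep_$auc, 1)
  # pooled confusion row sums equal true class counts
  expect_equal(rowSums(rep_$confusion), as.vector(table(labels)),
               ignore_attr = TRUE)

  # shuffled labels: accuracy near chance
  set.seed(22)
  n2 <- 400L
  x2 <- matrix(rnorm(n2 * 4), n2, 4)
  f2 <- feature_matrix(x2, sample(rep(0:1, each = n2 / 2)))
  rep2 <- fit_predict_cv(f2, "SWNN", folds = 5L, seed = 2L)
  expect_gt(rep2$accuracy, 0.5 - 0.07)
  expect_lt(rep2$accuracy, 0.5 + 0.07)
})

test_that("single-hidden-layer preset agrees with an independent nnet fit", {
  skip_if_not_installed("nnet")
  set.seed(23)
  n <- 80L
  x <- rbind(matrix(rnorm(n / 2 * 3, mean = -2), n / 2, 3),
             matrix(rnorm(n / 2 * 3, mean = 2), n / 2, 3))
  labels <- rep(0:1, each = n / 2)
  tr <- c(1:30, 41:70); te <- setdiff(seq_len(n), tr)
  net <- build_classifier("SWNN", 3L, 2L, seed = 1L)
  net <- fit_classifier(net, x[tr, ], labels[tr])
  ours <- max.col(predict(net, x[te, ])) - 1L
  ref <- nnet::nnet(x[tr, ], leafsight:::one_hot(labels[tr], 2L), size = 10,
                    softmax = TRUE, trace = FALSE, maxit = 300)
  theirs <- max.col(predict(ref, x[te, ])) - 1L
  expect_equal(mean(ours == labels[te]), 1)
  expect_equal(mean(theirs == labels[te]), 1)
  expect_equal(ours, theirs)
})

test_that("leave-one-out pools N predictions; small classes are rejected", {
  set.seed(24)
  x <- rbind(matrix(rnorm(10 * 2, -3), 10, 2), matrix(rnorm(10 * 2, 3), 10, 2))
  f <- feature_matrix(x, rep(0:1, each = 10))
  loo <- fit_predict_cv(f, "SWNN", folds = 20L, seed = 3L)
  expect_length(loo$predictions, 20L)
  expect_equal(sum(loo$confusion), 20)

  expect_error(fit_predict_cv(f, "SWNN", folds = 15L), "fewer than")

  g <- glance(loo)
  expect_identical(g$preset, "SWNN")
  expect_identical(nrow(tidy(loo)), 2L)
})

test_that("AUC of a perfect scorer is 1 and of a constant scorer 1/2", {
  labels <- rep(0:1, each = 20)
  perfect <- cbind(1 - labels, labels)
  expect_equal(leafsight:::macro_auc(perfect, labels), 1)
  constant <- matrix(0.5, 40, 2)
  expect_equal(leafsight:::macro_auc(constant, labels), 0.5)
})
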