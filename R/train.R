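#' Training configuration
#'
#' Defaults are the best hyperparameter values found by the
#' human-learning-optimization search: learning rate 0.0002, momentum
#' 0.702, minibatch 64, stochastic gradient descent with momentum, 100
#' epochs, and a stratified 60:10:30 train/validation/test split.
#'
#' @param learning_rate SGD step size.
#' @param momentum momentum coefficient.
#' @param minibatch minibatch size (>= 1).
#' @param epochs training epochs.
#' @param split length-3 train/validation/test fractions summing to 1.
#' @param clip global gradient-norm clipping threshold (`Inf` disables);
#'   stabilizes reduced-scale runs without changing well-conditioned ones.
#' @param seed integer seed controlling splitting, shuffling and weight
#'   initialization.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, momentum = 0.702,
                         minibatch = 64L, epochs = 100L,
                         split = c(train = 0.6, val = 0.1, test = 0.3),
                         clip = 5, seed = 1L) {
  stopifnot(minibatch >= 1, learning_rate >= 0, momentum >= 0, momentum < 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-8)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs), split = split, clip = clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Splits a labeled sample set 60:10:30 (by default) within each class,
#' deterministically for a given seed. Partitions are disjoint and
#' exhaustive; per-class counts respect the fractions within rounding.
#'
#' @param labels integer class labels (0-based).
#' @param cfg a [train_config()]; its `split` and `seed` are used.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, cfg = train_config()) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < 4L))
    stop("every class needs >= 4 samples; class ",
         names(tab)[which.min(tab)], " has ", min(tab), call. = FALSE)
  with_seed(cfg$seed, {
    tr <- integer(); va <- integer(); te <- integer()
    for (k in sort(unique(labels))) {
      idx <- sample(which(labels == k))
      n <- length(idx)
      n_tr <- round(cfg$split[1] * n)
      n_va <- max(1L, round(cfg$split[2] * n))
      if (n_tr + n_va >= n) n_tr <- n - n_va - 1L
      tr <- c(tr, idx[seq_len(n_tr)])
      va <- c(va, idx[n_tr + seq_len(n_va)])
      te <- c(te, idx[(n_tr + n_va + 1L):n])
    }
    list(train = sort(tr), val = sort(va), test = sort(te))
  })
}

one_hot <- function(labels, k) {
  y <- matrix(0, length(labels), k)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

cross_entropy <- function(p, y) -mean(rowSums(y * log(pmax(p, 1e-12))))

#' Train a model by minibatch SGD with momentum
#'
#' Cross-entropy training of an [architecture_graph] on labeled images.
#' Weight initialization, shuffling and the optimizer are all seeded, so a
#' fixed seed reproduces the loss history exactly. Training aborts with an
#' error naming the epoch if the loss turns non-finite.
#'
#' @param graph an [architecture_graph] whose class count matches the
#'   labels.
#' @param images list of `H x W x 3` arrays.
#' @param labels 0-based integer labels.
#' @param val_images,val_labels optional validation set.
#' @param cfg a [train_config()].
#' @return A list with the trained `model` and a `history` data frame of
#'   per-epoch training/validation loss and accuracy.
#' @export
train_model <- function(graph, images, labels, val_images = NULL,
                        val_labels = NULL, cfg = train_config()) {
  labels <- as.integer(labels)
  k <- graph$num_classes
  if (length(unique(labels)) > k)
    stop("more classes in labels than the graph head", call. = FALSE)
  side <- graph$input_shape[1]
  x <- stack_images(images, side)
  y <- one_hot(labels, k)
  n <- length(labels)
  model <- init_model(graph, seed = cfg$seed)
  vel <- list()
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_hits <- 0L
      for (start in seq(1L, n, by = cfg$minibatch)) {
        idx <- ord[start:min(start + cfg$minibatch - 1L, n)]
        xb <- x[idx, , , , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        fwd <- model_forward(model, xb, training = TRUE, keep = TRUE)
        model <- attr(fwd, "model") # refreshed BN running stats
        p <- fwd; attributes(p) <- attributes(p)["dim"]
        loss <- cross_entropy(p, yb)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
        ep_hits <- ep_hits + sum(max.col(p) == max.col(yb))
        dlogits <- (p - yb) / nrow(p)
        grads <- model_backward(model, fwd, dlogits)
        clip <- cfg$clip %||% Inf
        if (is.finite(clip)) {
          sq <- 0
          for (nm in names(grads)) for (fld in names(grads[[nm]]))
            sq <- sq + sum(grads[[nm]][[fld]]^2)
          gnorm <- sqrt(sq)
          if (!is.finite(gnorm))
            stop("training diverged (non-finite gradient) at epoch ", ep,
                 call. = FALSE)
          if (gnorm > clip)
            for (nm in names(grads)) for (fld in names(grads[[nm]]))
              grads[[nm]][[fld]] <- grads[[nm]][[fld]] * (clip / gnorm)
        }
        for (nm in names(grads)) {
          for (fld in names(grads[[nm]])) {
            key <- paste0(nm, ".", fld)
            g <- grads[[nm]][[fld]]
            v <- vel[[key]] %||% (g * 0)
            v <- cfg$momentum * v - cfg$learning_rate * g
            vel[[key]] <- v
            model$weights[[nm]][[fld]] <- model$weights[[nm]][[fld]] + v
          }
        }
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                        train_acc = ep_hits / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(val_images) && length(val_images)) {
        pv <- predict_model(model, val_images)
        row$val_loss <- cross_entropy(pv, one_hot(as.integer(val_labels), k))
        row$val_acc <- mean(max.col(pv) == as.integer(val_labels) + 1L)
      }
      history <- rbind(history, row)
    }
  })
  list(model = model, history = history)
}

#' Extract deep features at the self-attention tap
#'
#' Forwards images through a trained model and returns the self-attention
#' layer's activations: `N x 1024` for the bottleneck-residual model and
#' `N x 512` for the inverted-bottleneck model.
#'
#' @param model a `leaf_model`.
#' @param images list of `H x W x 3` arrays.
#' @param labels optional 0-based labels carried into the result.
#' @param batch internal forward batch size.
#' @return A [feature_matrix()] with columns tagged by the model name.
#' @export
extract_features <- function(model, images, labels = NULL, batch = 8L) {
  side <- model$graph$input_shape[1]
  n <- length(images)
  width <- extract_feature_width(model$graph)
  vals <- matrix(0, n, width)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    x <- stack_images(images[idx], side)
    out <- model_forward(model, x, training = FALSE, tap = "attention")
    vals[idx, ] <- attr(out, "tap")
  }
  if (is.null(labels)) labels <- rep(0L, n)
  feature_matrix(vals, labels,
                 paste0(model$graph$name, "_f", seq_len(width)))
}
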