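# Shared small fixtures, built in code at load time.

# brute-force sliding-window dark channel, the oracle for dark_channel()
brute_dark_channel <- function(image, patch) {
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- (patch - 1) %/% 2
  cm <- pmin(image[, , 1], image[, , 2], image[, , 3])
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ys <- max(1, i - r):min(h, i + r)
    xs <- max(1, j - r):min(w, j + r)
    out[i, j] <- min(cm[ys, xs])
  }
  out
}

# constant-color image helper
const_image <- function(rgb, side = 8L) {
  image_rgb(array(rep(rgb, each = side * side), c(side, side, 3L)))
}

# brute-force per-sample metric recount, the oracle for
# metrics_from_confusion()
brute_metrics <- function(truth, pred, k) {
  per <- data.frame(tpr = numeric(k), ppv = numeric(k), f1 = numeric(k),
                    fpr = numeric(k))
  for (c in seq_len(k) - 1L) {
    tp <- sum(truth == c & pred == c)
    fn <- sum(truth == c & pred != c)
    fp <- sum(truth != c & pred == c)
    tn <- sum(truth != c & pred != c)
    tpr <- if (tp + fn == 0) 0 else tp / (tp + fn)
    ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
    per$tpr[c + 1] <- tpr
    per$ppv[c + 1] <- ppv
    per$f1[c + 1] <- if (tpr + ppv == 0) 0 else 2 * tpr * ppv / (tpr + ppv)
    per$fpr[c + 1] <- if (fp + tn == 0) 0 else fp / (fp + tn)
  }
  list(per_class = per, accuracy = mean(truth == pred))
}

# tiny labeled image set for training-path tests
tiny_image_set <- function(classes = 3L, per_class = 8L, side = 32L,
                           seed = 7L) {
  make_leaf_images(classes = classes, per_class = per_class, side = side,
                   disease_contrast = 0.8, seed = seed)
}
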