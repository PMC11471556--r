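#' Synthetic leaf-image generator
#'
#' Produces class-conditional leaf-like RGB images: a textured dark
#' background, an elliptical green leaf, and class-specific disease blobs
#' whose count, size and hue differ by class while the leaf shape does not —
#' so the classification signal lives in the (optionally low-contrast)
#' disease region. Optionally the haze model `I = J t + (1 - t)` with white
#' airlight is applied forward at a constant transmission, giving fixtures
#' with a known clean ground truth for dehazing tests.
#'
#' @param classes number of classes (>= 2).
#' @param per_class images per class (>= 4).
#' @param side image side in pixels (>= 32).
#' @param disease_contrast blob-to-leaf contrast in `(0, 1]`; small values
#'   emulate the low-contrast symptoms the enhancement stage targets.
#' @param haze_t optional constant transmission in `(0, 1]`; `NULL` for no
#'   haze.
#' @param seed integer seed; the output is bit-reproducible per seed.
#' @return A list with `images` (list of `side x side x 3` arrays), `labels`
#'   (0-based integer), `masks` (list of logical disease masks), `classes`
#'   (character names) and, when hazed, `clean` (the pre-haze images).
#' @export
make_leaf_images <- function(classes = 4L, per_class = 10L, side = 64L,
                             disease_contrast = 0.3, haze_t = NULL,
                             seed = 1L) {
  stopifnot(classes >= 2, per_class >= 4, side >= 32,
            disease_contrast > 0, disease_contrast <= 1)
  if (!is.null(haze_t)) stopifnot(haze_t > 0, haze_t <= 1)
  with_seed(seed, {
    images <- vector("list", classes * per_class)
    masks <- vector("list", classes * per_class)
    labels <- integer(classes * per_class)
    xg <- matrix(rep(seq_len(side), each = side), side, side)
    yg <- matrix(rep(seq_len(side), side), side, side)
    cx <- side / 2; cy <- side / 2
    i <- 0L
    for (k in seq_len(classes)) {
      # class-specific blob statistics
      n_blob <- 1L + k
      blob_r <- side / (14 - min(k, 6))
      hue_shift <- c(0.12 * k, -0.05 * k, 0.02 * k)
      for (j in seq_len(per_class)) {
        i <- i + 1L
        bg <- 0.18 + 0.05 * matrix(stats::rnorm(side^2), side, side)
        img <- array(0, c(side, side, 3))
        img[, , 1] <- bg * 0.9; img[, , 2] <- bg; img[, , 3] <- bg * 0.8
        # elliptical leaf, fixed shape across classes, slight jitter
        ax <- side * (0.34 + stats::runif(1, -0.02, 0.02))
        ay <- side * (0.42 + stats::runif(1, -0.02, 0.02))
        leaf <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 <= 1
        tex <- 0.04 * matrix(stats::rnorm(side^2), side, side)
        leaf_col <- c(0.20, 0.45, 0.18)
        for (c in 1:3)
          img[, , c][leaf] <- leaf_col[c] + tex[leaf]
        # class-specific disease blobs inside the leaf
        mask <- matrix(FALSE, side, side)
        for (b in seq_len(n_blob)) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, 0.55)
          bx <- cx + rad * ax * cos(ang); by <- cy + rad * ay * sin(ang)
          br <- blob_r * stats::runif(1, 0.7, 1.3)
          blob <- (xg - bx)^2 + (yg - by)^2 <= br^2
          mask <- mask | (blob & leaf)
        }
        for (c in 1:3)
          img[, , c][mask] <- clip01(leaf_col[c] +
                                       disease_contrast * hue_shift[c] +
                                       tex[mask])
        img <- clip01(img)
        images[[i]] <- img
        masks[[i]] <- mask
        labels[i] <- k - 1L
      }
    }
    out <- list(images = images, labels = labels, masks = masks,
                classes = paste0("class", seq_len(classes) - 1L))
    if (!is.null(haze_t)) {
      out$clean <- images
      out$images <- lapply(images, synthesize_haze, t = haze_t)
    }
    out
  })
}

#' Synthetic feature-matrix generator
#'
#' Builds an `n x (informative + redundant + noise)` feature matrix with a
#' known ground truth: informative columns carry class-dependent Gaussian
#' means placed on an equally spaced grid (adjacent class means separated by
#' `effect_size` noise standard deviations, class order permuted per
#' column); redundant columns are noisy linear copies of randomly chosen
#' informative columns (copy noise sd `copy_noise`); noise columns are
#' class-independent standard normals. Columns are tagged
#' `informative*`, `redundant*_of_*`, `noise*`.
#'
#' @param n number of samples (split as evenly as possible over classes).
#' @param classes number of classes.
#' @param informative,redundant,noise column counts per role.
#' @param effect_size class-mean separation in noise-sd units (> 0).
#' @param copy_noise sd of the perturbation added to redundant copies.
#' @param seed integer seed.
#' @return A list with `features` (a [feature_matrix()]) and
#'   `informative_idx` (columns carrying class signal directly).
#' @export
make_feature_matrix <- function(n = 300L, classes = 3L, informative = 5L,
                                redundant = 10L, noise = 25L,
                                effect_size = 2, copy_noise = 0.1,
                                seed = 1L) {
  stopifnot(informative >= 1, effect_size > 0, classes >= 2, n >= classes)
  with_seed(seed, {
    labels <- rep(seq_len(classes) - 1L, length.out = n)
    m <- informative + redundant + noise
    vals <- matrix(0, n, m)
    tags <- character(m)
    for (j in seq_len(informative)) {
      ord <- sample(classes)
      mu <- effect_size * (ord - (classes + 1) / 2)
      vals[, j] <- mu[labels + 1L] + stats::rnorm(n)
      tags[j] <- paste0("informative", j)
    }
    src <- integer(redundant)
    for (j in seq_len(redundant)) {
      src[j] <- sample.int(informative, 1L)
      vals[, informative + j] <- vals[, src[j]] + copy_noise * stats::rnorm(n)
      tags[informative + j] <- paste0("redundant", j, "_of_", src[j])
    }
    for (j in seq_len(noise)) {
      vals[, informative + redundant + j] <- stats::rnorm(n)
      tags[informative + redundant + j] <- paste0("noise", j)
    }
    list(features = feature_matrix(vals, labels, tags),
         informative_idx = seq_len(informative),
         redundant_src = src)
  })
}

#' Write synthetic leaf images as a directory-per-class PNG tree
#'
#' @param set output of [make_leaf_images()].
#' @param dir output root.
#' @return invisibly, the written file paths.
#' @export
write_leaf_images <- function(set, dir) {
  paths <- character(length(set$images))
  for (i in seq_along(set$images)) {
    cls <- set$classes[set$labels[i] + 1L]
    d <- file.path(dir, cls)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(d, sprintf("img%04d.png", i))
    write_image(set$images[[i]], paths[i])
  }
  invisible(paths)
}
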