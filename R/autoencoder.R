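#' Augmentation configuration
#'
#' @param target_per_class generated images per class (default 1000, the
#'   per-class count the balanced datasets are brought to).
#' @param latent_dim latent width of the autoencoder (default 64).
#' @param epochs training epochs (default 30).
#' @param noise_scale sd of the latent perturbation used to generate
#'   variants (default 0.1; 0 reproduces plain reconstructions).
#' @param learning_rate SGD step size for autoencoder training.
#' @param image_side training/generation resolution (default 64).
#' @param seed integer seed.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(target_per_class = 1000L, latent_dim = 64L,
                           epochs = 30L, noise_scale = 0.1,
                           learning_rate = 0.05, image_side = 64L,
                           seed = 1L) {
  stopifnot(target_per_class >= 1, latent_dim >= 1, epochs >= 1,
            noise_scale >= 0, image_side >= 16)
  structure(list(target_per_class = as.integer(target_per_class),
                 latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs), noise_scale = noise_scale,
                 learning_rate = learning_rate,
                 image_side = as.integer(image_side),
                 seed = as.integer(seed)),
            class = "augment_config")
}

# Small convolutional autoencoder at cfg$image_side resolution.
# Encoder: conv(3->8, 3x3/2) relu, conv(8->16, 3x3/2) relu, flatten,
#          fc -> latent.
# Decoder: fc -> (side/4)^2 x 16, relu, nearest-upsample x2, conv(16->8),
#          relu, nearest-upsample x2, conv(8->3), sigmoid.
ae_init <- function(side, latent, seed) {
  s4 <- side %/% 4L
  with_seed(seed, {
    rn <- function(n, sd) stats::rnorm(n, sd = sd)
    list(
      e1 = list(W = array(rn(3 * 3 * 3 * 8, sqrt(2 / 27)), c(3, 3, 3, 8)), b = numeric(8)),
      e2 = list(W = array(rn(3 * 3 * 8 * 16, sqrt(2 / 72)), c(3, 3, 8, 16)), b = numeric(16)),
      ef = list(W = matrix(rn(s4 * s4 * 16 * latent, sqrt(1 / (s4 * s4 * 16))),
                           s4 * s4 * 16, latent), b = numeric(latent)),
      df = list(W = matrix(rn(latent * s4 * s4 * 16, sqrt(1 / latent)),
                           latent, s4 * s4 * 16), b = numeric(s4 * s4 * 16)),
      d1 = list(W = array(rn(3 * 3 * 16 * 8, sqrt(2 / 144)), c(3, 3, 16, 8)), b = numeric(8)),
      d2 = list(W = array(rn(3 * 3 * 8 * 3, sqrt(2 / 72)), c(3, 3, 8, 3)), b = numeric(3)),
      side = side, s4 = s4, latent = latent)
  })
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  H <- d[2] %/% 2L; W <- d[3] %/% 2L
  o <- array(0, c(d[1], H, W, d[4]))
  for (dy in 1:2) for (dx in 1:2)
    o <- o + dout[, seq(dy, d[2], by = 2L), seq(dx, d[3], by = 2L), ,
                  drop = FALSE]
  o
}

sigmoid <- function(x) 1 / (1 + exp(-x))

ae_encode <- function(ae, x, cache = FALSE) {
  h1 <- conv_fwd(x, ae$e1$W, ae$e1$b, 2L, cache = cache); a1 <- relu_fwd(h1)
  h2 <- conv_fwd(a1, ae$e2$W, ae$e2$b, 2L, cache = cache); a2 <- relu_fwd(h2)
  fl <- flatten_fwd(a2)
  z <- fc_fwd(fl, ae$ef$W, ae$ef$b)
  if (cache) list(z = z, h1 = h1, a1 = a1, h2 = h2, a2 = a2, fl = fl, x = x)
  else z
}

ae_decode <- function(ae, z, cache = FALSE) {
  n <- nrow(z)
  hf <- fc_fwd(z, ae$df$W, ae$df$b); af <- relu_fwd(hf)
  g <- array(af, c(n, ae$s4, ae$s4, 16L))
  u1 <- upsample2_fwd(g)
  h3 <- conv_fwd(u1, ae$d1$W, ae$d1$b, 1L, cache = cache); a3 <- relu_fwd(h3)
  u2 <- upsample2_fwd(a3)
  h4 <- conv_fwd(u2, ae$d2$W, ae$d2$b, 1L, cache = cache)
  y <- sigmoid(h4)
  if (cache) list(y = y, hf = hf, af = af, u1 = u1, h3 = h3, a3 = a3,
                  u2 = u2, h4 = h4, z = z)
  else y
}

ae_step <- function(ae, x, lr, vel = NULL, momentum = 0.9) {
  enc <- ae_encode(ae, x, cache = TRUE)
  dec <- ae_decode(ae, enc$z, cache = TRUE)
  n <- dim(x)[1]
  resid <- dec$y - x
  loss <- mean(resid^2)
  # d loss / d h4 through sigmoid
  dh4 <- (2 / length(resid)) * resid * dec$y * (1 - dec$y)
  r4 <- conv_bwd(dh4, ae$d2$W, attr(dec$h4, "cache"))
  du2 <- r4$dx
  da3 <- upsample2_bwd(du2)
  dh3 <- relu_bwd(da3, dec$h3)
  r3 <- conv_bwd(dh3, ae$d1$W, attr(dec$h3, "cache"))
  du1 <- r3$dx
  dg <- upsample2_bwd(du1)
  daf <- matrix(dg, n, ae$s4 * ae$s4 * 16L)
  dhf <- relu_bwd(daf, dec$hf)
  rf <- fc_bwd(dhf, dec$z, ae$df$W)
  dz <- rf$dx
  re <- fc_bwd(dz, enc$fl, ae$ef$W)
  da2 <- array(re$dx, dim(enc$a2))
  dh2 <- relu_bwd(da2, enc$h2)
  r2 <- conv_bwd(dh2, ae$e2$W, attr(enc$h2, "cache"))
  dh1 <- relu_bwd(r2$dx, enc$h1)
  r1 <- conv_bwd(dh1, ae$e1$W, attr(enc$h1, "cache"))
  if (is.null(vel))
    vel <- lapply(ae[c("e1", "e2", "ef", "df", "d1", "d2")],
                  function(p) list(W = p$W * 0, b = p$b * 0))
  gr <- list(e1 = r1, e2 = r2, ef = re, df = rf, d1 = r3, d2 = r4)
  for (nm in names(gr)) {
    vel[[nm]]$W <- momentum * vel[[nm]]$W - lr * gr[[nm]]$dW
    vel[[nm]]$b <- momentum * vel[[nm]]$b - lr * gr[[nm]]$db
    ae[[nm]]$W <- ae[[nm]]$W + vel[[nm]]$W
    ae[[nm]]$b <- ae[[nm]]$b + vel[[nm]]$b
  }
  list(ae = ae, vel = vel, loss = loss)
}

#' Train a convolutional autoencoder on a class of images
#'
#' Minibatch gradient descent on mean squared reconstruction error at
#' `image_side` resolution. Deterministic for a fixed seed.
#'
#' @param images list of `H x W x 3` arrays (>= 2).
#' @param cfg an [augment_config()].
#' @return A list with the trained autoencoder (`ae`) and the per-epoch
#'   reconstruction `loss` vector.
#' @export
train_autoencoder <- function(images, cfg = augment_config()) {
  if (length(images) < 2L)
    stop("need at least 2 images to train the autoencoder", call. = FALSE)
  side <- cfg$image_side
  x <- stack_images(images, side)
  ae <- ae_init(side, cfg$latent_dim, cfg$seed)
  n <- dim(x)[1]
  losses <- numeric(cfg$epochs)
  vel <- NULL
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      tot <- 0
      for (start in seq(1L, n, by = 16L)) {
        idx <- ord[start:min(start + 15L, n)]
        st <- ae_step(ae, x[idx, , , , drop = FALSE], cfg$learning_rate, vel)
        ae <- st$ae
        vel <- st$vel
        tot <- tot + st$loss * length(idx)
      }
      losses[ep] <- tot / n
    }
  })
  list(ae = ae, loss = losses)
}

#' Generate a balanced class by autoencoder resampling
#'
#' Trains (or reuses) an autoencoder on the class images, then expands the
#' class to exactly `target_per_class` images by passing each source image
#' through the encoder, perturbing its latent code with Gaussian noise of
#' sd `noise_scale`, and decoding. Passes are allocated round-robin: with
#' `n` sources and target `T`, every image receives `floor(T/n)` passes and
#' the first `T mod n` images one extra — for example 64 sources and target
#' 1000 give per-source counts of 15 or 16, and 500 sources doubling to
#' 1000 give exactly 2 each.
#'
#' @param images list of class images (each `H x W x 3`).
#' @param cfg an [augment_config()].
#' @param trained optional result of [train_autoencoder()] to reuse.
#' @return A list with `images` (exactly `target_per_class` generated
#'   arrays at `image_side`), `source` (index of the source image of each
#'   variant) and `loss` (training loss curve).
#' @export
generate_class <- function(images, cfg = augment_config(), trained = NULL) {
  n <- length(images)
  if (cfg$target_per_class < n)
    stop("`target_per_class` (", cfg$target_per_class,
         ") is below the class size (", n, ")", call. = FALSE)
  if (is.null(trained)) trained <- train_autoencoder(images, cfg)
  ae <- trained$ae
  x <- stack_images(images, cfg$image_side)
  z <- ae_encode(ae, x)
  base <- cfg$target_per_class %/% n
  extra <- cfg$target_per_class %% n
  passes <- rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
  out <- vector("list", cfg$target_per_class)
  src <- integer(cfg$target_per_class)
  i <- 0L
  with_seed(cfg$seed + 2L, {
    for (s in seq_len(n)) {
      if (passes[s] == 0L) next
      zz <- matrix(z[s, ], passes[s], ncol(z), byrow = TRUE)
      if (cfg$noise_scale > 0)
        zz <- zz + cfg$noise_scale * matrix(stats::rnorm(length(zz)),
                                            nrow(zz), ncol(zz))
      y <- ae_decode(ae, zz)
      for (p in seq_len(passes[s])) {
        i <- i + 1L
        out[[i]] <- clip01(array(y[p, , , ], dim(y)[2:4]))
        src[i] <- s
      }
    }
  })
  list(images = out, source = src, loss = trained$loss)
}

#' Balance a directory-per-class tree by autoencoder augmentation
#'
#' @param in_dir input root (one subdirectory per class).
#' @param out_dir output root; receives `target_per_class` PNGs per class.
#' @param cfg an [augment_config()].
#' @return invisibly, a named vector of per-class output counts.
#' @export
augment_dir <- function(in_dir, out_dir, cfg = augment_config()) {
  classes <- sort(list.dirs(in_dir, recursive = FALSE, full.names = FALSE))
  counts <- integer(length(classes)); names(counts) <- classes
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    fs <- sort(list.files(file.path(in_dir, cls),
                          pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                          full.names = TRUE))
    imgs <- lapply(fs, read_image)
    ccfg <- cfg
    ccfg$seed <- derive_seed(cfg$seed, cls)
    gen <- generate_class(imgs, ccfg)
    d <- file.path(out_dir, cls)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(gen$images))
      write_image(gen$images[[i]], file.path(d, sprintf("aug%04d.png", i)))
    counts[ci] <- length(gen$images)
  }
  invisible(counts)
}
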