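#' Configuration for dark-channel-prior dehazing
#'
#' The haze model is `I(X) = J(X) t(X) + L (1 - t(X))`: the observed image
#' `I` mixes the scene radiance `J` with the global atmospheric light `L`
#' according to the per-pixel transmission `t`. Restoration estimates `t`
#' from the dark channel and inverts the model with a floored transmission.
#'
#' @param a static additive offset used by the `"offset"` recovery form
#'   (default 0.2).
#' @param t0 transmission floor in `(0, 1]` (default 0.1).
#' @param omega haze retention factor in `(0, 1]` used during transmission
#'   estimation (default 0.95); a value below 1 leaves a trace of haze so
#'   restored images keep depth cues.
#' @param patch odd dark-channel window side in pixels (default 15).
#' @return A list of class `haze_config`.
#' @export
haze_config <- function(a = 0.2, t0 = 0.1, omega = 0.95, patch = 15L) {
  stopifnot(t0 > 0, t0 <= 1, omega > 0, omega <= 1, a >= 0, a < 1)
  patch <- as.integer(patch)
  if (patch < 1L || patch %% 2L == 0L)
    stop("`patch` must be odd and >= 1", call. = FALSE)
  structure(list(a = a, t0 = t0, omega = omega, patch = patch),
            class = "haze_config")
}

#' Configuration for bi-histogram equalization
#'
#' @param bins histogram bin count (default 256).
#' @param sigma Gaussian smoothing width of the histogram, in bins
#'   (default 3).
#' @param min_peak_separation minimum distance between detected histogram
#'   peaks, in bins (default 8).
#' @param brightness_target if `TRUE` (default) the output mean luminance is
#'   normalized back to the input mean.
#' @return A list of class `bihe_config`.
#' @export
bihe_config <- function(bins = 256L, sigma = 3, min_peak_separation = 8L,
                        brightness_target = TRUE) {
  stopifnot(bins >= 2, sigma > 0, min_peak_separation >= 1)
  structure(list(bins = as.integer(bins), sigma = sigma,
                 min_peak_separation = as.integer(min_peak_separation),
                 brightness_target = isTRUE(brightness_target)),
            class = "bihe_config")
}

# separable sliding-window minimum with truncated borders
window_min <- function(mat, patch) {
  r <- (patch - 1L) %/% 2L
  if (r == 0L) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  # rows
  out <- mat
  for (d in seq_len(r)) {
    out[(1 + d):h, ] <- pmin(out[(1 + d):h, , drop = FALSE],
                             mat[1:(h - d), , drop = FALSE])
    out[1:(h - d), ] <- pmin(out[1:(h - d), , drop = FALSE],
                             mat[(1 + d):h, , drop = FALSE])
  }
  # columns
  mat2 <- out
  for (d in seq_len(r)) {
    out[, (1 + d):w] <- pmin(out[, (1 + d):w, drop = FALSE],
                             mat2[, 1:(w - d), drop = FALSE])
    out[, 1:(w - d)] <- pmin(out[, 1:(w - d), drop = FALSE],
                             mat2[, (1 + d):w, drop = FALSE])
  }
  out
}

#' Dark channel of an RGB image
#'
#' The dark channel is the per-pixel minimum over color channels followed by
#' a sliding-window minimum over a `patch x patch` neighborhood (truncated at
#' image borders). Haze-free patches of natural images tend to contain
#' near-zero dark-channel values, so large values indicate airlight.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param patch odd window side, at most `min(H, W)`.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
dark_channel <- function(image, patch = 15L) {
  image <- image_rgb(image)
  patch <- as.integer(patch)
  if (patch %% 2L == 0L) stop("`patch` must be odd", call. = FALSE)
  if (patch > min(dim(image)[1:2]))
    stop("`patch` larger than image", call. = FALSE)
  window_min(pmin(image[, , 1], image[, , 2], image[, , 3]), patch)
}

#' Estimate global atmospheric light
#'
#' Takes the mean color of the pixels whose dark-channel value falls in the
#' brightest 0.1 % (at least one pixel).
#'
#' @param image `H x W x 3` array.
#' @param dark dark-channel map computed from `image`.
#' @return length-3 numeric vector in `[0, 1]`.
#' @export
estimate_atmospheric_light <- function(image, dark) {
  image <- image_rgb(image)
  stopifnot(all(dim(dark) == dim(image)[1:2]))
  n_top <- max(1L, floor(length(dark) * 0.001))
  thr <- sort(as.vector(dark), decreasing = TRUE)[n_top]
  idx <- which(dark >= thr)
  vapply(1:3, function(c) mean(image[, , c][idx]), numeric(1))
}

#' Estimate the transmission map
#'
#' `T = 1 - omega * dark_channel(I / L)`, clamped so values stay in
#' `[1 - omega, 1]`.
#'
#' @param image `H x W x 3` array.
#' @param L atmospheric light, length-3, all components positive.
#' @param cfg a [haze_config()].
#' @return `H x W` matrix.
#' @export
estimate_transmission <- function(image, L, cfg = haze_config()) {
  image <- image_rgb(image)
  if (any(L <= 0)) stop("atmospheric light components must be positive", call. = FALSE)
  norm <- array(0, dim(image))
  for (c in 1:3) norm[, , c] <- pmin(1, image[, , c] / L[c])
  dn <- window_min(pmin(norm[, , 1], norm[, , 2], norm[, , 3]), cfg$patch)
  1 - cfg$omega * dn
}

#' Dehaze an image
#'
#' Estimates the dark channel, atmospheric light and transmission, then
#' inverts the haze model with a floored transmission. Two recovery forms are
#' available: `"airlight"` (default) subtracts and restores the estimated
#' atmospheric light per channel, `J = (I - L) / max(T, t0) + L`, which
#' inverts a forward haze synthesis; `"offset"` uses the static scalar
#' offset `a` in both roles, `J = (I - a) / max(T, t0) + a`. Outputs are
#' clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array.
#' @param cfg a [haze_config()].
#' @param recovery `"airlight"` or `"offset"`.
#' @return dehazed `H x W x 3` array.
#' @export
dehaze <- function(image, cfg = haze_config(),
                   recovery = c("airlight", "offset")) {
  image <- image_rgb(image)
  recovery <- match.arg(recovery)
  # clamp the window to the image so small images remain processable
  eff <- min(cfg$patch, min(dim(image)[1:2]))
  if (eff %% 2L == 0L) eff <- eff - 1L
  cfg$patch <- as.integer(eff)
  dk <- dark_channel(image, cfg$patch)
  L <- estimate_atmospheric_light(image, dk)
  Tmap <- estimate_transmission(image, pmax(L, 1e-6), cfg)
  Tf <- pmax(Tmap, cfg$t0)
  out <- array(0, dim(image))
  for (c in 1:3) {
    offs <- if (recovery == "airlight") L[c] else cfg$a
    out[, , c] <- (image[, , c] - offs) / Tf + offs
  }
  clip01(out)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_histogram <- function(counts, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  padded <- c(rep(0, r), counts, rep(0, r))
  stats::convolve(padded, rev(k), type = "filter")
}

# leftmost-of-plateau local maxima, then greedy suppression by height
find_peaks <- function(h, min_sep) {
  n <- length(h)
  if (n < 3L) return(integer())
  prev <- c(-Inf, h[-n]); nxt <- c(h[-1], -Inf)
  cand <- which(h > prev & h >= nxt)
  cand <- cand[order(h[cand], decreasing = TRUE)]
  kept <- integer()
  for (p in cand)
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  sort(kept)
}

#' Bi-histogram equalization
#'
#' Contrast enhancement in five steps: (i) the luminance histogram is
#' Gaussian-smoothed; (ii) local maxima of the smoothed histogram are
#' detected; (iii) the maxima partition the intensity axis into sub-ranges,
#' each allocated its own output dynamic range (its input span);
#' (iv) each sub-histogram is equalized independently (midpoint-CDF
#' convention); (v) the output mean luminance is normalized back to the
#' input mean. Chrominance is preserved by rescaling RGB with the luminance
#' ratio. Constant images are returned unchanged.
#'
#' The number of non-empty sub-histograms that were equalized is attached as
#' attribute `"partitions"`.
#'
#' @param image `H x W x 3` array.
#' @param cfg a [bihe_config()].
#' @return enhanced `H x W x 3` array.
#' @export
bihe <- function(image, cfg = bihe_config()) {
  image <- image_rgb(image)
  y <- luminance(image)
  if (diff(range(y)) < 1e-12) {
    attr(image, "partitions") <- 0L
    return(image)
  }
  bins <- cfg$bins
  # bin index of each pixel on [0, 1]
  bi <- pmin(bins, pmax(1L, floor(y * bins) + 1L))
  counts <- tabulate(bi, nbins = bins)
  sm <- smooth_histogram(counts, cfg$sigma)
  peaks <- find_peaks(sm, cfg$min_peak_separation)
  # segment boundaries: [1, p1), [p1, p2), ..., [pk, bins]
  lo <- c(1L, peaks)
  hi <- c(peaks - 1L, bins)
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  map <- numeric(bins)
  n_nonempty <- 0L
  for (s in seq_along(lo)) {
    rng <- lo[s]:hi[s]
    cs <- counts[rng]
    tot <- sum(cs)
    out_lo <- (lo[s] - 1) / bins
    out_hi <- hi[s] / bins
    if (tot == 0) {
      map[rng] <- (rng - 0.5) / bins # identity for empty segments
      next
    }
    n_nonempty <- n_nonempty + 1L
    cdf_mid <- (cumsum(cs) - cs / 2) / tot
    map[rng] <- out_lo + cdf_mid * (out_hi - out_lo)
  }
  y2 <- matrix(map[bi], nrow(y), ncol(y))
  if (cfg$brightness_target) y2 <- y2 + (mean(y) - mean(y2))
  y2 <- clip01(y2)
  ratio <- y2 / pmax(y, 1e-6)
  out <- array(0, dim(image))
  for (c in 1:3) out[, , c] <- clip01(image[, , c] * ratio)
  attr(out, "partitions") <- n_nonempty
  out
}

#' Hybrid contrast enhancement
#'
#' Dark-channel dehazing followed by bi-histogram equalization, the
#' enhancement chain applied to every image before augmentation and
#' training. Deterministic for fixed input and configuration.
#'
#' @param image `H x W x 3` array.
#' @param haze_cfg a [haze_config()].
#' @param bihe_cfg a [bihe_config()].
#' @param recovery passed to [dehaze()].
#' @return enhanced `H x W x 3` array.
#' @export
enhance <- function(image, haze_cfg = haze_config(), bihe_cfg = bihe_config(),
                    recovery = c("airlight", "offset")) {
  bihe(dehaze(image, haze_cfg, recovery), bihe_cfg)
}

#' Forward haze synthesis
#'
#' Applies the haze model `I = J t + L (1 - t)` with a constant transmission,
#' used to fabricate hazy fixtures with a known ground truth.
#'
#' @param image clean image `J`.
#' @param t constant transmission in `(0, 1]`.
#' @param L atmospheric light (length 3 or scalar), default white.
#' @export
synthesize_haze <- function(image, t, L = c(1, 1, 1)) {
  image <- image_rgb(image)
  stopifnot(t > 0, t <= 1)
  if (length(L) == 1L) L <- rep(L, 3L)
  out <- array(0, dim(image))
  for (c in 1:3) out[, , c] <- image[, , c] * t + L[c] * (1 - t)
  clip01(out)
}

#' Batch enhancement over a directory tree
#'
#' Mirrors an input directory-per-class tree to an output tree, enhancing
#' every PNG/JPEG image.
#'
#' @param in_dir,out_dir input and output roots.
#' @inheritParams enhance
#' @return invisibly, the vector of written paths.
#' @export
enhance_dir <- function(in_dir, out_dir, haze_cfg = haze_config(),
                        bihe_cfg = bihe_config(),
                        recovery = c("airlight", "offset")) {
  recovery <- match.arg(recovery)
  fs <- list.files(in_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                   recursive = TRUE)
  written <- character(length(fs))
  for (i in seq_along(fs)) {
    img <- read_image(file.path(in_dir, fs[i]))
    enh <- enhance(img, haze_cfg, bihe_cfg, recovery)
    dest <- file.path(out_dir, fs[i])
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    write_image(enh, dest)
    written[i] <- dest
  }
  invisible(written)
}
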