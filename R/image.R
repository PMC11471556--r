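#' RGB image containers and file I/O
#'
#' Images are plain numeric arrays of dimension `H x W x 3` with intensities
#' in `[0, 1]`. `image_rgb()` validates and normalizes an array into this
#' form; `read_image()`/`write_image()` handle PNG and JPEG files, quantizing
#' to 8 bits on write by round-half-up.
#'
#' @param pixels numeric array `H x W x 3` (a `H x W` matrix is replicated
#'   across channels).
#' @return A numeric `H x W x 3` array with all values in `[0, 1]`.
#' @export
image_rgb <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must be finite", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 1))
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  storage.mode(pixels) <- "double"
  pixels
}

#' @rdname image_rgb
#' @param image an image array.
#' @export
is_image_rgb <- function(image) {
  is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L &&
    !anyNA(image) && all(image >= 0) && all(image <= 1)
}

# Rec. 601 luma; used wherever a scalar luminance channel is needed.
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

clip01 <- function(x) pmin(pmax(x, 0), 1) # argument order keeps dim attributes

#' @rdname image_rgb
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE] # drop alpha
  image_rgb(px)
}

#' @rdname image_rgb
#' @param quality JPEG quality in `[0, 1]`.
#' @export
write_image <- function(image, path, quality = 0.95) {
  image <- image_rgb(image)
  # quantize to 8 bit, round half up, so a write/read round trip is stable
  q <- floor(image * 255 + 0.5) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(q, path, quality = quality),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read a directory-per-class image tree
#'
#' @param dir root directory whose immediate subdirectories are class names.
#' @return list with `images` (list of arrays), `labels` (integer, 0-based),
#'   `classes` (character), `files` (character).
#' @export
read_image_tree <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", dir, call. = FALSE)
  images <- list(); labels <- integer(); files <- character()
  for (k in seq_along(classes)) {
    fs <- sort(list.files(file.path(dir, classes[k]),
                          pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                          full.names = TRUE))
    for (f in fs) {
      images[[length(images) + 1L]] <- read_image(f)
      labels <- c(labels, k - 1L)
      files <- c(files, f)
    }
  }
  list(images = images, labels = labels, classes = classes, files = files)
}

#' Bilinear resize of an RGB image
#'
#' @param image `H x W x 3` array.
#' @param side target side in pixels (output is `side x side x 3`).
#' @export
resize_image <- function(image, side) {
  image <- image_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h == side && w == side) return(image)
  # align-corners-free bilinear sampling
  sy <- (seq_len(side) - 0.5) * h / side + 0.5
  sx <- (seq_len(side) - 0.5) * w / side + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1);   fx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(side, side, 3L))
  for (c in 1:3) {
    ch <- image[, , c]
    a <- ch[y0, x0]; b <- ch[y0, x1]; d <- ch[y1, x0]; e <- ch[y1, x1]
    top <- a * (1 - rep(fx, each = side)) + b * rep(fx, each = side)
    bot <- d * (1 - rep(fx, each = side)) + e * rep(fx, each = side)
    out[, , c] <- top * (1 - fy) + bot * fy
  }
  clip01(out)
}
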