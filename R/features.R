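#' Feature matrices with labels and column provenance
#'
#' A `feature_matrix` bundles an `N x d` numeric matrix of deep features, a
#' length-`N` integer label vector (0-based class codes) and one provenance
#' tag per column recording which model or generator produced it.
#'
#' @param values `N x d` numeric matrix, all entries finite.
#' @param labels integer vector of length `N`, values in `[0, K)`.
#' @param tags character vector of length `d` (defaults to `f1..fd`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, tags = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature values must be finite", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("`labels` length must equal the row count", call. = FALSE)
  if (is.null(tags)) tags <- paste0("f", seq_len(ncol(values)))
  if (length(tags) != ncol(values))
    stop("`tags` length must equal the column count", call. = FALSE)
  colnames(values) <- tags
  structure(list(values = values, labels = labels, tags = as.character(tags)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Concatenation fusion of two feature matrices
#'
#' Joins the columns of `fa` and `fb` (in that order) for the same samples;
#' the fused width is the sum of widths, e.g. `N x 1024` and `N x 512`
#' features fuse to `N x 1536`.
#'
#' @param fa,fb `feature_matrix` objects over the same samples (equal row
#'   counts and identical label vectors).
#' @return A fused `feature_matrix`.
#' @export
fuse <- function(fa, fb) {
  stopifnot(inherits(fa, "feature_matrix"), inherits(fb, "feature_matrix"))
  if (nrow(fa$values) != nrow(fb$values))
    stop("row counts differ", call. = FALSE)
  if (!identical(fa$labels, fb$labels))
    stop("label vectors differ", call. = FALSE)
  feature_matrix(cbind(fa$values, fb$values), fa$labels,
                 c(fa$tags, fb$tags))
}

#' Read/write feature matrices as CSV
#'
#' The header row holds the column tags; the final column, named `label`,
#' holds the integer class codes.
#'
#' @param x a `feature_matrix`.
#' @param path CSV file path.
#' @export
write_features_csv <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  df <- as.data.frame(x$values)
  names(df) <- x$tags
  df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("no `label` column in ", path, call. = FALSE)
  lab <- as.integer(df$label)
  df$label <- NULL
  feature_matrix(as.matrix(df), lab, names(df))
}

#' Tidy a feature matrix into a tibble
#'
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @export
tidy.feature_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$values)) |>
    (\(d) {d$label <- x$labels; d})()
}
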