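#' Median-of-ratios size factors
#'
#' Per-sample library-size factors by the median-of-ratios method: genes with
#' a positive count in every sample form the reference, each gene's reference
#' value is its geometric mean across samples, and a sample's factor is the
#' median of its counts-to-reference ratios. Factors are not rescaled
#' afterwards, so downstream absolute thresholds (the activity level of 50
#' normalized counts) keep their meaning.
#'
#' @param counts A [count_matrix()] or a numeric genes-by-samples matrix.
#' @return Named numeric vector of positive per-sample factors, of class
#'   `size_factors`.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  ref <- rowSums(m > 0) == ncol(m) & !apply(m, 1L, anyNA)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "median-of-ratios reference is undefined", call. = FALSE)
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2L, function(col) exp(stats::median(col - loggeo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors are not all finite and positive", call. = FALSE)
  structure(sf, class = "size_factors")
}

#' Divide counts by size factors
#'
#' @param x A [count_matrix()] (factors are computed if not supplied and the
#'   normalized slot is filled in) or a plain matrix.
#' @param sf Size factors from [size_factors()]; computed from `x` when NULL.
#' @return For a `count_matrix`, the object with `normalized` filled in and
#'   the factors stored as `attr(, "size_factors")`; for a matrix, the
#'   normalized matrix.
#' @export
normalize_counts <- function(x, sf = NULL) {
  if (inherits(x, "count_matrix")) {
    if (is.null(sf)) sf <- size_factors(x$counts)
    stopifnot(length(sf) == ncol(x$counts))
    x$normalized <- sweep(x$counts, 2L, unclass(sf), "/")
    attr(x, "size_factors") <- sf
    return(x)
  }
  m <- as.matrix(x)
  if (is.null(sf)) sf <- size_factors(m)
  stopifnot(length(sf) == ncol(m))
  sweep(m, 2L, unclass(sf), "/")
}

#' Normalized matrix accessor
#'
#' Returns the normalized matrix of a `count_matrix`, normalizing on the fly
#' if needed.
#' @param x A [count_matrix()].
#' @return Numeric matrix of normalized counts.
#' @export
normalized_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(x$normalized)) x <- normalize_counts(x)
  x$normalized
}
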