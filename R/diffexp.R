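#' Per-gene contrast statistics between two conditions
#'
#' For every gene: the mean normalized count per condition, the log2 fold
#' change of pseudocounted means, a two-sided unequal-variance (Welch) test
#' on the log2(normalized + pseudocount) replicate values, and
#' Benjamini-Hochberg q-values computed within the supplied gene universe.
#' With fewer than two replicates in either condition the p-value is
#' undefined and reported as NA.
#'
#' @param normalized Numeric genes-by-samples matrix of normalized counts, or
#'   a [count_matrix()].
#' @param metadata Sample metadata (ignored for a `count_matrix`).
#' @param cond_num,cond_den Numerator and denominator conditions of the
#'   contrast; `lfc = log2((mean_num + pc) / (mean_den + pc))`.
#' @param pseudocount Pseudocount on the normalized scale (default 1).
#' @param time_label_num,time_label_den Optional time-label restrictions for
#'   either side of the contrast.
#' @return Data frame of class `de_result` with columns `gene`, `mean_num`,
#'   `mean_den`, `lfc`, `p`, `q` and an attribute `contrast`.
#' @export
contrast_stats <- function(normalized, metadata = NULL, cond_num, cond_den,
                           pseudocount = 1,
                           time_label_num = NULL, time_label_den = NULL) {
  if (inherits(normalized, "count_matrix")) {
    metadata <- normalized$metadata
    normalized <- normalized_counts(normalized)
  }
  stopifnot(is.matrix(normalized), !is.null(metadata))
  pick <- function(cond, tl) {
    keep <- metadata$condition == cond
    if (!is.null(tl)) keep <- keep & metadata$time_label == tl
    ids <- metadata$sample_id[keep]
    if (!length(ids)) stop("no samples for condition '", cond, "'",
                           call. = FALSE)
    normalized[, ids, drop = FALSE]
  }
  a <- pick(cond_num, time_label_num)
  b <- pick(cond_den, time_label_den)
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  mean_num <- rowMeans(a)
  mean_den <- rowMeans(b)
  lfc <- log2((mean_num + pseudocount) / (mean_den + pseudocount))
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2L || n_b < 2L) {
    p <- rep(NA_real_, nrow(a))
  } else {
    p <- vapply(seq_len(nrow(a)), function(i) {
      xi <- la[i, ]; yi <- lb[i, ]
      tryCatch(stats::t.test(xi, yi, var.equal = FALSE)$p.value,
               # both groups constant: agreement decides
               error = function(e)
                 if (isTRUE(all.equal(mean(xi), mean(yi)))) 1 else 0)
    }, numeric(1L))
  }
  res <- data.frame(gene = rownames(normalized),
                    mean_num = unname(mean_num),
                    mean_den = unname(mean_den),
                    lfc = unname(lfc),
                    p = p,
                    q = adjust_bh(p),
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- c(numerator = cond_num, denominator = cond_den)
  attr(res, "pseudocount") <- pseudocount
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control over the supplied p-values, treating
#' them as one gene universe (q-values are only comparable within the
#' universe they were adjusted in). NA p-values yield NA q-values and do not
#' count toward the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Numeric vector of q-values, original order.
#' @export
adjust_bh <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Ingest an externally computed differential-expression table
#'
#' Lets the downstream classification run on the exact output of an external
#' DE engine (e.g. a negative-binomial Wald test). The TSV must carry the
#' columns `gene`, `mean_num`, `mean_den`, `lfc`, `p`, `q`.
#'
#' @param path TSV path.
#' @param contrast Optional length-2 character vector naming the
#'   numerator/denominator conditions.
#' @return A `de_result` data frame.
#' @export
ingest_de_table <- function(path, contrast = c(NA, NA)) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("gene", "mean_num", "mean_den", "lfc", "p", "q")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("DE table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$gene))
    stop("duplicated gene(s) in DE table", call. = FALSE)
  fin <- !is.na(tab$p) & !is.na(tab$q)
  bad <- which(fin & tab$q < tab$p - 1e-12)
  if (length(bad))
    stop("q < p at row(s) ", paste(bad, collapse = ", "),
         " (gene ", paste(tab$gene[bad], collapse = ", "), ")", call. = FALSE)
  if (any(fin & (tab$q < 0 | tab$q > 1)))
    stop("q-values outside [0, 1]", call. = FALSE)
  res <- tab[, req]
  attr(res, "contrast") <- c(numerator = contrast[1L],
                             denominator = contrast[2L])
  class(res) <- c("de_result", "data.frame")
  res
}
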