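#' Row-wise z-scoring of a log-expression matrix
#'
#' Centers and scales every gene (row) to mean 0 and unit standard deviation,
#' the transform under which expression heat maps and their dendrograms are
#' drawn. Zero-variance rows cannot be scaled; they are set to all zeros and
#' flagged.
#'
#' @param m Numeric matrix (genes x samples), typically log2(normalized +
#'   pseudocount) restricted to a gene set.
#' @return Matrix of the same shape; `attr(, "zero_variance")` is a logical
#'   vector marking the flat rows.
#' @export
scale_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  flat <- sd == 0 | is.na(sd)
  out <- (m - mu) / ifelse(flat, 1, sd)
  out[flat, ] <- 0
  attr(out, "zero_variance") <- unname(flat)
  out
}

#' Agglomerative clustering of samples
#'
#' Complete-linkage hierarchical clustering on Euclidean distances between
#' sample columns of a (row-scaled) expression matrix — the default geometry
#' of expression heat-map dendrograms. Deterministic given the input order.
#'
#' @param scaled Numeric matrix, samples in columns (>= 3 samples).
#' @param method Linkage passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
cluster_samples <- function(scaled, method = "complete") {
  if (ncol(scaled) < 3L) stop("need at least 3 samples", call. = FALSE)
  stats::hclust(stats::dist(t(scaled)), method = method)
}

#' Assign query samples to the nearest reference centroid
#'
#' Operationalizes "clusters with the target cells / remains clustered with
#' the start cells" as a machine-checkable statistic: on log2(normalized +
#' pseudocount) values over a gene set, each reference condition's centroid
#' is its per-gene replicate mean, and every query sample is assigned to the
#' reference with the higher Pearson correlation. Ties are flagged, never
#' silently broken. The full-sample dendrogram (over row-scaled values) is
#' attached for reporting.
#'
#' @param gene_ids Character vector of genes to restrict to (a signature or
#'   sub-reprogramome), or a [gene_set()].
#' @param normalized Normalized genes-by-samples matrix, or a
#'   [count_matrix()].
#' @param metadata Sample metadata (ignored for a `count_matrix`).
#' @param query_condition Condition whose samples are assigned
#'   (default "reprogramming").
#' @param pseudocount Pseudocount before log2.
#' @return Data frame of class `cluster_assignment`: `sample_id`,
#'   `cor_start`, `cor_target`, `assigned` ("start"/"target", NA on tie),
#'   `tie`; the `hclust` linkage of all samples is `attr(, "linkage")`.
#' @export
assign_to_reference <- function(gene_ids, normalized, metadata = NULL,
                                query_condition = "reprogramming",
                                pseudocount = 1) {
  if (inherits(normalized, "count_matrix")) {
    metadata <- normalized$metadata
    normalized <- normalized_counts(normalized)
  }
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$gene_ids
  gene_ids <- intersect(gene_ids, rownames(normalized))
  if (length(gene_ids) < 3L)
    stop("need at least 3 genes present in the matrix", call. = FALSE)
  lg <- log2(normalized[gene_ids, , drop = FALSE] + pseudocount)
  ref_ids <- function(cond) {
    ids <- metadata$sample_id[metadata$condition == cond]
    if (!length(ids)) stop("no '", cond, "' samples", call. = FALSE)
    ids
  }
  cen_s <- rowMeans(lg[, ref_ids("start"), drop = FALSE])
  cen_t <- rowMeans(lg[, ref_ids("target"), drop = FALSE])
  q_ids <- metadata$sample_id[metadata$condition == query_condition]
  if (!length(q_ids))
    stop("no '", query_condition, "' samples to assign", call. = FALSE)
  cor_s <- apply(lg[, q_ids, drop = FALSE], 2L, stats::cor, y = cen_s)
  cor_t <- apply(lg[, q_ids, drop = FALSE], 2L, stats::cor, y = cen_t)
  tie <- abs(cor_s - cor_t) < 1e-12
  out <- data.frame(sample_id = q_ids,
                    cor_start = unname(cor_s),
                    cor_target = unname(cor_t),
                    assigned = ifelse(tie, NA_character_,
                                      ifelse(cor_t > cor_s,
                                             "target", "start")),
                    tie = unname(tie),
                    stringsAsFactors = FALSE)
  if (ncol(lg) >= 3L)
    attr(out, "linkage") <- cluster_samples(scale_rows(lg))
  class(out) <- c("cluster_assignment", "data.frame")
  out
}
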