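#' @importFrom utils read.delim write.table
NULL

.conditions <- c("start", "vector_control", "reprogramming", "target")

#' Construct a count matrix with sample metadata
#'
#' The central container of the pipeline: a genes-by-samples matrix of
#' non-negative (real-valued) counts plus one metadata row per sample. Values
#' are accepted as reals so that externally normalized or tximport-style
#' matrices can be ingested.
#'
#' @param counts Numeric matrix, genes in rows (unique rownames = gene
#'   symbols), samples in columns (unique colnames = sample ids).
#' @param metadata Data frame with columns `sample_id`, `condition` (one of
#'   start, vector_control, reprogramming, target), `replicate` (positive
#'   integer) and `time_label` (free text). Every sample in `counts` must
#'   appear exactly once.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `metadata` and `normalized` (NULL until [normalize_counts()] is run).
#' @export
count_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "replicate", "time_label")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent))
    stop("sample(s) in count matrix missing from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(metadata$condition), .conditions)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.conditions, collapse = ", "),
         call. = FALSE)
  if (any(metadata$replicate < 1))
    stop("replicate numbers must be positive integers", call. = FALSE)
  # drop metadata rows for samples absent from the matrix, keep matrix order
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata, normalized = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "raw" else "normalized"))
  print(table(x$metadata$condition))
  invisible(x)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The count matrix is tab-delimited with a header row of sample ids and a
#' first column named `gene` holding gene symbols; the metadata file lists
#' `sample_id`, `condition`, `replicate` and `time_label` for every sample.
#'
#' @param path Path to the counts TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata_path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1L] != "gene")
    stop("counts TSV must have a first column named 'gene'", call. = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in count matrix", call. = FALSE)
  rownames(m) <- genes
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

#' Construct or read a gene set
#'
#' `read_gene_set()` accepts either a plain list (one symbol per line) or an
#' annotation-style TSV export in which the symbol column repeats once per
#' annotation (as GO exports do); duplicates are collapsed, preserving the
#' order of first occurrence.
#'
#' @param path File to read.
#' @param name Set name (defaults to the file name).
#' @param symbol_column For TSV dialects, the column holding gene symbols;
#'   by name if the file has a header containing it, else the first column.
#' @return An object of class `gene_set` with fields `name`, `source` and
#'   `gene_ids`.
#' @export
read_gene_set <- function(path, name = basename(path),
                          symbol_column = "symbol") {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gene set file is empty: ", path, call. = FALSE)
  if (any(grepl("\t", lines, fixed = TRUE))) {
    first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    has_header <- symbol_column %in% first
    col <- if (has_header) match(symbol_column, first) else 1L
    body <- if (has_header) lines[-1L] else lines
    ids <- vapply(strsplit(body, "\t", fixed = TRUE),
                  function(x) trimws(x[col]), character(1L))
  } else {
    ids <- trimws(lines)
  }
  ids <- ids[nzchar(ids)]
  gene_set(unique(ids), name = name, source = path)
}

#' @rdname read_gene_set
#' @param gene_ids Character vector of gene symbols (unique, non-empty).
#' @param source Free-text provenance.
#' @export
gene_set <- function(gene_ids, name = "gene_set", source = "in-memory") {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("gene set must be non-empty", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene set contains duplicates", call. = FALSE)
  structure(list(name = name, source = source, gene_ids = gene_ids),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes (%s)\n", x$name,
              length(x$gene_ids), x$source))
  invisible(x)
}

#' Align a gene set to the genes present in a count matrix
#'
#' Splits a gene set into the members measured in the matrix and the members
#' missing from it (gene identity is by case-sensitive symbol).
#'
#' @param gene_set A [gene_set()].
#' @param x A [count_matrix()] or a character vector of gene ids.
#' @return A list with `present` (a `gene_set`, or NULL when empty) and
#'   `missing` (character vector).
#' @export
align_gene_set <- function(gene_set, x) {
  universe <- if (inherits(x, "count_matrix")) rownames(x$counts)
              else as.character(x)
  hit <- gene_set$gene_ids %in% universe
  present <- if (any(hit))
    gene_set(gene_set$gene_ids[hit], name = gene_set$name,
             source = gene_set$source) else NULL
  list(present = present, missing = gene_set$gene_ids[!hit])
}

#' Write (and re-read) pipeline results
#'
#' Writes the per-gene table to `<prefix>.genes.tsv` (deterministic column
#' order, full double precision) and the summary list to
#' `<prefix>.summary.json`.
#'
#' @param per_gene Data frame of per-gene results.
#' @param summary Named list (category counts, quantification sums, cluster
#'   assignments, thresholds, ...).
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(per_gene, summary, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  genes_path <- paste0(prefix, ".genes.tsv")
  json_path <- paste0(prefix, ".summary.json")
  write.table(format(per_gene, digits = 15, trim = TRUE, scientific = FALSE),
              genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(genes = genes_path, summary = json_path))
}

#' @rdname write_results
#' @export
read_results <- function(prefix) {
  per_gene <- read.delim(paste0(prefix, ".genes.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  summary <- jsonlite::read_json(paste0(prefix, ".summary.json"),
                                 simplifyVector = TRUE)
  list(per_gene = per_gene, summary = summary)
}
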