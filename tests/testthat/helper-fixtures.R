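# Small in-code fixture builders shared across test files.

write_counts_fixture <- function(counts, meta, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  counts_path <- file.path(dir, "counts.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = counts_path, metadata = meta_path)
}

tiny_meta <- function(sample_ids, condition) {
  data.frame(sample_id = sample_ids,
             condition = condition,
             replicate = seq_along(sample_ids),
             time_label = "48h",
             stringsAsFactors = FALSE)
}

# a de_result row set built directly, bypassing contrast_stats
make_de <- function(gene, mean_num, mean_den, lfc = NULL, p = 0.5, q = NULL,
                    pc = 1) {
  if (is.null(lfc)) lfc <- log2((mean_num + pc) / (mean_den + pc))
  if (is.null(q)) q <- pmin(1, p)  # caller sets q when it matters
  res <- data.frame(gene = gene, mean_num = mean_num, mean_den = mean_den,
                    lfc = lfc, p = p, q = q, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

make_activity <- function(gene, state, condition = "start") {
  data.frame(gene = gene, condition = condition, state = state,
             min_replicate_value = ifelse(state == "active", 100, 0),
             mean_value = ifelse(state == "active", 100, 0),
             stringsAsFactors = FALSE)
}
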