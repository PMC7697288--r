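#' Run the full legitimacy pipeline on a count matrix
#'
#' Orchestrates normalization, activity calling, contrast statistics,
#' sub-reprogramome partitioning, PIANO response classification,
#' reprogramming quantification and nearest-centroid similarity for one
#' analyzed gene set, and optionally writes the per-gene TSV and summary
#' JSON. Size factors are always estimated on the full matrix; q-values are
#' adjusted within the analyzed gene set.
#'
#' The start and target conditions are required. The PIANO and similarity
#' stages run only when reprogramming (and, for PIANO, vector-control)
#' samples are present.
#'
#' @param cm A [count_matrix()] (raw counts; normalized on entry).
#' @param gene_set Optional [gene_set()] or character vector restricting the
#'   analysis; genes missing from the matrix are reported, not an error.
#' @param cfg Primary [threshold_config()].
#' @param lenient_cfg Second-tier thresholds for [tiered_partition()]; set
#'   `tiered = FALSE` to partition at `cfg` only.
#' @param tiered Use the two-tier partition (default TRUE).
#' @param reprogramming_time Optional time label selecting one reprogramming
#'   time point.
#' @param out_prefix If given, results are written via [write_results()].
#' @return List of class `reprolegit_result`: `per_gene` (data frame),
#'   `summary` (list), plus the intermediate objects (`counts`, `partition`,
#'   `piano`, `quantification`, `similarity`, `de`).
#' @export
run_pipeline <- function(cm, gene_set = NULL,
                         cfg = preset_thresholds("strict"),
                         lenient_cfg = preset_thresholds("lenient"),
                         tiered = TRUE,
                         reprogramming_time = NULL,
                         out_prefix = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  cm <- normalize_counts(cm)
  meta <- cm$metadata
  for (cond in c("start", "target"))
    if (!any(meta$condition == cond))
      stop("condition '", cond, "' is required", call. = FALSE)
  has_reprog <- any(meta$condition == "reprogramming")
  has_control <- any(meta$condition == "vector_control")

  missing <- character(0)
  genes <- rownames(cm$counts)
  set_name <- "all_genes"
  if (!is.null(gene_set)) {
    if (!inherits(gene_set, "gene_set")) gene_set <- gene_set(gene_set)
    al <- align_gene_set(gene_set, cm)
    if (is.null(al$present))
      stop("no gene of set '", gene_set$name, "' is in the matrix",
           call. = FALSE)
    genes <- al$present$gene_ids
    missing <- al$missing
    set_name <- gene_set$name
  }
  norm <- cm$normalized[genes, , drop = FALSE]

  act <- list(
    start = classify_activity(norm, meta, "start", cfg$activity_threshold),
    target = classify_activity(norm, meta, "target", cfg$activity_threshold))
  if (has_reprog)
    act$reprogramming <- classify_activity(norm, meta, "reprogramming",
                                           cfg$activity_threshold,
                                           time_label = reprogramming_time)

  de <- list(target_vs_start = contrast_stats(norm, meta, "target", "start",
                                              cfg$pseudocount))
  partition <- if (tiered)
    tiered_partition(de$target_vs_start, act$start, act$target,
                     cfg, lenient_cfg)
  else
    partition_reprogramome(de$target_vs_start, act$start, act$target, cfg)

  quant <- reprogramming_amount(partition, de$target_vs_start, cfg, set_name)

  piano <- NULL
  if (has_reprog && has_control) {
    de$reprog_vs_start <- contrast_stats(norm, meta, "reprogramming",
                                         "start", cfg$pseudocount,
                                         time_label_num = reprogramming_time)
    de$reprog_vs_control <- contrast_stats(norm, meta, "reprogramming",
                                           "vector_control", cfg$pseudocount,
                                           time_label_num = reprogramming_time)
    de$reprog_vs_target <- contrast_stats(norm, meta, "reprogramming",
                                          "target", cfg$pseudocount,
                                          time_label_num = reprogramming_time)
    piano <- classify_all(de$reprog_vs_start, de$reprog_vs_control,
                          de$reprog_vs_target, partition, cfg)
  }

  similarity <- NULL
  if (has_reprog) {
    similarity <- list()
    for (cl in c("up", "down")) {
      ids <- partition$gene[partition$class == cl]
      if (length(ids) >= 3L)
        similarity[[paste0(cl, "_reprogramome")]] <-
          assign_to_reference(ids, norm, meta, pseudocount = cfg$pseudocount)
    }
    if (nrow(partition) >= 3L)
      similarity$full_set <-
        assign_to_reference(partition$gene, norm, meta,
                            pseudocount = cfg$pseudocount)
  }

  per_gene <- .per_gene_table(genes, act, partition, de, piano, quant)
  summary <- list(
    set_name = set_name,
    n_genes_analyzed = length(genes),
    n_genes_missing = length(missing),
    missing_genes = missing,
    thresholds = unclass(cfg),
    size_factors = as.list(attr(cm, "size_factors")),
    class_counts = as.list(partition_counts(partition)),
    piano_counts = if (!is.null(piano))
      as.list(table(piano$category)) else NULL,
    quantification = quant[c("up_sum", "down_sum", "net")],
    cluster_assignment = if (!is.null(similarity))
      lapply(similarity, function(s)
        as.list(stats::setNames(s$assigned, s$sample_id))) else NULL)

  res <- list(per_gene = per_gene, summary = summary, counts = cm,
              partition = partition, piano = piano, quantification = quant,
              similarity = similarity, de = de)
  class(res) <- "reprolegit_result"
  if (!is.null(out_prefix)) write_results(per_gene, summary, out_prefix)
  res
}

.per_gene_table <- function(genes, act, partition, de, piano, quant) {
  dts <- de$target_vs_start
  i <- match(genes, dts$gene)
  k <- match(genes, partition$gene)
  out <- data.frame(
    gene = genes,
    mean_start = dts$mean_den[i],
    mean_target = dts$mean_num[i],
    active_start = act$start$state[match(genes, act$start$gene)],
    active_target = act$target$state[match(genes, act$target$gene)],
    class = partition$class[k],
    tier = partition$tier[k],
    in_activatome = partition$in_activatome[k],
    in_erasome = partition$in_erasome[k],
    lfc_target_vs_start = dts$lfc[i],
    p_target_vs_start = dts$p[i],
    q_target_vs_start = dts$q[i],
    stringsAsFactors = FALSE)
  if (!is.null(act$reprogramming))
    out$active_reprogramming <-
      act$reprogramming$state[match(genes, act$reprogramming$gene)]
  if (!is.null(piano)) {
    j <- match(genes, piano$gene)
    out$piano <- ifelse(is.na(j), "silent_excluded", piano$category[j])
    out$fc_vs_start <- piano$fc_vs_start[j]
    out$fc_vs_control <- piano$fc_vs_control[j]
    out$fc_vs_target <- piano$fc_vs_target[j]
    out$p_vs_start <- piano$p_vs_start[j]
  }
  a <- match(genes, quant$addends$gene)
  out$lfc_addend <- quant$addends$addend[a]
  out
}

#' @export
print.reprolegit_result <- function(x, ...) {
  cat(sprintf("reprolegit result: '%s', %d genes\n", x$summary$set_name,
              x$summary$n_genes_analyzed))
  cat("class counts:\n")
  print(unlist(x$summary$class_counts))
  if (!is.null(x$summary$piano_counts)) {
    cat("PIANO counts:\n")
    print(unlist(x$summary$piano_counts))
  }
  cat(sprintf("quantification: up %.1f LFC, down %.1f LFC\n",
              x$summary$quantification$up_sum,
              x$summary$quantification$down_sum))
  invisible(x)
}
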