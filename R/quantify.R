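#' Quantify enrichment/reprogramming of a gene set as summed |LFC|
#'
#' The amount of upreprogramming is the sum of absolute log2 fold changes
#' (start vs target) over the target-enriched (up-class) genes; the amount of
#' downreprogramming sums over the start-enriched genes. For activatome and
#' erasome genes the silent side's mean is floored at the activity threshold
#' before the ratio (threshold-capped LFC), which bounds the contribution of
#' zeros by what can actually be claimed above the detection level. Per-gene
#' addends are returned for audit so that alternative weightings can be
#' recomputed downstream.
#'
#' @param partition A `reprogramome_partition`.
#' @param de `de_result` for the target-vs-start contrast on the same genes;
#'   its `mean_num` is the target mean and `mean_den` the start mean.
#' @param cfg A [threshold_config()] (supplies the activity threshold and
#'   pseudocount).
#' @param set_name Label for the report.
#' @return Object of class `quantification_report`: list with `set_name`,
#'   `n_genes`, `up_sum`, `down_sum`, `net` (up minus down) and a data frame
#'   `addends` (`gene`, `class`, `addend`).
#' @export
reprogramming_amount <- function(partition, de,
                                 cfg = preset_thresholds("strict"),
                                 set_name = "gene_set") {
  idx <- match(partition$gene, de$gene)
  if (anyNA(idx))
    stop("DE table must cover every partitioned gene", call. = FALSE)
  pc <- cfg$pseudocount
  thr <- cfg$activity_threshold
  num <- de$mean_num[idx]   # target-side mean
  den <- de$mean_den[idx]   # start-side mean
  # floor the silent side at the activity threshold
  den <- ifelse(partition$in_activatome, pmax(den, thr), den)
  num <- ifelse(partition$in_erasome, pmax(num, thr), num)
  addend <- abs(log2((num + pc) / (den + pc)))

  enriched <- partition$class %in% c("up", "down")
  addends <- data.frame(gene = partition$gene[enriched],
                        class = partition$class[enriched],
                        addend = addend[enriched],
                        stringsAsFactors = FALSE)
  structure(list(set_name = set_name,
                 n_genes = nrow(partition),
                 up_sum = sum(addends$addend[addends$class == "up"]),
                 down_sum = sum(addends$addend[addends$class == "down"]),
                 net = sum(addends$addend[addends$class == "up"]) -
                   sum(addends$addend[addends$class == "down"]),
                 addends = addends),
            class = "quantification_report")
}

#' @export
print.quantification_report <- function(x, ...) {
  cat(sprintf("Quantification of '%s' (%d genes)\n", x$set_name, x$n_genes))
  cat(sprintf("  upreprogramming:   %.1f LFC over %d genes\n", x$up_sum,
              sum(x$addends$class == "up")))
  cat(sprintf("  downreprogramming: %.1f LFC over %d genes\n", x$down_sum,
              sum(x$addends$class == "down")))
  cat(sprintf("  net: %.1f LFC\n", x$net))
  invisible(x)
}

#' Fold expression above the activity threshold
#'
#' For genes whose reference level is "not expressed", the residual
#' expression of a sample is reported relative to the activity threshold
#' itself: a value of 11.8 means the mean normalized count is 11.8 times the
#' threshold. Values below 1 indicate sub-threshold expression.
#'
#' @param mean Mean normalized count(s).
#' @param threshold Activity threshold (> 0).
#' @return `mean / threshold`.
#' @export
fold_above_threshold <- function(mean, threshold = 50) {
  if (any(threshold <= 0)) stop("threshold must be > 0", call. = FALSE)
  mean / threshold
}
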