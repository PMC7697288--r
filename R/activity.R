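#' Active/inactive expression calls per gene for one condition
#'
#' A gene is active in a condition only when its normalized count strictly
#' exceeds the activity threshold in every replicate; a single replicate at
#' or below the threshold forces an inactive call. The rule is deliberately
#' conservative: activity is an all-replicates property, not a mean property.
#'
#' @param normalized Numeric genes-by-samples matrix of normalized counts, or
#'   a [count_matrix()] (its normalized slot is used, computed if absent).
#' @param metadata Sample metadata data frame (ignored when `normalized` is a
#'   `count_matrix`).
#' @param condition Condition whose replicates to evaluate.
#' @param threshold Activity threshold on the normalized-count scale
#'   (default 50).
#' @param time_label Optional time label to restrict the replicates to; by
#'   default all replicates of the condition are pooled.
#' @return Data frame with one row per gene: `gene`, `condition`, `state`
#'   ("active"/"inactive"), `min_replicate_value`, `mean_value`.
#' @export
classify_activity <- function(normalized, metadata = NULL, condition,
                              threshold = 50, time_label = NULL) {
  if (inherits(normalized, "count_matrix")) {
    metadata <- normalized$metadata
    normalized <- normalized_counts(normalized)
  }
  stopifnot(is.matrix(normalized), !is.null(metadata))
  keep <- metadata$condition == condition
  if (!is.null(time_label)) keep <- keep & metadata$time_label == time_label
  ids <- metadata$sample_id[keep]
  if (!length(ids))
    stop("no samples for condition '", condition, "'",
         if (!is.null(time_label)) paste0(" at time '", time_label, "'"),
         call. = FALSE)
  sub <- normalized[, ids, drop = FALSE]
  mins <- apply(sub, 1L, min)
  data.frame(gene = rownames(normalized),
             condition = condition,
             state = ifelse(mins > threshold, "active", "inactive"),
             min_replicate_value = unname(mins),
             mean_value = unname(rowMeans(sub)),
             stringsAsFactors = FALSE)
}
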