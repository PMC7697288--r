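#' PIANO response category for genes
#'
#' The decision table at the heart of the legitimacy analysis. Each gene's
#' transcriptional response in the reprogramming samples is judged against
#' three references — the start cells, the vector control, and the target
#' cells — in the light of what the gene *should* do (its sub-reprogramome
#' class):
#'
#' For an up-class gene (should rise to target levels), rules are evaluated
#' in priority order: a change below `respond_fc` against either the start or
#' the vector-control reference, an inconsistent direction between the two
#' references, or a p-value at or above `respond_p` is **no_response**;
#' a significant, consistent downward response is **wrong_down**; a
#' significant upward response landing at least `aberrant_fc` above the
#' target level with a significant reprogramming-vs-target gap is
#' **over_up**; an upward response within `proximity_fc` of the target is
#' **proper_up**; an upward response still more than `proximity_fc` short of
#' the target is **insufficient_up**. Down-class genes mirror these rules
#' with all directions reversed.
#'
#' Shared genes should not move at all: a significant consistent change of at
#' least `aberrant_fc` against both references that also lands at least
#' `aberrant_fc` beyond the target level is **unwanted_up** /
#' **unwanted_down**; anything else is **no_response**. Silent and uncertain
#' genes are **not_applicable**.
#'
#' @param class Partition class per gene (`up`, `down`, `shared`,
#'   `silent_both`, `uncertain`); recycled if length 1.
#' @param fc_start,fc_control Fold change of the reprogramming samples vs the
#'   start and vector-control references (fold scale; values below 1 mean
#'   downregulation).
#' @param fc_target Fold ratio of the reprogramming level to the target level.
#' @param p_start P-value of the reprogramming-vs-start contrast.
#' @param p_target P-value of the reprogramming-vs-target contrast (required
#'   only for the over_* calls).
#' @param cfg A [threshold_config()].
#' @return Character vector of PIANO categories.
#' @export
gene_response <- function(class, fc_start, fc_control, fc_target,
                          p_start, p_target = NA_real_,
                          cfg = preset_thresholds("strict")) {
  n <- max(length(class), length(fc_start))
  class <- rep_len(class, n)
  fc_start <- rep_len(fc_start, n)
  fc_control <- rep_len(fc_control, n)
  fc_target <- rep_len(fc_target, n)
  p_start <- rep_len(p_start, n)
  p_target <- rep_len(p_target, n)
  vapply(seq_len(n), function(i)
    .piano_one(class[i], fc_start[i], fc_control[i], fc_target[i],
               p_start[i], p_target[i], cfg),
    character(1L))
}

.piano_one <- function(class, fs, fc, ft, ps, pt, cfg) {
  if (class %in% c("silent_both", "uncertain")) return("not_applicable")
  rfc <- cfg$respond_fc; rp <- cfg$respond_p
  afc <- cfg$aberrant_fc; pfc <- cfg$proximity_fc
  sig <- !is.na(ps) && ps < rp
  resp_up <- fs >= rfc && fc >= rfc && sig
  resp_down <- fs <= 1 / rfc && fc <= 1 / rfc && sig
  sig_t <- !is.na(pt) && pt < rp

  if (class == "up") {
    if (resp_down) return("wrong_down")
    if (!resp_up) return("no_response")
    if (ft >= afc && sig_t) return("over_up")
    if (1 / ft > pfc) return("insufficient_up")
    return("proper_up")
  }
  if (class == "down") {
    if (resp_up) return("wrong_up")
    if (!resp_down) return("no_response")
    if (ft <= 1 / afc && sig_t) return("over_down")
    if (ft > pfc) return("insufficient_down")
    return("proper_down")
  }
  if (class == "shared") {
    if (fs >= afc && fc >= afc && ft >= afc && sig) return("unwanted_up")
    if (fs <= 1 / afc && fc <= 1 / afc && ft <= 1 / afc && sig)
      return("unwanted_down")
    return("no_response")
  }
  stop("unknown partition class: ", class, call. = FALSE)
}

.piano_levels <- c("proper_up", "proper_down",
                   "insufficient_up", "insufficient_down",
                   "over_up", "over_down",
                   "wrong_up", "wrong_down",
                   "unwanted_up", "unwanted_down",
                   "no_response", "not_applicable")

#' Classify every gene of a partitioned set
#'
#' Builds the fold/significance inputs from the three reprogramming contrasts
#' and applies [gene_response()] to every non-silent gene (silent genes are
#' dropped; uncertain genes are reported as not_applicable).
#'
#' @param de_start,de_control,de_target `de_result` tables for reprogramming
#'   vs start, vs vector control, and vs target.
#' @param partition A `reprogramome_partition` over the same gene universe.
#' @param cfg A [threshold_config()].
#' @return Data frame of class `piano_calls`: `gene`, `class`, `category`,
#'   `fc_vs_start`, `fc_vs_control`, `fc_vs_target`, `p_vs_start`,
#'   `p_vs_control`, `p_vs_target`; the per-category-by-class count table is
#'   attached as `attr(, "counts")`.
#' @export
classify_all <- function(de_start, de_control, de_target, partition,
                         cfg = preset_thresholds("strict")) {
  genes <- partition$gene[partition$class != "silent_both"]
  i_s <- match(genes, de_start$gene)
  i_c <- match(genes, de_control$gene)
  i_t <- match(genes, de_target$gene)
  if (anyNA(i_s) || anyNA(i_c) || anyNA(i_t))
    stop("all three contrasts must cover every non-silent gene",
         call. = FALSE)
  cls <- partition$class[match(genes, partition$gene)]
  calls <- data.frame(
    gene = genes,
    class = cls,
    category = gene_response(cls,
                             2^de_start$lfc[i_s],
                             2^de_control$lfc[i_c],
                             2^de_target$lfc[i_t],
                             de_start$p[i_s],
                             de_target$p[i_t],
                             cfg),
    fc_vs_start = 2^de_start$lfc[i_s],
    fc_vs_control = 2^de_control$lfc[i_c],
    fc_vs_target = 2^de_target$lfc[i_t],
    p_vs_start = de_start$p[i_s],
    p_vs_control = de_control$p[i_c],
    p_vs_target = de_target$p[i_t],
    stringsAsFactors = FALSE)
  attr(calls, "counts") <- table(
    class = factor(calls$class,
                   levels = c("up", "down", "shared", "uncertain")),
    category = factor(calls$category, levels = .piano_levels))
  attr(calls, "thresholds") <- cfg
  class(calls) <- c("piano_calls", "data.frame")
  calls
}

#' Category counts across a grid of response thresholds
#'
#' Re-runs the PIANO classification under each setting of
#' `(respond_fc, proximity_fc, respond_p)` and tabulates category counts,
#' making the stringency dependence of the calls explicit. The default grid
#' holds the two screens discussed for insufficiency: the stringent one
#' (deficit > 1.5x, response >= 1.5x, p < 0.05) and the lenient one
#' (deficit > 2x, response >= 2x, p < 0.01).
#'
#' @param de_start,de_control,de_target,partition As in [classify_all()].
#' @param grid Data frame with columns `respond_fc`, `proximity_fc`,
#'   `respond_p` (one row per setting).
#' @param cfg Base [threshold_config()] supplying all other cutoffs.
#' @return Data frame: one row per setting, columns are the grid values plus
#'   one count column per PIANO category.
#' @export
threshold_sensitivity <- function(de_start, de_control, de_target, partition,
                                  grid = data.frame(
                                    respond_fc = c(1.5, 2),
                                    proximity_fc = c(1.5, 2),
                                    respond_p = c(0.05, 0.01)),
                                  cfg = preset_thresholds("strict")) {
  stopifnot(all(c("respond_fc", "proximity_fc", "respond_p") %in%
                  names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$respond_fc <- grid$respond_fc[i]
    cfg_i$proximity_fc <- grid$proximity_fc[i]
    cfg_i$respond_p <- grid$respond_p[i]
    calls <- classify_all(de_start, de_control, de_target, partition, cfg_i)
    counts <- table(factor(calls$category, levels = .piano_levels))
    cbind(grid[i, , drop = FALSE], as.data.frame(t(as.matrix(counts))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
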