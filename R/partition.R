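#' Partition a gene set into sub-reprogramomes
#'
#' Assigns every gene of the analyzed set to exactly one of five classes from
#' the start-vs-target contrast and the per-condition activity calls:
#' \describe{
#'   \item{up}{target-enriched (the upreprogramome): fold(target/start) at
#'     least `enrich_fc` with q below `enrich_q`.}
#'   \item{down}{start-enriched (the downreprogramome), mirrored.}
#'   \item{silent_both}{inactive in both cell types; excluded from all
#'     downstream response calls and quantification.}
#'   \item{shared}{active in at least one cell type, fold-change magnitude
#'     below `shared_fc` and q at or above `shared_q`.}
#'   \item{uncertain}{everything between the shared and enriched definitions
#'     (significant but small, or large but insignificant).}
#' }
#' Within the up class, genes active in the target only are flagged as the
#' activatome (must be switched on); within the down class, genes active in
#' the start only are the erasome (must be silenced).
#'
#' @param de `de_result` for the target (numerator) vs start (denominator)
#'   contrast, covering every gene of the set.
#' @param activity_start,activity_target Activity calls from
#'   [classify_activity()] for the start and target conditions.
#' @param cfg A [threshold_config()].
#' @return Data frame of class `reprogramome_partition`: `gene`, `class`,
#'   `tier` (NA here; see [tiered_partition()]), `in_activatome`,
#'   `in_erasome`, `lfc`, `q`.
#' @export
partition_reprogramome <- function(de, activity_start, activity_target,
                                   cfg = preset_thresholds("strict")) {
  stopifnot(inherits(de, "de_result"))
  genes <- de$gene
  s_state <- activity_start$state[match(genes, activity_start$gene)]
  t_state <- activity_target$state[match(genes, activity_target$gene)]
  if (anyNA(s_state) || anyNA(t_state))
    stop("every gene needs activity calls in both conditions", call. = FALSE)

  fold_mag <- 2^abs(de$lfc)
  up <- 2^de$lfc >= cfg$enrich_fc & !is.na(de$q) & de$q < cfg$enrich_q
  down <- 2^(-de$lfc) >= cfg$enrich_fc & !is.na(de$q) & de$q < cfg$enrich_q
  silent <- s_state == "inactive" & t_state == "inactive"
  shared <- fold_mag < cfg$shared_fc & !is.na(de$q) & de$q >= cfg$shared_q

  class <- rep("uncertain", length(genes))
  class[shared] <- "shared"
  class[down] <- "down"
  class[up] <- "up"
  class[silent] <- "silent_both"

  part <- data.frame(gene = genes,
                     class = class,
                     tier = NA_character_,
                     in_activatome = class == "up" &
                       t_state == "active" & s_state == "inactive",
                     in_erasome = class == "down" &
                       s_state == "active" & t_state == "inactive",
                     lfc = de$lfc,
                     q = de$q,
                     stringsAsFactors = FALSE)
  attr(part, "thresholds") <- cfg
  class(part) <- c("reprogramome_partition", "data.frame")
  part
}

#' Two-tier (strict then lenient) partition
#'
#' Genes resolved as enriched at the strict stringency keep that call with
#' tier "strict"; genes left shared or uncertain are re-evaluated at the
#' lenient stringency and, if then enriched, carry tier "lenient". Remaining
#' genes take their lenient-tier class. Silent genes are silent at any tier.
#'
#' @param de,activity_start,activity_target As in
#'   [partition_reprogramome()].
#' @param strict_cfg,lenient_cfg Threshold configurations; the strict fold
#'   cutoff must be at least the lenient one and the strict q cutoff at most
#'   the lenient one.
#' @return A `reprogramome_partition` with the `tier` column filled for
#'   enriched genes.
#' @export
tiered_partition <- function(de, activity_start, activity_target,
                             strict_cfg = preset_thresholds("strict"),
                             lenient_cfg = preset_thresholds("lenient")) {
  if (strict_cfg$enrich_fc < lenient_cfg$enrich_fc ||
      strict_cfg$enrich_q > lenient_cfg$enrich_q)
    stop("strict thresholds must be at least as stringent as lenient ones",
         call. = FALSE)
  strict <- partition_reprogramome(de, activity_start, activity_target,
                                   strict_cfg)
  lenient <- partition_reprogramome(de, activity_start, activity_target,
                                    lenient_cfg)
  out <- strict
  resolved <- strict$class %in% c("up", "down", "silent_both")
  out$tier[strict$class %in% c("up", "down")] <- "strict"
  redo <- !resolved
  out$class[redo] <- lenient$class[redo]
  out$in_activatome[redo] <- lenient$in_activatome[redo]
  out$in_erasome[redo] <- lenient$in_erasome[redo]
  out$tier[redo & out$class %in% c("up", "down")] <- "lenient"
  attr(out, "thresholds") <- list(strict = strict_cfg, lenient = lenient_cfg)
  out
}

#' Class counts of a partition
#' @param part A `reprogramome_partition`.
#' @return Named integer vector over the five classes plus the two flags.
#' @export
partition_counts <- function(part) {
  lv <- c("up", "down", "shared", "silent_both", "uncertain")
  n <- vapply(lv, function(k) sum(part$class == k), integer(1L))
  c(n, activatome = sum(part$in_activatome), erasome = sum(part$in_erasome))
}
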