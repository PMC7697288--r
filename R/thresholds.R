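#' Threshold configuration for the legitimacy pipeline
#'
#' Single home for every numeric cutoff used anywhere in the pipeline. All
#' fold thresholds are on the fold (not log2) scale and must exceed 1; all
#' significance levels lie in (0, 1).
#'
#' @param activity_threshold Normalized-count level that every replicate must
#'   strictly exceed for a gene to be called active (default 50).
#' @param enrich_fc,enrich_q Fold and FDR cutoffs defining target-/start-
#'   enriched genes in the start-vs-target contrast.
#' @param shared_fc,shared_q A gene is "shared" (similarly expressed) when its
#'   fold-change magnitude is below `shared_fc` and its q-value is at or above
#'   `shared_q`; genes between the shared and enriched definitions are
#'   "uncertain".
#' @param respond_fc,respond_p Minimum fold change (vs both the start and the
#'   vector-control references) and p-value for a reprogramming sample to
#'   count as having responded at all.
#' @param proximity_fc Fold window around the target level within which a
#'   responding gene counts as having reached the target ("proper"); a
#'   responding gene still more than `proximity_fc` short of the target is
#'   "insufficient".
#' @param aberrant_fc,aberrant_q Fold and significance cutoffs for the
#'   aberrant categories (over- and unwanted reprogramming).
#' @param pseudocount Normalized-count pseudocount added before any log2
#'   ratio, keeping fold changes finite for silent genes.
#'
#' @return An object of class `threshold_config` (a named list).
#' @seealso [preset_thresholds()]
#' @export
threshold_config <- function(activity_threshold = 50,
                             enrich_fc = 2, enrich_q = 0.01,
                             shared_fc = 1.5, shared_q = 0.05,
                             respond_fc = 1.5, respond_p = 0.05,
                             proximity_fc = 1.5,
                             aberrant_fc = 2, aberrant_q = 0.01,
                             pseudocount = 1) {
  cfg <- list(activity_threshold = activity_threshold,
              enrich_fc = enrich_fc, enrich_q = enrich_q,
              shared_fc = shared_fc, shared_q = shared_q,
              respond_fc = respond_fc, respond_p = respond_p,
              proximity_fc = proximity_fc,
              aberrant_fc = aberrant_fc, aberrant_q = aberrant_q,
              pseudocount = pseudocount)
  folds <- c("enrich_fc", "shared_fc", "respond_fc", "proximity_fc",
             "aberrant_fc")
  for (f in folds) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 1)
      stop("'", f, "' must be a single fold > 1", call. = FALSE)
  }
  for (s in c("enrich_q", "shared_q", "respond_p", "aberrant_q")) {
    if (!is.numeric(cfg[[s]]) || cfg[[s]] <= 0 || cfg[[s]] >= 1)
      stop("'", s, "' must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$activity_threshold <= 0)
    stop("'activity_threshold' must be > 0", call. = FALSE)
  if (cfg$pseudocount < 0)
    stop("'pseudocount' must be >= 0", call. = FALSE)
  structure(cfg, class = "threshold_config")
}

#' Named stringency presets
#'
#' Three named enrichment stringencies: `strict` (2-fold, q < 0.01),
#' `lenient` (1.5-fold, q < 0.05) and `broad` (1.3-fold, q < 0.05). The
#' response/proximity/aberrant cutoffs are shared across presets and can be
#' overridden via `...`.
#'
#' @param preset One of `"strict"`, `"lenient"`, `"broad"`.
#' @param ... Overrides passed on to [threshold_config()].
#' @return A `threshold_config`.
#' @export
preset_thresholds <- function(preset = c("strict", "lenient", "broad"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    strict  = list(enrich_fc = 2,   enrich_q = 0.01),
    lenient = list(enrich_fc = 1.5, enrich_q = 0.05),
    broad   = list(enrich_fc = 1.3, enrich_q = 0.05, aberrant_q = 0.05))
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(threshold_config, args)
  attr(cfg, "preset") <- preset
  cfg
}

#' @export
print.threshold_config <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("Threshold configuration",
      if (!is.null(preset)) paste0(" (preset: ", preset, ")"), "\n", sep = "")
  cat(sprintf("  activity: normalized counts > %g in every replicate\n",
              x$activity_threshold))
  cat(sprintf("  enriched: fold >= %g, q < %g; shared: fold < %g, q >= %g\n",
              x$enrich_fc, x$enrich_q, x$shared_fc, x$shared_q))
  cat(sprintf("  respond: fold >= %g vs both controls, p < %g\n",
              x$respond_fc, x$respond_p))
  cat(sprintf("  proximity to target: %g-fold; aberrant: %g-fold, q < %g\n",
              x$proximity_fc, x$aberrant_fc, x$aberrant_q))
  cat(sprintf("  pseudocount: %g\n", x$pseudocount))
  invisible(x)
}
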