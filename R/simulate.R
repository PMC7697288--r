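#' Configuration of the synthetic reprogramming experiment
#'
#' Describes a desk-scale negative-binomial emulation of a reprogramming
#' RNA-seq design: four sample conditions (start cells, vector controls,
#' reprogramming intermediates, target cells), four planted gene classes
#' (target-enriched, start-enriched, shared, silent) plus exclusively
#' expressed activatome/erasome genes, library-size variation, and per-gene
#' reprogramming completeness. Counts are NB with variance
#' `mu + dispersion * mu^2`; a dispersion of 0 gives Poisson counts.
#'
#' Reprogramming means interpolate between start and target on the log scale,
#' `log2 mu_reprog = (1 - c) log2 mu_start + c log2 mu_target`, for the
#' legitimate categories (proper c = 1, insufficient c = 0.5, none c = 0 by
#' default); aberrant categories plant their own levels: `wrong` moves
#' opposite to the required direction by `wrong_lfc` log2 units, `over`
#' overshoots the target by `over_fc`-fold, and `unwanted` moves a shared
#' gene by `unwanted_fc`-fold.
#'
#' @param n_up,n_down,n_shared,n_silent,n_activatome,n_erasome Genes per
#'   planted class (activatome/erasome genes belong to the up/down classes
#'   but are expressed in only one cell type).
#' @param lfc Planted |log2 fold change| of the enriched classes: a single
#'   value, or a range `c(lo, hi)` sampled uniformly per gene.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline normalized-count means (defaults put the central 95% in
#'   roughly 200-2000).
#' @param silent_meanlog,silent_sdlog Log-normal parameters of silent-side
#'   means (well below the activity threshold).
#' @param dispersion NB dispersion alpha (>= 0).
#' @param replicates Named integer vector of replicates per condition
#'   (each >= 2).
#' @param size_factor_sdlog Log-normal sd of the per-sample library-size
#'   factors.
#' @param completeness Named list of per-class category fractions: elements
#'   `up`, `down` (over `proper`, `insufficient`, `none`, `wrong`, `over`)
#'   and `shared` (over `none`, `unwanted_up`, `unwanted_down`); each must
#'   sum to 1.
#' @param completeness_values Completeness c for the legitimate categories.
#' @param wrong_lfc,over_fc,unwanted_fc Aberrant effect sizes (see above).
#' @param control_offset_sdlog Optional log-normal off-target perturbation of
#'   the vector-control means (0 = controls share start means exactly).
#' @param time_label Time label written into the metadata.
#' @param seed Default seed used by [simulate_experiment()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_up = 150, n_down = 150, n_shared = 300,
                              n_silent = 20, n_activatome = 30,
                              n_erasome = 30,
                              lfc = c(1.5, 3),
                              baseline_meanlog = log(632.5),
                              baseline_sdlog = 0.587,
                              silent_meanlog = log(4), silent_sdlog = 0.5,
                              dispersion = 0.05,
                              replicates = c(start = 4, vector_control = 4,
                                             reprogramming = 2, target = 3),
                              size_factor_sdlog = 0.2,
                              completeness = list(
                                up = c(proper = 0.78, insufficient = 0.05,
                                       none = 0.17, wrong = 0, over = 0),
                                down = c(proper = 0.10, insufficient = 0.25,
                                         none = 0.65, wrong = 0, over = 0),
                                shared = c(none = 1, unwanted_up = 0,
                                           unwanted_down = 0)),
                              completeness_values = c(proper = 1,
                                                      insufficient = 0.5,
                                                      none = 0),
                              wrong_lfc = 1.5, over_fc = 2.5,
                              unwanted_fc = 4,
                              control_offset_sdlog = 0,
                              time_label = "48h",
                              seed = NULL) {
  cfg <- as.list(environment())
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (length(lfc) == 1L) cfg$lfc <- c(lfc, lfc)
  if (any(cfg$lfc <= 0)) stop("planted lfc must be > 0", call. = FALSE)
  req <- c("start", "vector_control", "reprogramming", "target")
  if (!all(req %in% names(replicates)))
    stop("replicates must name all four conditions", call. = FALSE)
  if (any(replicates < 2))
    stop("at least 2 replicates per condition", call. = FALSE)
  for (k in names(completeness)) {
    if (abs(sum(completeness[[k]]) - 1) > 1e-8)
      stop("completeness fractions for '", k, "' must sum to 1",
           call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# integer allocation of n genes to categories by fraction (largest-remainder)
.alloc <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  rep(names(fracs), times = base)
}

#' Simulate a reprogramming count experiment with ground truth
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (overrides `cfg$seed`); required from one of the
#'   two.
#' @return List with `counts` (a [count_matrix()]) and `truth` (data frame of
#'   class `synthetic_truth`: planted class, flags, lfc, PIANO category,
#'   completeness and the three expected means per gene). The seed is
#'   recorded on both objects.
#' @export
simulate_experiment <- function(cfg = simulation_config(), seed = cfg$seed) {
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)

  draw_base <- function(n) stats::rlnorm(n, cfg$baseline_meanlog,
                                         cfg$baseline_sdlog)
  draw_silent <- function(n) stats::rlnorm(n, cfg$silent_meanlog,
                                           cfg$silent_sdlog)
  draw_lfc <- function(n) stats::runif(n, cfg$lfc[1L], cfg$lfc[2L])

  blocks <- list()
  add <- function(n, class, prefix, mu_s, mu_t, acto = FALSE, eras = FALSE) {
    if (n == 0L) return(invisible())
    fr <- switch(class, up = cfg$completeness$up,
                 down = cfg$completeness$down,
                 shared = cfg$completeness$shared,
                 silent_both = c(none = 1))
    cat_short <- .alloc(n, fr)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      gene = sprintf("%s%04d", prefix, seq_len(n)),
      class = class, in_activatome = acto, in_erasome = eras,
      mu_start = mu_s, mu_target = mu_t, cat_short = cat_short,
      stringsAsFactors = FALSE)
  }
  b <- draw_base(cfg$n_up)
  add(cfg$n_up, "up", "UPG", b, b * 2^draw_lfc(cfg$n_up))
  b <- draw_base(cfg$n_down)
  add(cfg$n_down, "down", "DNG", b * 2^draw_lfc(cfg$n_down), b)
  b <- draw_base(cfg$n_shared)
  add(cfg$n_shared, "shared", "SHG", b, b)
  b <- draw_silent(cfg$n_silent)
  add(cfg$n_silent, "silent_both", "SIG", b, b)
  add(cfg$n_activatome, "up", "ACT", draw_silent(cfg$n_activatome),
      draw_base(cfg$n_activatome), acto = TRUE)
  add(cfg$n_erasome, "down", "ERA", draw_base(cfg$n_erasome),
      draw_silent(cfg$n_erasome), eras = TRUE)
  truth <- do.call(rbind, blocks)
  if (is.null(truth) || !nrow(truth)) stop("empty simulation", call. = FALSE)

  # reprogramming mean per gene from the planted category
  cv <- cfg$completeness_values
  l2s <- log2(truth$mu_start); l2t <- log2(truth$mu_target)
  up_dir <- ifelse(truth$class == "down", -1, 1)  # required direction
  comp <- ifelse(truth$cat_short %in% names(cv), cv[truth$cat_short], NA_real_)
  mu_r <- 2^((1 - comp) * l2s + comp * l2t)           # legitimate categories
  wrong <- truth$cat_short == "wrong"
  mu_r[wrong] <- truth$mu_start[wrong] *
    2^(-up_dir[wrong] * cfg$wrong_lfc)
  over <- truth$cat_short == "over"
  mu_r[over] <- truth$mu_target[over] * cfg$over_fc^(up_dir[over])
  mu_r[truth$cat_short == "unwanted_up"] <-
    truth$mu_start[truth$cat_short == "unwanted_up"] * cfg$unwanted_fc
  mu_r[truth$cat_short == "unwanted_down"] <-
    truth$mu_start[truth$cat_short == "unwanted_down"] / cfg$unwanted_fc
  truth$mu_reprog <- mu_r
  truth$completeness <- comp
  truth$lfc <- l2t - l2s
  truth$category <- .planted_category(truth$class, truth$cat_short)
  truth$cat_short <- NULL

  # vector-control means: start means, optionally perturbed off-target
  mu_c <- truth$mu_start
  if (cfg$control_offset_sdlog > 0)
    mu_c <- mu_c * stats::rlnorm(nrow(truth), 0, cfg$control_offset_sdlog)

  conds <- c("start", "vector_control", "reprogramming", "target")
  reps <- cfg$replicates[conds]
  sample_id <- unlist(lapply(conds, function(cn)
    paste0(cn, "_", seq_len(reps[[cn]]))))
  meta <- data.frame(sample_id = sample_id,
                     condition = rep(conds, times = reps),
                     replicate = unlist(lapply(reps, seq_len)),
                     time_label = cfg$time_label,
                     stringsAsFactors = FALSE)
  sf <- stats::rlnorm(nrow(meta), 0, cfg$size_factor_sdlog)
  mu_of <- list(start = truth$mu_start, vector_control = mu_c,
                reprogramming = truth$mu_reprog, target = truth$mu_target)
  counts <- vapply(seq_len(nrow(meta)), function(j) {
    mu <- mu_of[[meta$condition[j]]] * sf[j]
    if (cfg$dispersion == 0) stats::rpois(nrow(truth), mu)
    else stats::rnbinom(nrow(truth), mu = mu, size = 1 / cfg$dispersion)
  }, numeric(nrow(truth)))
  dimnames(counts) <- list(truth$gene, meta$sample_id)

  cm <- count_matrix(counts, meta)
  attr(cm, "seed") <- seed
  attr(cm, "true_size_factors") <- stats::setNames(sf, meta$sample_id)
  class(truth) <- c("synthetic_truth", "data.frame")
  attr(truth, "seed") <- seed
  list(counts = cm, truth = truth)
}

.planted_category <- function(class, cat_short) {
  out <- character(length(class))
  up <- class == "up"; down <- class == "down"
  out[cat_short == "none"] <- "no_response"
  out[up & cat_short == "proper"] <- "proper_up"
  out[up & cat_short == "insufficient"] <- "insufficient_up"
  out[up & cat_short == "wrong"] <- "wrong_down"
  out[up & cat_short == "over"] <- "over_up"
  out[down & cat_short == "proper"] <- "proper_down"
  out[down & cat_short == "insufficient"] <- "insufficient_down"
  out[down & cat_short == "wrong"] <- "wrong_up"
  out[down & cat_short == "over"] <- "over_down"
  out[cat_short %in% c("unwanted_up", "unwanted_down")] <-
    cat_short[cat_short %in% c("unwanted_up", "unwanted_down")]
  out[class == "silent_both"] <- "not_applicable"
  out
}

#' Compare pipeline calls with the planted truth
#'
#' @param truth A `synthetic_truth` table.
#' @param partition A `reprogramome_partition` over the same genes.
#' @param piano_calls Optional `piano_calls` table.
#' @return List with the class confusion matrix, per-class sensitivity, the
#'   false-enrichment rate (planted shared genes called enriched), and — when
#'   PIANO calls are given — the category confusion matrix and per-category
#'   recall (diagonal fraction).
#' @export
evaluate_recovery <- function(truth, partition, piano_calls = NULL) {
  idx <- match(truth$gene, partition$gene)
  if (anyNA(idx)) stop("partition must cover all simulated genes",
                       call. = FALSE)
  lv <- c("up", "down", "shared", "silent_both", "uncertain")
  class_confusion <- table(truth = factor(truth$class, levels = lv),
                           called = factor(partition$class[idx], levels = lv))
  sens <- diag(class_confusion) / pmax(rowSums(class_confusion), 1L)
  shared <- truth$class == "shared"
  fer <- if (any(shared))
    mean(partition$class[idx][shared] %in% c("up", "down")) else NA_real_
  out <- list(class_confusion = class_confusion,
              class_sensitivity = sens,
              false_enrichment_rate = fer)
  if (!is.null(piano_calls)) {
    j <- match(truth$gene, piano_calls$gene)
    keep <- !is.na(j)
    pc <- table(truth = factor(truth$category[keep], levels = .piano_levels),
                called = factor(piano_calls$category[j[keep]],
                                levels = .piano_levels))
    out$piano_confusion <- pc
    out$piano_recall <- diag(pc) / pmax(rowSums(pc), 1L)
  }
  out
}
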