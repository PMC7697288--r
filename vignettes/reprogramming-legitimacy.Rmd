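---
title: "Evaluating reprogramming legitimacy from RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reprogramming legitimacy from RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprolegit)
```

## The question the package answers

Cell-fate reprogramming — e.g. fibroblasts pushed toward pluripotency by the
OSKM factors — succeeds in only a small fraction of cells, so bulk
transcriptional responses cannot simply be read as progress. A more
disciplined question is: of the genes that *must* change to convert the
start cell type into the target cell type (the **reprogramome**), which ones
actually moved, in the right direction, far enough, and no further? This
package turns that question into a fixed sequence of computations on a
gene-level count matrix with four sample roles: `start` cells, `vector_control`
cells (carrying the delivery vector but no reprogramming factors),
`reprogramming` intermediates, and `target` cells.

The stages are:

1. **Normalization** — median-of-ratios size factors; all later thresholds
   are defined on this normalized-count scale.
2. **Activity calls** — a gene is *active* in a condition only when every
   replicate strictly exceeds a normalized-count threshold (default 50).
3. **Contrast statistics** — per-gene means, log2 fold changes of
   pseudocounted means, Welch tests on log2 replicate values, BH q-values
   within the analyzed gene universe.
4. **Sub-reprogramome partition** — each gene of the analyzed set becomes
   `up` (target-enriched; the upreprogramome), `down` (start-enriched; the
   downreprogramome), `shared`, `silent_both`, or `uncertain`, with
   activatome/erasome flags for genes expressed in only one cell type.
5. **PIANO classification** — each gene's response in the reprogramming
   samples is judged against all three references and labelled proper,
   insufficient, aberrant (wrong/unwanted/over, each up and down), or no
   response.
6. **Quantification** — summed |log2 FC| over the up and down classes.
7. **Similarity** — row-scaled complete-linkage clustering and
   nearest-centroid correlation assignment of reprogramming samples to
   start or target.

## The decision rules and their thresholds

All cutoffs live in one object, `threshold_config()`, with three named
enrichment presets: `strict` (2-fold, q < 0.01), `lenient` (1.5-fold,
q < 0.05) and `broad` (1.3-fold, q < 0.05). The two-tier partition
(`tiered_partition()`) applies the strict preset first and re-evaluates
unresolved genes at the lenient preset, recording the tier of every
enriched call.

The PIANO table for an up-class gene, in priority order:

| rule | condition | category |
|---|---|---|
| 1 | change vs start or vs vector control below `respond_fc` (1.5), directions inconsistent, or p ≥ `respond_p` (0.05) | `no_response` |
| 2 | consistent, significant change *downward* | `wrong_down` |
| 3 | upward, lands ≥ `aberrant_fc` (2) above target with a significant reprogramming-vs-target gap | `over_up` |
| 4 | upward, within `proximity_fc` (1.5) of the target level | `proper_up` |
| 5 | upward, still > `proximity_fc` short of target | `insufficient_up` |

Down-class genes mirror the table. Shared genes may only earn
`unwanted_up`/`unwanted_down` (a significant ≥ `aberrant_fc` move against
both references that also lands ≥ `aberrant_fc` beyond the target level);
everything else is `no_response`. Silent and uncertain genes are
`not_applicable`: forcing uncertain genes through the shared-gene rules
would contaminate the unwanted-reprogramming scan with genes whose baseline
classification is itself unsettled.

Design choices worth knowing about:

* **Both references.** A response must clear the bar against the start
  cells *and* the vector control, which excludes vector/culture artifacts;
  effect sizes are reported against start. A change that points up against
  one reference and down against the other counts as no response.
* **Priority order.** `no_response` → `wrong` → `over` → `proper` →
  `insufficient`. Aberrant calls are deliberately not maskable by marginal
  proper calls; where a gene satisfies both the over and proper windows the
  over call wins, and the significance requirement on the
  reprogramming-vs-target gap keeps marginal overshoots (large ratio,
  noisy) out of the over bin.
* **p vs q.** The response screen uses an unadjusted p (default 0.05) while
  enrichment screens use BH q-values, mirroring how the two kinds of screens
  are usually reported; both are separate fields in the config rather than
  harmonized.
* **Strictness is two-sided for insufficiency.** Loosening the proximity
  window (1.5 → 2) *reduces* the insufficient count; `threshold_sensitivity()`
  tabulates the categories across such settings so this dependence is
  explicit rather than buried.

## Numerical conventions

* Activity uses a strict inequality: a replicate at exactly the threshold
  is inactive.
* Fold changes are ratios of pseudocounted means (`pseudocount` = 1
  normalized count), keeping every log2 ratio finite, including for
  activatome/erasome genes with zero counts on one side.
* BH adjustment is performed within the analyzed gene set (e.g. the
  pathway), not transcriptome-wide: the q-values accompany set-level
  screens and are only comparable inside the universe they were adjusted
  in.
* Quantification floors the silent side of activatome/erasome genes at the
  activity threshold before the ratio, so a gene switched on from zero
  contributes what can be claimed above the detection level rather than an
  arbitrarily large ratio. The summed-|LFC| definition is the simplest
  reading of "amounts of reprogramming in log2 fold change units"; per-gene
  addends are emitted so any alternative weighting can be recomputed.
* Size factors are not rescaled after the median step, so the activity
  threshold keeps an absolute meaning on the normalized scale. Whether 50
  normalized counts is the right activity level for a *different* dataset
  is inherently dataset-dependent; it is a config knob, not a constant.
* `contrast_stats()` is a lightweight log-scale Welch test, not a
  negative-binomial Wald test. For exact replication of an external DE
  engine's output, `ingest_de_table()` accepts its table and the
  classification layers run unchanged.
* Nearest-centroid assignment breaks no ties: an exactly ambiguous sample
  is flagged. Clustering uses Euclidean distance and complete linkage on
  row-scaled log2 values — the defaults of the usual heat-map machinery —
  and both the dendrogram and the correlation statistic are reported, the
  latter because dendrogram-topology claims are brittle.

## What the simulator emulates — and what it does not

`simulation_config()` describes a negative-binomial experiment shaped like
a typical reprogramming study: 4 start replicates, 4 vector controls,
2 reprogramming replicates, 3 target replicates; baseline means log-normal
with the central 95% in roughly 200–2000 normalized counts; NB dispersion
0.05; log-normal library-size factors (sd 0.2); planted |log2 FC| drawn
from U(1.5, 3) for enriched classes. A single fixed planted fold change
would make every enriched gene share one log-scale shift, which a
Pearson-correlation centroid assignment cannot see (correlation is
shift-invariant), so a spread is the default; analyses that need a pinned
effect size set `lfc` explicitly.

Each gene carries a **completeness** value `c`: the reprogramming-state
mean interpolates between start and target on the log scale,
`log2 mu_r = (1-c) log2 mu_s + c log2 mu_t`, consistent with all decision
rules being fold-based. Defaults plant the structure reported for a
successfully reprogrammed pathway (up-class genes mostly complete, a few
insufficient at c = 0.5, some non-responders); aberrant categories plant
their own levels (wrong: 1.5 log2 units opposite the required direction;
over: 2.5-fold beyond target; unwanted: 4-fold from a shared baseline).
Vector controls share the start means exactly unless an off-target
perturbation knob is set.

Two honest limitations of the emulation. First, median-of-ratios
normalization assumes most genes do not change; a small simulated universe
with an asymmetric planted signal produces composition bias (the size
factor absorbs part of the signal), so simulated designs here keep shared
genes in the majority or plant up/down symmetrically — as in real data,
where normalization runs on the whole transcriptome and any one pathway is
negligible. Second, the generator draws independent NB counts per gene:
no gene–gene correlation, no batch structure beyond library size, no
zero inflation, and no time-course autocorrelation. Passing recovery tests
therefore demonstrates that the decision rules are implemented correctly
and are well-calibrated under the stated noise model, not that any
particular biological dataset will be called correctly.

## Problem sizes and test conditions

The packaged checks run at desk scale, chosen so the full suite completes
in well under a minute of simulation time while keeping Monte-Carlo error
small relative to every margin tested: partition recovery uses 500 up +
500 down + 1000 shared + 100 silent genes at |log2 FC| = 2, dispersion
0.05, 4 replicates per condition (sensitivity ≥ 0.95 demanded); PIANO
recovery plants all eleven categories at strong effects (|log2 FC| = 3,
overshoot 3-fold, unwanted 4-fold — each planted effect at least ~2
standard errors beyond its decision bar) and demands ≥ 0.90 per-category
recall; null calibration uses 5000 static genes (≤ 1% unwanted calls,
p-value uniformity). The rule table itself is checked against an
independently coded oracle on an exhaustive grid of ~36,000
fold–significance–class combinations, and the BH step is checked against a
naive step-up evaluation on 1000 random p-vectors.

## Running the workflow

The `analysis/` directory holds the numbered drivers:
`01_simulate.R` writes the synthetic experiment and its truth table;
`02_partition.R` partitions and quantifies; `03_piano.R` classifies
responses and scans thresholds; `04_similarity.R` reports cluster
assignments and scores all calls against the truth. `scripts/acceptance.R`
recomputes the headline quantities from scratch into a single JSON file.
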