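---
title: "Methods: integrated single-cell atlas characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated single-cell atlas characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`bcatlas` implements the computational core of an integrated breast-cancer
single-cell atlas analysis: quality control, batch-mixing evaluation,
compartment annotation, expression-based malignancy calling, gene-set
activity, a bootstrap-stabilized cluster taxonomy, compositional statistics,
and clade-level survival association. It is built for desk-scale synthetic
and downsampled data; every stage is an exported, individually testable
function. This vignette documents the models, the numerical choices behind
them, what the bundled generator emulates, and the package's limitations.

## The data model

All single-cell stages operate on a `cell_bundle`: a sparse non-negative
count matrix (cells × genes) plus a cell-metadata tibble (at least `cell_id`,
usually `batch` and `donor`) and a gene-metadata tibble (`symbol`, plus
`chromosome`/`start` for the CNV stages). Everything downstream returns
plain tibbles, so results compose with dplyr/ggplot2 directly.

## Quality control

`mad_outlier_filter()` removes cells using adaptive per-batch thresholds
rather than fixed cutoffs: a cell is dropped iff any of total counts,
detected genes (both on the log1p scale, two-sided) or mitochondrial
fraction (raw scale, upper side only) falls outside
median ± 3 × MAD for its batch, with the 1.4826 normal-consistency
constant. Two deliberate conventions: a metric whose MAD is zero filters
nothing (a degenerate spread must not delete a batch), and batches under 10
cells pass through unfiltered with a warning (no stable median/MAD exists).
`lognormalize()` is the standard `log1p(count / total × 10^4)`; zeros map to
zeros so sparsity is preserved. `select_hvg()` ranks genes by variance
standardized against a loess mean–variance trend (span 0.5, degree 2), so
highly expressed genes do not dominate; ties break by gene symbol for
determinism and constant genes rank strictly last. `doublet_score_lite()`
scores each cell by the fraction of artificial doublets (averaged random
count pairs) among its k nearest neighbors in a joint PCA.

## Batch-mixing metrics and the baseline corrector

Three complementary metrics quantify batch mixing of any embedding:

* `batch_asw()` — mean of `1 − |silhouette|` of the batch labels; 1 means
  batches are indistinguishable.
* `kbet()` — per sampled cell, a chi-square goodness-of-fit test of the
  k-nearest-neighborhood batch composition against global proportions; the
  statistic reported is the acceptance rate at level α, which approaches
  1 − α under perfect mixing. k defaults to min(50, 10% of cells) and is
  raised automatically when an expected neighborhood count falls below 1
  (the chi-square approximation would otherwise break).
* `ilisi()` — inverse Simpson index of batch probabilities under Gaussian
  neighbor weights whose bandwidth is tuned per cell by binary search to a
  target perplexity (30), ranging from 1 (unmixed) to the number of batches.

`rank_integrations()` aggregates the three (all oriented higher = better)
by the mean of per-metric ranks, mirroring how integration methods are
chosen in benchmark studies. The built-in corrector,
`baseline_batch_center()`, subtracts the per-batch mean in embedding space —
deliberately the simplest location-only correction, serving as the reference
point that any serious integration should beat.

## Annotation

`graph_cluster()` builds a kNN graph, re-weights edges by shared-nearest-
neighbor Jaccard overlap (pruning below 1/15), and runs Louvain at a given
resolution. Compartments (epithelial / immune / stromal) are assigned at
cluster level by `marker_compartments()`: per-panel mean z-scored expression
of canonical markers (EPCAM/KRT8/KRT18; PTPRC/CD3D/CD3E/CD68;
COL1A1/COL1A2/ENG), cluster-averaged, argmax with deterministic tie-breaks.
`consensus_relabel()` merges multiple annotation sources by per-cell
majority vote with the cluster compartment as tie-breaker; it is idempotent.
`donor_entropy_filter()` flags donor-specific clusters via the normalized
donor entropy `H / ln(D)` (0 by convention when a single donor is present);
clusters under 0.3 are excluded from taxonomy building, removing
patient-private clonal expansions. `stratified_markers()` performs
one-vs-rest differential expression with batch as a stratum: tie-corrected
rank-sum z per batch, combined with weights `sqrt(n1·n2/(n+1))`
(a van Elteren-style design-based weighting), so genes shifted only between
batches are not called markers. `nearest_centroid_label()` is a Spearman
nearest-centroid subtyper for pseudo-bulk profiles; rank-based, hence
invariant to monotone transforms.

## Malignancy from expression-derived copy number

`cnv_smooth()` is a deliberately transparent, non-HMM estimator: per-gene
relative log expression against the mean of a non-malignant reference,
smoothed by a 101-gene moving average along genomic order strictly within
chromosomes, then median-centered per cell; genes whose reference mean
count falls below 0.1 are dropped. Scores are deviations (0 =
copy-neutral). `malignancy_score()` is the mean absolute deviation over
retained genes. `classify_malignant()` samples 100 non-epithelial negative
controls per dataset, takes the equal-tailed 90% interval of their scores,
and flags epithelial cells outside their dataset's interval. Control ids
and intervals are returned for audit. By construction held-out copy-neutral
cells are flagged at roughly the interval's tail mass (~10%) — the
package's calibration tests verify exactly that.

## Gene-set activity

`aucell_score()` ranks genes per cell (random tie-break under a fixed seed)
and scores the area under the recovery curve of set members within the top
5% of the ranking, normalized to [0, 1] by the maximum attainable area.
`ssgsea_project()` is a single-sample weighted KS statistic for bulk
profiles. Its rank weight is `|r − (n+1)/2|^τ` with τ = 0.25 — centered
absolute ranks rather than the conventional raw ranks. This choice makes
the score exactly antisymmetric under reversal of the expression ordering
(`score(set, −x) = −score(set, x)`), so up- and down-regulation are treated
symmetrically; the property is verified to machine precision in the test
suite. Both scores are invariant to monotone transforms of expression.

## Cluster taxonomy

`recursive_bipartition()` organizes clusters into a binary tree: at each
node the member clusters' centroids are split by 2-means; over 400 bootstrap
resamples (per-cluster resampling, sizes square-root downsampled so large
clusters do not dominate their centroid) the modal bipartition is adopted
and its frequency reported as the node's stability. `node_signatures()`
derives per-node gene signatures by batch-stratified rank-sum between the
two clades (BH q < 0.05, capped at 25 genes per direction).
`rf_discriminative_factors()` trains a class-balanced random forest (500
trees, equal-size stratified sampling) on arbitrary per-cell features to
rank what distinguishes the clades at a chosen depth, reporting Gini
importances and each top feature's higher-mean side.
`taxonomy_to_newick()` serializes the tree with stabilities (and optional
annotations such as survival calls) as node labels.

## Composition

`ctds()` computes the cell-type diversity score: Shannon entropy of
per-sample type proportions normalized by `ln(K)` over the compartment's
type universe, with the Miller–Madow small-sample correction
`(K_observed − 1)/(2n)` applied before normalization and the result clipped
to [0, 1]. A single-type universe scores 0 and is flagged rather than
producing 0/0. `differential_abundance()` tests centered log-ratio
transformed proportions (pseudocount 0.5; rows sum to zero exactly) per
cell type against a contrast — grade is dichotomized 3 vs 1–2 — with the
remaining covariates (subtype, age, batch) as fixed effects; Wald CIs and
BH adjustment across types. Rank-deficient designs abort naming the
aliased terms instead of silently dropping them.

## Survival

`fit_cox()` is a from-scratch Cox proportional-hazards fit with Breslow
tie handling: Newton–Raphson with step-halving, convergence at gradient
norm < 1e-8, monotone-likelihood detection at |β| > 15. It matches
`survival::coxph(ties = "breslow")` to numerical precision (verified in the
tests, which also check it against a grid-search partial-likelihood oracle);
the hand-rolled version exists because its numerics are part of the
package's contract, with the established implementation kept as an
independent cross-check. `fisher_combine()` is Fisher's method
(−2Σln p ~ χ²(2m), zero p-values clipped to the smallest positive double
with a warning). `node_survival_scan()` projects every clade's signature,
plus inflammation and proliferation confounder sets, onto each bulk cohort
with `ssgsea_project()`, fits `time ~ clade + age + inflammation +
proliferation` on z-scaled scores (hazard ratios per SD), BH-adjusts within
cohort, combines cohorts per clade with Fisher's method, and labels clades
advantage/disadvantage at q < 0.05.

## The synthetic generator

Real atlas-scale data (hundreds of thousands of cells across eight
datasets) cannot ship with a package, so `simulate_atlas()` provides a
fully specified stand-in whose planted structure exercises every stage:

* Counts are negative binomial: gene log-means ~ N(log 0.3, 1), NB size
  ~ logNormal(log 10, 0.5), per-cell depth ~ logNormal(log 4000, 0.25);
  expected profiles are depth-scaled softmaxes of the log-means.
* Three compartments with the canonical marker panels up-shifted (+2 on the
  log scale); nine cell types, including four malignant epithelial types
  arranged in a planted two-level hierarchy (two super-groups), each type
  and super-group carrying a 10-gene +1.5 signature drawn from a reserved
  chr1/chr2 block so signatures never collide with markers or the CNV
  segment.
* Batch effects are additive N(0, 0.5) shifts on the log-mean per
  batch × gene — a location effect the baseline corrector can remove,
  which is exactly what a baseline should face.
* Malignant cells carry a 50-gene 2× copy-number gain on chromosome 3,
  applied after depth scaling so the segment's expected counts double.
* 5% doublets: expected profiles of random singlet pairs averaged and
  resampled.
* Grade-3 donors double their T-cell weight — the planted compositional
  effect recovered by the differential-abundance stage.

Companion generators give a bulk survival cohort
(`simulate_bulk_cohort()`: exponential hazard `h0·exp(βa)` with independent
exponential censoring and signature genes shifted by the latent activity)
and a composition table (`simulate_composition()`). Defaults are
deliberately desk-scale (1,200 singlets, 600 genes) and were fixed once,
up front; tests and the acceptance script run against these defaults.

## Limitations

* The CNV estimator is a moving average, not an HMM: it resolves one large
  planted segment cleanly but has no changepoint model, and per-cell median
  centering leaks a small uniform offset into copy-neutral chromosomes of
  aneuploid cells.
* The baseline batch corrector removes location effects only; it cannot fix
  batch-specific scale or nonlinear distortions, and is meant as a floor
  for comparison, not an integration method.
* The generator's batch effect matches the corrector's model; conclusions
  about correction quality on real data do not follow.
* `ssgsea_project()` with centered-rank weights is a symmetrized variant,
  not a reimplementation of the published ssGSEA weighting; scores are
  comparable within, not across, scoring schemes.
* The Cox fit covers right censoring with Breslow ties only — no Efron
  ties, stratification, or time-varying covariates.
* All stages materialize dense matrices at some point and target thousands,
  not millions, of cells.
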