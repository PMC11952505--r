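# bcatlas

Characterization toolkit for integrated single-cell breast-cancer atlases:
quality control, batch-mixing metrics, compartment annotation,
expression-based malignancy calling, gene-set activity, a
bootstrap-stabilized cluster taxonomy, compositional statistics, and
clade-level survival association — implemented as small, pipeable,
tidyverse-native functions over a sparse count container.

## The scientific problem

Integrating tumor single-cell RNA-seq datasets collected across studies
raises a chain of questions that this package answers quantitatively:

* **Is the integration any good?** Batch mixing is scored three ways and
  aggregated: the batch silhouette score (mean of `1 − |silhouette|`), the
  kBET acceptance rate (chi-square tests of k-nearest-neighborhood batch
  composition against global proportions, acceptance ≈ 1 − α when mixed),
  and iLISI (perplexity-tuned inverse Simpson index of neighborhood batch
  probabilities, ranging 1 → number of batches).
* **Which cells are malignant?** Copy-number deviations are inferred from
  expression — relative log expression against a non-malignant reference,
  averaged over a moving window along genomic order within chromosomes,
  median-centered per cell — and summarized per cell as

  `MalignancyScore = Σ |CNVscore| / #genes`.

  Epithelial cells are flagged malignant when their score leaves the
  equal-tailed 90% interval of 100 sampled non-epithelial controls from the
  same dataset.
* **How are tumors composed?** The cell-type diversity score

  `CTDS = (H + (K_obs − 1)/(2n)) / ln K` (clipped to [0, 1])

  is normalized Shannon entropy with a Miller–Madow small-sample
  correction; differential abundance is tested on centered log-ratio
  proportions with covariate adjustment and BH correction.
* **Do transcriptional clades carry prognosis?** Clusters are organized
  into a binary taxonomy by bootstrap-stabilized recursive 2-means
  bipartition; each clade's signature is projected onto bulk cohorts by a
  single-sample rank statistic and tested in a from-scratch Breslow Cox
  model `time ~ clade + age + inflammation + proliferation`, with BH
  adjustment within cohorts and Fisher's method (`−2Σln p ~ χ²(2m)`)
  across them.

Atlas-scale inputs cannot ship with a package, so `simulate_atlas()`
generates a fully specified negative-binomial stand-in with planted batch
effects, marker-defined compartments, a two-level malignant-type
hierarchy, a 50-gene 2× copy-number gain, doublets, and a grade-linked
composition shift — every pipeline stage is validated against this planted
truth. See `vignettes/atlas-methods.Rmd` for models and numerical choices.

## Worked example

```r
library(bcatlas)

# 1. simulate a small multi-batch tumor atlas with planted structure
sim <- simulate_atlas(sim_config(seed = 1))
sim$bundle
#> <cell_bundle> 1260 cells x 600 genes
#>   cell metadata:  cell_id, batch, donor, age, grade, subtype
#>   gene metadata:  symbol, chromosome, start

# 2. QC, normalize, embed
qc <- mad_outlier_filter(sim$bundle)
norm <- lognormalize(qc$bundle)
emb <- pca_embed(norm, select_hvg(norm, 300), d = 10)
batch <- qc$bundle$cells$batch
centered <- baseline_batch_center(emb, batch)

# 3. score batch mixing: raw PCA vs the baseline-centered embedding
rank_integrations(list(raw = emb, centered = centered), batch, seed = 1)
#> # A tibble: 2 × 5
#>   embedding batch_asw_score kbet_acceptance ilisi_mean aggregate_rank
#>   <chr>               <dbl>           <dbl>      <dbl>          <dbl>
#> 1 centered            0.995           0.922       2.66              1
#> 2 raw                 0.546           0           1.02              2

# 4. cluster and annotate compartments from canonical markers
cl <- graph_cluster(centered, k = 15, resolution = 0.5, seed = 1)
comp <- marker_compartments(qc$bundle, cl)
table(comp$cell_compartment)
#> epithelial     immune    stromal
#>        615        388        244

# 5. malignancy from expression-derived copy number
#    (window 21 suits the 120-genes-per-chromosome simulation)
ref <- which(comp$cell_compartment != "epithelial")
cnv <- cnv_smooth(qc$bundle, reference_cells = ref, window = 21)
mal <- classify_malignant(malignancy_score(cnv), batch,
                          comp$cell_compartment == "epithelial", seed = 1)
truth <- sim$truth$cells[match(qc$bundle$cells$cell_id,
                               sim$truth$cells$cell_id), ]
epi <- comp$cell_compartment == "epithelial"
table(called = mal$cells$malignant[epi], truth = truth$malignant[epi])
#>        truth
#> called  FALSE TRUE
#>   FALSE   140   14
#>   TRUE     60  401

# 6. compositional analysis on a 40-sample cohort with a planted
#    2-fold T-cell enrichment in grade-3 tumors
tab <- simulate_composition(n_samples = 40, affected_type = 1,
                            lfc = log(2), seed = 1)
differential_abundance(tab, contrast = "grade") |> dplyr::filter(q < 0.05)
#> # A tibble: 1 × 8
#>   cell_type estimate     se ci_low ci_high           p          q direction
#>   <chr>        <dbl>  <dbl>  <dbl>   <dbl>       <dbl>      <dbl> <chr>
#> 1 type01       0.613 0.0929  0.431   0.796 0.000000194 0.00000194 enriched
```

The malignancy stage recovers 401 of 415 planted malignant cells (96.6%);
normal epithelial cells are flagged above the nominal 10% control rate
because their profiles genuinely differ from the immune/stromal reference —
the calibration tests verify the nominal rate on matched held-out controls.
The recovered abundance coefficient (0.613) is the planted `log(2)` shift
as seen through the centered log-ratio transform, which spreads part of any
single-type change across the remaining types.

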