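# betscreen

Integrative screen analysis for nominating mediator genes of
BET-bromodomain-inhibitor (BETi) response in MYC-driven medulloblastoma.

BET inhibitors such as JQ1 and IBET151 suppress transcription of thousands of
enhancer-driven genes at once, which makes it hard to say *which* suppressed
gene actually causes the loss of viability. `betscreen` implements the
three-way evidence integration that answers this: a gene is nominated as a
**mediator** of drug response when it is

1. **transcriptionally suppressed** by drug — comparative marker selection
   with a signal-to-noise statistic, label-permutation p-values and
   Benjamini–Hochberg q (call: p < 0.05 and q < 0.1, downregulated);
2. **cell-essential** — CRISPR knockout dropout scores converted to
   dependency probabilities by a two-component empirical mixture model
   (call: probability > 0.35 and FDR < 0.2); and
3. **sufficient to rescue** the drug effect — ORF overexpression screens
   under drug, scored as log2 fold change versus the initial time point
   (call: LFC > 1.5 and q < 0.25).

The package also implements the surrounding quantifications: gene-set overlap
tests (hypergeometric/Fisher and Pearson chi-square), cross-drug rescue
concordance (OLS R²), gene-level ChIP-seq binding scores (200-bp read
extension, rpm/bp coverage integrated over the gene ±500 kb, per-sample
Z-transform), clonal DNA-barcode survival and cross-replicate sharing (the
predetermined-tolerance analysis), and Bliss-independence synergy scoring of
dose matrices. Every stage is exercisable offline through synthetic-data
generators with planted ground truth.

## The dependency mixture model

For each cell line, the distribution of gene dependency scores `s` (more
negative = more depleted) is modeled as a mixture of two empirically anchored
components: `f_dep`, a kernel density fit to the scores of *pan-essential*
genes (genes in the bottom 26% of scores in ≥ 90% of a reference panel of
lines), and `f_non`, fit to the scores of genes *not expressed* in that line.
With mixing weight π estimated by EM over all gene scores,

```
P(dependent | s) = π f_dep(s) / (π f_dep(s) + (1 − π) f_non(s))
```

Tail clamps then force probability 1 below score −1.5 and 0 above 0.25, the
probability-versus-score curve is smoothed with a Gaussian kernel of SD 0.15
(score units), re-clipped, and projected to be non-increasing in score.
Genes are ranked by probability and the q-value at rank i is the running mean
of (1 − probability) over ranks 1..i.

## Worked example

`run_pipeline()` simulates a full coherent study (CRISPR screen + reference
panel, expression profiles, two-drug ORF rescue screen, barcode experiment,
dose matrix) and runs every stage:

```r
library(betscreen)
res <- run_pipeline(default_config(seed = 1))

res$mediators
#> [1] "gene0129" "gene0509" "gene0679" "gene0836" "gene0930"
identical(sort(res$mediators), res$truth$mediators)
#> [1] TRUE
```

The nominated mediator set is exactly the planted triple intersection. The
stage outputs carry the usual summaries:

```r
res$dependency_model
#> Two-component empirical dependency mixture model
#>   mixing weight pi: 0.102 (EM)
#>   anchors: 101 pan-essential, 100 unexpressed
#>   clamps: prob = 1 below -1.50, 0 above 0.25; smoothing sd 0.15

res$concordance          # cross-drug rescue concordance
#>   r_squared   p_value     n
#>       0.562 2.61e-181  1000

res$bliss
#> Bliss-independence synergy analysis
#>   combination wells: 16
#>   mean excess inhibition: 0.1333 (tolerance 0.05)
#>   synergy: YES
```

π ≈ 0.10 recovers the planted 10% essential-gene fraction; the Bliss mean
excess ≈ 0.13 reflects the planted per-well excess of 0.15 attenuated by
clipping at fully inhibitory doses. Each fitted object has `tidy()`,
`glance()` and `autoplot()` methods; `write_pipeline_outputs()` (via the
`out_dir` argument) writes per-stage TSV/JSON files plus a provenance record
echoing every threshold and the seed, so identical config + seed gives
byte-identical outputs.

Individual stages are plain functions over tibbles, e.g.

```r
s   <- simulate_crispr_screen(seed = 1)
lfc <- compute_guide_lfc(s$counts, paste0("final_", 1:6), paste0("etp_", 1:6))
gs  <- aggregate_gene_scores(lfc, s$guide_map)
overlap_fisher(n_a = 18, n_b = 18, k = 5, n_universe = 12579)$p_value
#> [1] 2.768135e-11
```

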