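---
title: "Methods: integrative nomination of BETi mediator genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative nomination of BETi mediator genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betscreen)
```

# The problem and the model

BET-bromodomain inhibition suppresses transcription broadly, so differential
expression alone cannot identify which suppressed genes drive the loss of
viability in MYC-driven medulloblastoma cells. `betscreen` integrates three
orthogonal genome-scale assays and nominates as *mediators* the genes that
pass all three:

* **Suppressed by drug.** Two-condition expression profiles are scored per
  gene with the signal-to-noise ratio
  `SNR = (mu_drug − mu_vehicle) / (sd_drug' + sd_vehicle')`, where each
  group's standard deviation is floored at `0.2 × |group mean|` (and 1e-8).
  Significance comes from a two-sided label-permutation test; genes with
  p < 0.05, BH q < 0.1 and negative SNR form the suppressed set. A
  Bonferroni mode (adjusted value < 0.1) is provided for low-dimensional
  chromatin-mark panels, and a rank-based top-N mode for fixed-size sets.

* **Essential.** Guide-level log2 fold changes (mean over final samples of
  log2(RPM + 1) minus the same over early-time-point samples) are collapsed
  to gene scores by the median over a gene's guides, non-targeting guides
  excluded. A two-component empirical mixture converts scores into
  dependency probabilities (next section); genes with probability > 0.35 and
  FDR < 0.2 are called essential.

* **Rescuing.** ORF abundances after ~3 weeks under drug are scored as log2
  RPM fold change versus the initial time point, per replicate, averaged per
  arm. Each arm's screen-wide LFC distribution is its own null: robust z =
  (LFC − median) / (1.4826 · MAD), one-sided upper normal p, BH q. Rescue
  ORFs have mean LFC > 1.5 and q < 0.25; ORFs passing only the q bar are
  tracked separately (`q_only`), since reproducible sub-threshold enrichment
  is biologically informative. Genes with several ORFs collapse to their
  best (max-LFC) ORF.

Overlap significance between gene sets uses the upper-tail hypergeometric
(Fisher) test for small sets and the Pearson chi-square (1 df, no continuity
correction) for large ones; the chi-square refuses tables with any expected
cell below 1 and points the user to Fisher.

# The dependency mixture model in detail

Let `s_g` be gene g's score in one line. Two kernel densities are fit with
`stats::density` (Gaussian kernel, Silverman's rule-of-thumb bandwidth) on a
shared 512-point grid spanning the observed score range extended by 1 unit on
each side: `f_dep` from the scores of pan-essential genes in that line and
`f_non` from the scores of genes not expressed in that line (default: mean
log2 expression below 0.2). Pan-essentials are derived from a multi-line
panel as genes in the bottom 26% of each line's scores in at least 90% of
lines; with fewer than two panel lines an explicit list must be supplied.
Both anchor sets must contribute at least 20 scored genes.

The mixing weight π is estimated by EM over all gene scores with the two
densities held fixed (responsibilities averaged; fixed π = 0.5 available via
`fit_pi = FALSE`). The raw posterior
`π f_dep / (π f_dep + (1 − π) f_non)` is then post-processed in a fixed
order:

1. **Clamp**: probability 1 below score −1.5, 0 above 0.25 — the tails of
   empirical densities are noise-dominated, and scores that extreme are
   unambiguous;
2. **Smooth**: discrete Gaussian convolution of the probability-versus-score
   curve, kernel SD 0.15 in score units, kernel truncated at 4 SD and
   renormalized (edge padding with boundary values);
3. **Re-clip** to [0, 1] and re-impose the clamps exactly;
4. **Isotonic projection**: the curve is made non-increasing in score by a
   running maximum from the right.

Step 4 is a deliberate strengthening: with arbitrary (e.g. overlapping or
multimodal) anchor sets a raw KDE posterior can wiggle, and a more negative
score should never yield a lower dependency probability. For well-separated
anchors the projection is a no-op. The smoothing width is interpreted in
score units (not rank space); sensitivity to this choice is low because the
curve is near-linear over the transition region at the default bandwidths.

Per-gene q-values aggregate the local false discovery rate: with genes ranked
by descending probability, `q_i = mean(1 − p)` over ranks 1..i, which is
nondecreasing by construction. The FDR is computed per line across all scored
genes.

# Synthetic data: what it emulates and what it does not

Every generator is deterministic given its seed, returns planted truth
tables, and writes/reads the same TSV formats as real inputs.

* `simulate_crispr_screen()` — two-time-point dropout screen: log-normal
  clone abundances (log-SD 0.5), negative-binomial counts (dispersion 0.2,
  the screen-literature default; the library geometry scales the 73,687-guide
  / 18,454-gene + 1,000 non-targeting design down to 1,000 genes × 4 guides
  + 100 controls), mean library size 2e6 reads. Essential genes deplete by a
  mean guide LFC of −1.0, attenuated per guide by a multiplicative efficacy
  drawn from N(1, 0.2) truncated at 0 — this is why multiple guides per gene
  are aggregated. Six samples per time point by default: dropout screens are
  sequenced with deep replication, and at the fixed dispersion of 0.2 this
  depth is what makes a −1.0 effect resolvable at the stated calling
  operating point (recall ≥ 0.9 at FPR ≤ 0.05).
* `simulate_orf_screen()` — ETP, vehicle arm and two drug arms sharing the
  planted rescue effect (+2 log2 by default) with independent per-arm noise,
  plus drug-independent drift; cross-arm concordance therefore rises with
  the effect/noise ratio.
* `simulate_expression()` — Gaussian log2 expression, planted suppressed
  genes shifted down under drug.
* `simulate_barcode_experiment()` — one ETP pool; a planted
  predetermined-tolerant fraction survives drug in every replicate, all
  other clones survive each replicate independently with probability
  1 − kill_prob; vehicle replicates impose no selection. The scaled default
  (10,000 barcodes, 8 replicates) mirrors the 600,000-barcode design.
* `simulate_dose_response()` — Hill single-agent survival, Bliss
  independent-action product minus a planted excess, Gaussian well noise,
  clipping to [0, 1].
* `simulate_study()` — a coherent study for the end-to-end pipeline: gene
  roles (mediator, suppressed-and-essential, single-evidence, rescue-only,
  unexpressed) are planted disjointly by seeded sampling; the CRISPR line
  comes with a 4-line reference panel sharing its essential genes so
  pan-essentials are derived, not assumed; unexpressed genes sit at the
  expression detection floor and anchor the non-dependent component.
  Mediator-class effects are planted clearly above the calling thresholds
  (depletion −1.5, rescue +5, expression shift 2.0 = 4 noise SD): this
  generator's purpose is a recoverable end-to-end truth, while threshold-
  marginal behavior is the job of the stage-level generators.

None of the generators emulate copy-number artifacts in guide counts
(CERES-style correction is out of scope), guide off-target activity,
batch/plate effects, microarray preprocessing, or clone-size drift in the
barcode pools. Passing tests therefore demonstrate correctness of the
scoring and integration machinery under the stated stochastic model, not
robustness to those real-data pathologies.

# Pipeline, thresholds and provenance

`run_pipeline(default_config(seed), out_dir)` runs all stages and writes
per-stage TSVs plus `provenance.json` echoing the seed and every threshold;
outputs are a pure function of (config, seed). Key defaults, all
configurable: dependency clamps −1.5 / 0.25, smoothing SD 0.15, probability
> 0.35, FDR < 0.2, pan-essential quantile 0.26 at 90% of lines, unexpressed
cutoff 0.2 (log2 units); rescue LFC > 1.5 (log2), q < 0.25; marker p < 0.05,
q < 0.1, 1,000 permutations (exact enumeration whenever the number of
distinct labelings is at most 10,000); barcode ETP filter 3 reads, detection
threshold 1 read; Bliss synergy tolerance 0.05 mean excess; ChIP read
extension 200 bp and gene flank 500 kb; pseudocount 1 on RPM.

Two integration choices are deliberately the package's own. First, the gene
universes for overlap tests default to the corresponding library gene spaces
(CRISPR: 18,454; ORF: 12,579 at full scale) and are always echoed in the
output, since overlap p-values are meaningless without their universe.
Second, mediator nomination requires the rescue call to reproduce in **both**
drug arms: a single-arm call at q < 0.25 among ~1,000 ORFs carries a
material false-positive rate under heavy-tailed count noise, and consistency
across two structurally distinct inhibitors is the natural reproducibility
filter; the per-arm union is still reported for set-level summaries.

# Numerical choices and degenerate inputs

* Permutation p-values: exact mode enumerates all `choose(n, nA)` labelings,
  excludes the observed one and uses `p = (1 + #{|SNR*| ≥ |SNR|}) / M`;
  sampled mode uses `(1 + k) / (1 + B)`. Both keep p ≥ 1/M. For equal group
  sizes the complement labeling always ties the observed statistic, so the
  smallest attainable two-sided p is 2/M — worth remembering when choosing
  replicate numbers.
* Robust-z q-values error on MAD = 0 (a degenerate screen) rather than
  dividing by a floor; the marker SNR instead floors per-group SDs, the
  comparative-marker-selection convention for near-constant features.
* Coverage: reads are extended 200 bp from their 5′ end in strand direction
  ("." treated as "+"), per-bp value `1e6 / total mapped reads`; extensions
  running off the chromosome start are clipped with a counted warning.
  Genome-wide coverage mass is exactly 200 × 1e6 rpm·bp up to clipping.
* Z-transform uses the sample SD (n − 1); constant columns map to all zeros
  by policy rather than NaN.
* Bliss analysis caps normalized viability at 1 before computing inhibition
  so expected inhibition stays within [0, 1]; the synergy flag uses the mean
  excess over combination wells, with the full per-well excess matrix always
  reported.
* Ties in gene-level ORF collapse break deterministically (first by LFC,
  then input order); all ranking-based outputs are stable under input
  permutation.

# Problem sizes

The test suite and the end-to-end pipeline run at the scaled geometry
(1,000 genes × 4 guides, 1,000 ORFs, 10,000 barcodes, 5–6 replicates per
condition), chosen so a full run completes in seconds while keeping every
statistical regime (anchored KDEs, BH across ~1,000 features, 8-replicate
sharing profiles) representative. Full-scale shapes are available through
the generator arguments.

# Known limitations

* The dependency layer scores genes by median-of-guides; it does not model
  guide efficacy or copy-number effects, so scores are comparable within a
  screen but not calibrated across screens the way a full guide-activity
  model would be.
* The rescue q-value treats the cross-ORF LFC distribution as the null;
  replicate-level variance is used only through the arm mean. With few
  replicates and strong selection this is conservative for weak hits.
* The marker permutation test is bounded by design resolution (min p = 2/M
  for balanced groups); with 3-replicate designs only Bonferroni-free,
  direction-informed interpretation is meaningful.
* Barcode analysis treats presence as count ≥ 1 after the ETP filter;
  sequencing-depth differences between replicates are not renormalized, so
  grossly unbalanced libraries should be depth-filtered upstream.
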