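#' Simulate a pooled CRISPR knockout depletion screen
#'
#' Generates guide-level sequencing counts for a two-time-point dropout
#' screen: early-time-point (ETP) samples taken just after library infection
#' and final samples taken after ~21 days of passaging. Clone abundances are
#' log-normal across guides; counts are negative-binomial around expected
#' abundance. Guides against planted essential genes are depleted at the
#' final time point by `depletion_effect` log2 units, attenuated per guide by
#' a multiplicative efficacy drawn around 1; non-targeting control guides
#' carry no effect.
#'
#' @param n_genes Number of targeted genes (scaled default 1000; the
#'   full-scale library targets 18,454 genes).
#' @param guides_per_gene Guides per gene (4).
#' @param n_control_guides Non-targeting guides (scaled default 100;
#'   full-scale 1000).
#' @param n_samples Samples per time point (ETP and final; default 4
#'   6: deep replication at both time points, sized so the mixture
#'   model's calling operating point is met at the default effect size).
#' @param library_size Mean total reads per sample.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param fraction_essential Fraction of genes planted as essential.
#' @param depletion_effect Mean guide log2 fold change for essential genes
#'   (negative; default -1).
#' @param efficacy_sd SD of per-guide multiplicative efficacy around 1.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `counts` (count tibble, ETP columns `etp_*` and final
#'   columns `final_*`), `guide_map` (guide_id, gene, is_control) and
#'   `truth` (gene, essential flag).
#' @export
simulate_crispr_screen <- function(n_genes = 1000,
                                   guides_per_gene = 4,
                                   n_control_guides = 100,
                                   n_samples = 6,
                                   library_size = 2e6,
                                   dispersion = 0.2,
                                   fraction_essential = 0.1,
                                   depletion_effect = -1.0,
                                   efficacy_sd = 0.2,
                                   seed = 1) {
  stopifnot(fraction_essential >= 0, fraction_essential <= 1,
            dispersion > 0, is.finite(depletion_effect))
  n_guides <- n_genes * guides_per_gene + n_control_guides
  if (n_guides > 5e6) abort("library too large to represent")
  set.seed(seed)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  n_ess <- round(fraction_essential * n_genes)
  essential <- genes[seq_len(n_ess)]

  sim <- sim_crispr_counts(genes, essential, guides_per_gene,
                           n_control_guides, n_samples, library_size,
                           dispersion, depletion_effect, efficacy_sd)
  list(counts = sim$counts,
       guide_map = sim$guide_map,
       truth = tibble::tibble(gene = genes, essential = genes %in% essential))
}

# engine shared by simulate_crispr_screen and simulate_study; caller seeds RNG
sim_crispr_counts <- function(genes, essential, guides_per_gene,
                              n_control_guides, n_samples, library_size,
                              dispersion, depletion_effect, efficacy_sd) {
  n_genes <- length(genes)
  n_guides <- n_genes * guides_per_gene + n_control_guides
  guide_map <- tibble::tibble(
    feature_id = c(sprintf("%s_sg%d", rep(genes, each = guides_per_gene),
                           rep(seq_len(guides_per_gene), n_genes)),
                   sprintf("NTC_%04d", seq_len(n_control_guides))),
    gene = c(rep(genes, each = guides_per_gene),
             rep("NONTARGETING", n_control_guides)),
    is_control = c(rep(FALSE, n_genes * guides_per_gene),
                   rep(TRUE, n_control_guides))
  )

  base_abund <- exp(rnorm(n_guides, 0, 0.5))
  base_abund <- base_abund / sum(base_abund)

  effect <- rep(0, n_guides)
  ess_guides <- guide_map$gene %in% essential
  efficacy <- pmax(0, rnorm(sum(ess_guides), 1, efficacy_sd))
  effect[ess_guides] <- depletion_effect * efficacy

  final_abund <- base_abund * 2^effect
  final_abund <- final_abund / sum(final_abund)

  draw <- function(abund) {
    as.integer(rnbinom(n_guides, mu = abund * library_size, size = 1 / dispersion))
  }
  counts <- tibble::tibble(feature_id = guide_map$feature_id)
  for (s in seq_len(n_samples)) counts[[paste0("etp_", s)]] <- draw(base_abund)
  for (s in seq_len(n_samples)) counts[[paste0("final_", s)]] <- draw(final_abund)
  list(counts = counts, guide_map = guide_map)
}

#' Simulate an ORF overexpression rescue screen
#'
#' Emulates the rescue-screen design: an ORF library infected into cells that
#' are then split into a vehicle (DMSO) arm and two drug arms (two
#' structurally distinct BET inhibitors), with abundance read out at the
#' initial time point and assay end. Planted rescue ORFs are enriched only
#' under drug; the two drug arms share the planted effect and differ by
#' independent per-arm noise, so cross-drug concordance rises with the
#' effect-to-noise ratio.
#'
#' @param n_orfs Number of ORFs (scaled default 1000; full-scale ~17,255).
#' @param n_reps Replicates per arm.
#' @param library_size Mean total reads per sample.
#' @param dispersion Negative-binomial dispersion.
#' @param fraction_rescue Fraction of ORFs planted as rescue ORFs.
#' @param rescue_effect Mean log2 enrichment of rescue ORFs under drug.
#' @param drift_sd SD of drug-independent per-ORF drift (log2 units).
#' @param arm_noise_sd SD of per-arm, per-ORF noise around the shared drug
#'   effect (log2 units).
#' @param seed Integer seed.
#' @return List with `counts` (columns `etp_*`, `dmso_*`, `drugA_*`,
#'   `drugB_*`), `orf_map` (feature_id, gene, is_control) and `truth`
#'   (gene, rescue flag).
#' @export
simulate_orf_screen <- function(n_orfs = 1000,
                                n_reps = 2,
                                library_size = 2e6,
                                dispersion = 0.2,
                                fraction_rescue = 0.02,
                                rescue_effect = 2.0,
                                drift_sd = 0.3,
                                arm_noise_sd = 0.3,
                                seed = 1) {
  stopifnot(fraction_rescue >= 0, fraction_rescue <= 1, dispersion > 0)
  set.seed(seed)
  orfs <- sprintf("ORF%04d", seq_len(n_orfs))
  n_res <- round(fraction_rescue * n_orfs)
  rescue <- orfs[seq_len(n_res)]

  base_abund <- exp(rnorm(n_orfs, 0, 0.5))
  base_abund <- base_abund / sum(base_abund)

  drift <- rnorm(n_orfs, 0, drift_sd)
  shared <- ifelse(orfs %in% rescue, rescue_effect, 0)
  eff_a <- drift + shared + rnorm(n_orfs, 0, arm_noise_sd)
  eff_b <- drift + shared + rnorm(n_orfs, 0, arm_noise_sd)

  draw <- function(effect) {
    abund <- base_abund * 2^effect
    abund <- abund / sum(abund)
    as.integer(rnbinom(n_orfs, mu = abund * library_size, size = 1 / dispersion))
  }
  counts <- tibble::tibble(feature_id = orfs)
  counts[["etp_1"]] <- draw(rep(0, n_orfs))
  for (r in seq_len(n_reps)) counts[[paste0("dmso_", r)]] <- draw(drift)
  for (r in seq_len(n_reps)) counts[[paste0("drugA_", r)]] <- draw(eff_a)
  for (r in seq_len(n_reps)) counts[[paste0("drugB_", r)]] <- draw(eff_b)

  list(counts = counts,
       orf_map = tibble::tibble(feature_id = orfs, gene = orfs,
                                is_control = FALSE),
       truth = tibble::tibble(gene = orfs, rescue = orfs %in% rescue))
}

#' Simulate two-condition expression profiles with planted suppressed genes
#'
#' Gaussian log2 expression for a vehicle and a drug condition; planted
#' suppressed genes are shifted down by `effect` under drug, mimicking the
#' broad transcriptional suppression seen after BET-bromodomain inhibition.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition.
#' @param fraction_suppressed Fraction of genes planted as drug-suppressed.
#' @param effect Mean log2 down-shift of suppressed genes under drug.
#' @param noise_sd Residual SD (log2 units).
#' @param seed Integer seed.
#' @return List with `expr` (tibble: gene column then sample columns
#'   `vehicle_*`, `drug_*`), `labels` (sample, condition) and `truth`
#'   (gene, suppressed flag).
#' @export
simulate_expression <- function(n_genes = 1000,
                                n_reps = 5,
                                fraction_suppressed = 0.1,
                                effect = 1.5,
                                noise_sd = 0.5,
                                seed = 1) {
  stopifnot(fraction_suppressed >= 0, fraction_suppressed <= 1, noise_sd > 0)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  n_sup <- round(fraction_suppressed * n_genes)
  suppressed <- genes[seq_len(n_sup)]
  baseline <- rnorm(n_genes, 7, 2)
  shift <- ifelse(genes %in% suppressed, -effect, 0)

  expr <- tibble::tibble(gene = genes)
  for (r in seq_len(n_reps)) {
    expr[[paste0("vehicle_", r)]] <- baseline + rnorm(n_genes, 0, noise_sd)
  }
  for (r in seq_len(n_reps)) {
    expr[[paste0("drug_", r)]] <- baseline + shift + rnorm(n_genes, 0, noise_sd)
  }
  labels <- tibble::tibble(
    sample = setdiff(names(expr), "gene"),
    condition = rep(c("vehicle", "drug"), each = n_reps))
  list(expr = expr, labels = labels,
       truth = tibble::tibble(gene = genes,
                              suppressed = genes %in% suppressed))
}

#' Simulate a clonal DNA-barcode drug-treatment experiment
#'
#' Emulates lineage tracing of drug tolerance: a barcoded founder pool is
#' expanded, sampled at the early time point (ETP), then split into replicate
#' drug and vehicle treatments derived from the same pre-treatment clone
#' pool. A planted fraction of clones is predetermined-tolerant and survives
#' drug in every replicate; every other clone survives each drug replicate
#' independently with probability `1 - kill_prob`. Vehicle replicates impose
#' no selection.
#'
#' @param n_barcodes Number of distinct clonal barcodes (scaled default
#'   10,000; full-scale library 600,000).
#' @param n_reps Replicates per treatment arm (8).
#' @param fraction_tolerant Fraction of clones planted as drug-tolerant.
#' @param kill_prob Per-replicate probability that a non-tolerant clone is
#'   eliminated by drug.
#' @param depth Mean sequencing reads per sample.
#' @param dispersion Negative-binomial dispersion.
#' @param seed Integer seed.
#' @return List with `counts` (columns `etp`, `drug_*`, `vehicle_*`) and
#'   `truth` (barcode, tolerant flag).
#' @export
simulate_barcode_experiment <- function(n_barcodes = 10000,
                                        n_reps = 8,
                                        fraction_tolerant = 0.25,
                                        kill_prob = 0.9,
                                        depth = 2e6,
                                        dispersion = 0.2,
                                        seed = 1) {
  stopifnot(fraction_tolerant >= 0, fraction_tolerant <= 1,
            kill_prob >= 0, kill_prob <= 1)
  set.seed(seed)
  bcs <- sprintf("bc%06d", seq_len(n_barcodes))
  n_tol <- round(fraction_tolerant * n_barcodes)
  tolerant <- seq_len(n_barcodes) <= n_tol

  base_abund <- exp(rnorm(n_barcodes, 0, 0.5))
  base_abund <- base_abund / sum(base_abund)
  draw <- function(alive) {
    abund <- base_abund * alive
    tot <- sum(abund)
    if (tot == 0) return(rep(0L, n_barcodes))
    as.integer(rnbinom(n_barcodes, mu = abund / tot * depth,
                       size = 1 / dispersion))
  }
  counts <- tibble::tibble(feature_id = bcs,
                           etp = draw(rep(1, n_barcodes)))
  for (r in seq_len(n_reps)) {
    alive <- tolerant | (runif(n_barcodes) > kill_prob)
    counts[[paste0("drug_", r)]] <- draw(as.numeric(alive))
  }
  for (r in seq_len(n_reps)) {
    counts[[paste0("vehicle_", r)]] <- draw(rep(1, n_barcodes))
  }
  list(counts = counts,
       truth = tibble::tibble(barcode = bcs, tolerant = tolerant))
}

#' Simulate a combination dose-response viability surface
#'
#' Single-agent survival follows a Hill curve per drug,
#' `S(d) = 1 / (1 + (d / ic50)^h)`; combination viability is the Bliss
#' independent-action product `S_a * S_b` minus a planted synergy excess on
#' nonzero-dose wells, plus Gaussian noise, clipped to `[0, 1]`.
#'
#' @param doses_a,doses_b Dose vectors (must start at 0, strictly increasing).
#' @param ic50_a,ic50_b,hill_a,hill_b Hill parameters per drug.
#' @param synergy_excess Planted excess inhibition: a scalar applied to every
#'   double-nonzero-dose well, or a matrix of the full grid shape.
#' @param noise_sd SD of well-level Gaussian noise.
#' @param seed Integer seed.
#' @return List with `viability` (matrix, doses A in rows) and
#'   `truth_excess` (matrix of planted excess per well).
#' @export
simulate_dose_response <- function(doses_a = c(0, 0.1, 0.3, 1, 3),
                                   doses_b = c(0, 0.1, 0.3, 1, 3),
                                   ic50_a = 1, hill_a = 1.5,
                                   ic50_b = 1, hill_b = 1.5,
                                   synergy_excess = 0,
                                   noise_sd = 0,
                                   seed = 1) {
  stopifnot(doses_a[1] == 0, doses_b[1] == 0,
            all(diff(doses_a) > 0), all(diff(doses_b) > 0))
  set.seed(seed)
  hill <- function(d, ic50, h) ifelse(d == 0, 1, 1 / (1 + (d / ic50)^h))
  sa <- hill(doses_a, ic50_a, hill_a)
  sb <- hill(doses_b, ic50_b, hill_b)
  surf <- outer(sa, sb)
  if (length(synergy_excess) == 1) {
    exc <- matrix(0, length(doses_a), length(doses_b))
    exc[doses_a != 0, doses_b != 0] <- synergy_excess
  } else {
    exc <- synergy_excess
    stopifnot(all(dim(exc) == dim(surf)))
  }
  v <- surf - exc
  if (noise_sd > 0) {
    v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v))
  }
  v <- pmin(pmax(v, 0), 1)
  v[1, 1] <- 1
  dimnames(v) <- list(as.character(doses_a), as.character(doses_b))
  dimnames(exc) <- dimnames(v)
  list(viability = v, truth_excess = exc)
}
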