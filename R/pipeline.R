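#' Simulate a coherent integrative BETi study with planted mediators
#'
#' Generates every input the integrative pipeline consumes — a CRISPR
#' dropout screen for the analyzed line plus a small reference panel of
#' lines sharing its essential genes, two-condition expression profiles, an
#' ORF rescue screen under two drug arms, a clonal-barcode experiment and a
#' combination dose matrix — with gene roles planted coherently: mediator
#' genes are simultaneously drug-suppressed, essential and rescuing, and the
#' surrounding single- and double-evidence genes exercise every branch of
#' the integration. Mediator-class effects are planted well above the
#' calling thresholds (strong dependencies near the pan-essential score
#' range, several-fold rescue enrichment under drug) so the planted truth is
#' recoverable by design; marginal behavior is exercised by the stage-level
#' generators instead.
#'
#' @param n_genes Gene universe size (scaled default 1000).
#' @param n_mediators Planted triple-evidence genes (5).
#' @param n_supp_ess Additional suppressed-and-essential (not rescue) genes
#'   (15).
#' @param n_ess_only,n_supp_only Single-evidence genes (80 each).
#' @param n_rescue_only Rescue-only genes (5).
#' @param n_unexpressed Unexpressed genes anchoring the non-dependent
#'   mixture component (100).
#' @param n_ref_lines Reference cell lines for pan-essential derivation (4).
#' @param crispr_samples,orf_reps,expr_reps Replication per assay.
#' @param depletion_effect Guide-level depletion of essential genes (-1.5).
#' @param rescue_effect Drug-arm log2 enrichment of rescue ORFs (+5).
#' @param expr_effect Log2 down-shift of suppressed genes (2).
#' @param seed Integer seed.
#' @return List of stage inputs (`crispr`, `panel_scores`, `expression`,
#'   `orf`, `barcodes`, `dose`) and a `truth` list of planted gene sets.
#' @export
simulate_study <- function(n_genes = 1000,
                           n_mediators = 5,
                           n_supp_ess = 15,
                           n_ess_only = 80,
                           n_supp_only = 80,
                           n_rescue_only = 5,
                           n_unexpressed = 100,
                           n_ref_lines = 4,
                           crispr_samples = 4,
                           orf_reps = 3,
                           expr_reps = 5,
                           depletion_effect = -1.5,
                           rescue_effect = 5,
                           expr_effect = 2,
                           seed = 1) {
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  roles <- sample(genes)  # seeded role assignment
  take <- function(n) {
    out <- roles[seq_len(n)]
    roles <<- roles[-seq_len(n)]
    out
  }
  mediators <- take(n_mediators)
  supp_ess <- take(n_supp_ess)
  ess_only <- take(n_ess_only)
  supp_only <- take(n_supp_only)
  rescue_only <- take(n_rescue_only)
  unexpressed <- take(n_unexpressed)

  essential <- c(mediators, supp_ess, ess_only)
  suppressed <- c(mediators, supp_ess, supp_only)
  rescue <- c(mediators, rescue_only)

  crispr <- sim_crispr_counts(genes, essential, guides_per_gene = 4,
                              n_control_guides = 100,
                              n_samples = crispr_samples,
                              library_size = 2e6, dispersion = 0.2,
                              depletion_effect = depletion_effect,
                              efficacy_sd = 0.2)

  # reference panel sharing the essential set, for pan-essential derivation
  panel_scores <- tibble::tibble(gene = genes)
  for (l in seq_len(n_ref_lines)) {
    ln <- sim_crispr_counts(genes, essential, 4, 100, crispr_samples,
                            2e6, 0.2, depletion_effect, 0.2)
    lfc <- compute_guide_lfc(ln$counts,
                             paste0("final_", seq_len(crispr_samples)),
                             paste0("etp_", seq_len(crispr_samples)))
    gs <- aggregate_gene_scores(lfc, ln$guide_map)
    panel_scores[[paste0("line_", l)]] <- gs$score[match(genes, gs$gene)]
  }

  # expression: unexpressed genes sit below the detection cutoff
  baseline <- rnorm(n_genes, 7, 2)
  baseline[baseline < 0.5] <- 0.5
  baseline[genes %in% unexpressed] <- runif(n_unexpressed, 0, 0.1)
  shift <- ifelse(genes %in% suppressed, -expr_effect, 0)
  expr <- tibble::tibble(gene = genes)
  # undetected genes sit at the detection floor with floor-level noise
  noise_sd <- ifelse(genes %in% unexpressed, 0.03, 0.5)
  for (r in seq_len(expr_reps)) {
    expr[[paste0("vehicle_", r)]] <-
      pmax(baseline + rnorm(n_genes, 0, noise_sd), 0)
  }
  for (r in seq_len(expr_reps)) {
    expr[[paste0("drug_", r)]] <-
      pmax(baseline + shift + rnorm(n_genes, 0, noise_sd), 0)
  }
  expr_labels <- tibble::tibble(
    sample = setdiff(names(expr), "gene"),
    condition = rep(c("vehicle", "drug"), each = expr_reps))

  # ORF rescue screen: rescue genes enriched in both drug arms
  orf_abund <- exp(rnorm(n_genes, 0, 0.5))
  orf_abund <- orf_abund / sum(orf_abund)
  drift <- rnorm(n_genes, 0, 0.3)
  shared <- ifelse(genes %in% rescue, rescue_effect, 0)
  eff_a <- drift + shared + rnorm(n_genes, 0, 0.3)
  eff_b <- drift + shared + rnorm(n_genes, 0, 0.3)
  draw_orf <- function(effect) {
    ab <- orf_abund * 2^effect
    ab <- ab / sum(ab)
    as.integer(rnbinom(n_genes, mu = ab * 2e6, size = 1 / 0.2))
  }
  orf_counts <- tibble::tibble(feature_id = paste0(genes, "_orf"),
                               etp_1 = draw_orf(rep(0, n_genes)))
  for (r in seq_len(orf_reps)) {
    orf_counts[[paste0("dmso_", r)]] <- draw_orf(drift)
  }
  for (r in seq_len(orf_reps)) {
    orf_counts[[paste0("drugA_", r)]] <- draw_orf(eff_a)
  }
  for (r in seq_len(orf_reps)) {
    orf_counts[[paste0("drugB_", r)]] <- draw_orf(eff_b)
  }
  orf_map <- tibble::tibble(feature_id = paste0(genes, "_orf"),
                            gene = genes, is_control = FALSE)

  barcodes <- simulate_barcode_experiment(n_barcodes = 10000, n_reps = 8,
                                          fraction_tolerant = 0.25,
                                          kill_prob = 0.9,
                                          seed = (seed * 7 + 1) %% .Machine$integer.max)
  dose <- simulate_dose_response(synergy_excess = 0.15, noise_sd = 0.02,
                                 seed = (seed * 7 + 2) %% .Machine$integer.max)

  list(
    crispr = crispr,
    panel_scores = panel_scores,
    expression = list(expr = expr, labels = expr_labels),
    orf = list(counts = orf_counts, orf_map = orf_map),
    barcodes = barcodes,
    dose = dose,
    truth = list(universe = genes,
                 mediators = sort(mediators),
                 essential = sort(essential),
                 suppressed = sort(suppressed),
                 rescue = sort(rescue),
                 unexpressed = sort(unexpressed)))
}

#' Default pipeline configuration
#'
#' Stage parameters for [run_pipeline()], echoing every threshold so the
#' provenance record is complete. Values mirror the analysis defaults:
#' dependency clamps -1.5/0.25, smoothing SD 0.15, probability > 0.35 with
#' FDR < 0.2; rescue LFC > 1.5 with q < 0.25; marker p < 0.05 with q < 0.1;
#' ETP barcode filter 3 reads; Bliss synergy tolerance 0.05.
#'
#' @param seed Integer seed.
#' @return Named list of stage parameters.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_genes = 1000),
    crispr = list(pseudocount = 1, clamp_low = -1.5, clamp_high = 0.25,
                  smooth_sigma = 0.15, prob_threshold = 0.35,
                  fdr_threshold = 0.2, pan_quantile = 0.26,
                  pan_fraction = 0.90, unexpressed_cutoff = 0.2),
    orf = list(pseudocount = 1, lfc_threshold = 1.5, q_threshold = 0.25),
    markers = list(p_threshold = 0.05, q_threshold = 0.1, n_perm = 1000,
                   correction = "BH"),
    barcodes = list(min_etp_count = 3, detection_threshold = 1),
    synergy = list(synergy_tolerance = 0.05))
}

#' Run the full integrative pipeline on a synthetic study
#'
#' Orchestrates every stage on data from [simulate_study()]: CRISPR
#' dependency calling, marker selection, ORF rescue scoring with cross-drug
#' concordance, three-way integration with overlap tests, barcode survival
#' and sharing, and Bliss synergy. Writes per-stage TSV/JSON outputs plus a
#' JSON provenance record; identical config and seed give identical outputs.
#'
#' @param config List from [default_config()].
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @return List of stage results, invisibly including `truth`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.null(config$seed)) abort("config must carry a seed")
  study <- simulate_study(n_genes = config$simulate$n_genes,
                          seed = config$seed)

  ## CRISPR dependency stage
  cc <- config$crispr
  n_s <- sum(grepl("^etp_", names(study$crispr$counts)))
  glfc <- compute_guide_lfc(study$crispr$counts,
                            paste0("final_", seq_len(n_s)),
                            paste0("etp_", seq_len(n_s)),
                            pseudocount = cc$pseudocount)
  gene_scores <- aggregate_gene_scores(glfc, study$crispr$guide_map)
  pan <- derive_pan_essential(study$panel_scores,
                              pan_quantile = cc$pan_quantile,
                              pan_fraction = cc$pan_fraction)
  expr_m <- as.matrix(study$expression$expr[-1])
  veh <- study$expression$labels$sample[
    study$expression$labels$condition == "vehicle"]
  unexpr <- study$expression$expr$gene[
    rowMeans(expr_m[, veh, drop = FALSE]) < cc$unexpressed_cutoff]
  model <- fit_dependency_model(gene_scores, pan, unexpr,
                                clamp_low = cc$clamp_low,
                                clamp_high = cc$clamp_high,
                                smooth_sigma = cc$smooth_sigma)
  dep_calls <- call_essentials(gene_scores, model,
                               prob_threshold = cc$prob_threshold,
                               fdr_threshold = cc$fdr_threshold)

  ## marker-selection stage
  mc <- config$markers
  markers <- call_markers(study$expression$expr, study$expression$labels,
                          p_threshold = mc$p_threshold,
                          q_threshold = mc$q_threshold,
                          correction = mc$correction,
                          n_perm = mc$n_perm, seed = config$seed)

  ## ORF rescue stage
  oc <- config$orf
  n_r <- sum(grepl("^drugA_", names(study$orf$counts)))
  orf_lfc <- compute_orf_lfc(
    study$orf$counts, "etp_1",
    list(dmso = paste0("dmso_", seq_len(n_r)),
         drugA = paste0("drugA_", seq_len(n_r)),
         drugB = paste0("drugB_", seq_len(n_r))),
    orf_map = study$orf$orf_map, pseudocount = oc$pseudocount)
  rescue_a <- call_rescue(orf_lfc, "drugA", oc$lfc_threshold, oc$q_threshold)
  rescue_b <- call_rescue(orf_lfc, "drugB", oc$lfc_threshold, oc$q_threshold)
  conc <- concordance(orf_lfc$mean_lfc_drugA, orf_lfc$mean_lfc_drugB)
  # mediator nomination requires the rescue evidence to reproduce across
  # both structurally distinct drugs; the per-arm union is still reported
  rescue_union <- union(rescue_a$gene[rescue_a$rescue],
                        rescue_b$gene[rescue_b$rescue])
  rescue_genes <- intersect(rescue_a$gene[rescue_a$rescue],
                            rescue_b$gene[rescue_b$rescue])

  ## integration stage
  suppressed_genes <- markers$gene[markers$suppressed]
  essential_genes <- dep_calls$gene[dep_calls$essential]
  evid <- classify_genes(suppressed_genes, essential_genes, rescue_genes,
                         study$truth$universe)
  n_univ <- length(study$truth$universe)
  overlaps <- dplyr::bind_rows(
    overlap_chisq(length(suppressed_genes), length(essential_genes),
                  sum(evid$evidence$suppressed & evid$evidence$essential),
                  n_univ),
    overlap_fisher(length(rescue_genes), length(essential_genes),
                   sum(evid$evidence$rescue & evid$evidence$essential),
                   n_univ))

  ## barcode stage
  bc <- config$barcodes
  eligible <- filter_etp(study$barcodes$counts, "etp", bc$min_etp_count)
  surv <- surviving_fraction(study$barcodes$counts, eligible,
                             paste0("drug_", 1:8), bc$detection_threshold)
  sharing <- sharing_profile(study$barcodes$counts, eligible,
                             paste0("drug_", 1:8), paste0("vehicle_", 1:8),
                             bc$detection_threshold)

  ## synergy stage
  bliss <- bliss_excess(study$dose$viability,
                        config$synergy$synergy_tolerance)

  result <- list(
    gene_scores = gene_scores, dependency_model = model,
    dependency_calls = dep_calls, markers = markers,
    orf_lfc = orf_lfc, rescue_calls_drugA = rescue_a,
    rescue_calls_drugB = rescue_b, rescue_union = rescue_union,
    concordance = conc,
    evidence = evid$evidence, mediators = evid$mediators,
    overlaps = overlaps, surviving_fraction = surv, sharing = sharing,
    bliss = bliss, truth = study$truth, config = config)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(result$gene_scores, p("gene_scores.tsv"), progress = FALSE)
  readr::write_tsv(tidy(result$dependency_model), p("model_curve.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$dependency_calls, p("dependency_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$markers, p("marker_stats.tsv"), progress = FALSE)
  readr::write_lines(result$markers$gene[result$markers$suppressed],
                     p("suppressed_genes.txt"))
  readr::write_tsv(result$orf_lfc, p("orf_lfc.tsv"), progress = FALSE)
  readr::write_tsv(result$rescue_calls_drugA, p("rescue_calls_drugA.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$rescue_calls_drugB, p("rescue_calls_drugB.tsv"),
                   progress = FALSE)
  jsonlite::write_json(result$concordance, p("concordance.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(result$evidence, p("gene_evidence.tsv"), progress = FALSE)
  readr::write_lines(result$mediators, p("mediators.txt"))
  jsonlite::write_json(result$overlaps, p("overlap_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(surviving_fraction = result$surviving_fraction,
         shared_across_all = result$sharing$shared_across_all,
         drug_specific_fraction = result$sharing$drug_specific_fraction),
    p("sharing_summary.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(tidy(result$bliss), p("bliss.tsv"), progress = FALSE)
  jsonlite::write_json(glance(result$bliss), p("bliss_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$config, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
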