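# shared fixture builders; everything is generated in code at test time

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# count tibble with explicit totals so RPM values are easy to reason about
toy_counts <- function(feature_counts, sample_ids) {
  tib <- tibble::tibble(feature_id = names(feature_counts))
  m <- do.call(rbind, feature_counts)
  for (j in seq_along(sample_ids)) tib[[sample_ids[j]]] <- as.integer(m[, j])
  tib
}

# dependency model fitted on well-separated synthetic anchors
fitted_toy_model <- function(seed = 11, n = 400, ...) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n))
  dep <- genes[1:60]
  non <- genes[301:400]
  score <- c(rnorm(60, -1, 0.2), rnorm(240, 0, 0.25), rnorm(100, 0, 0.2))
  line <- tibble::tibble(gene = genes, score = score)
  list(model = fit_dependency_model(line, dep, non, ...), scores = line,
       dep = dep, non = non)
}

# anchored dependency-calling recovery on a default-condition screen
dependency_recovery <- function(seed, n_samples = 6) {
  s <- simulate_crispr_screen(n_genes = 1000, n_samples = n_samples,
                              seed = seed)
  fin <- paste0("final_", seq_len(n_samples))
  etp <- paste0("etp_", seq_len(n_samples))
  lfc <- compute_guide_lfc(s$counts, fin, etp)
  gs <- aggregate_gene_scores(lfc, s$guide_map)
  ess <- s$truth$gene[s$truth$essential]
  set.seed(seed + 1000)
  panel <- tibble::tibble(gene = s$truth$gene)
  for (l in 1:3) {
    ln <- betscreen:::sim_crispr_counts(s$truth$gene, ess, 4, 100,
                                        n_samples, 2e6, 0.2, -1.0, 0.2)
    lf <- compute_guide_lfc(ln$counts, fin, etp)
    g2 <- aggregate_gene_scores(lf, ln$guide_map)
    panel[[paste0("line_", l)]] <- g2$score[match(panel$gene, g2$gene)]
  }
  pan <- derive_pan_essential(panel)
  unexpr <- sample(s$truth$gene[!s$truth$essential], 100)
  model <- fit_dependency_model(gs, pan, unexpr)
  calls <- call_essentials(gs, model)
  called <- calls$gene[calls$essential]
  list(recall = mean(ess %in% called),
       fpr = mean(setdiff(s$truth$gene, ess) %in% called),
       calls = calls, model = model)
}
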