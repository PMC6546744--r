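test_that("all generators are deterministic given a seed", {
  a <- simulate_crispr_screen(n_genes = 50, n_control_guides = 20, seed = 5)
  b <- simulate_crispr_screen(n_genes = 50, n_control_guides = 20, seed = 5)
  expect_identical(a, b)
  expect_identical(simulate_orf_screen(n_orfs = 50, seed = 5),
                   simulate_orf_screen(n_orfs = 50, seed = 5))
  expect_identical(simulate_expression(n_genes = 50, seed = 5),
                   simulate_expression(n_genes = 50, seed = 5))
  expect_identical(simulate_barcode_experiment(n_barcodes = 200, seed = 5),
                   simulate_barcode_experiment(n_barcodes = 200, seed = 5))
  expect_identical(simulate_dose_response(noise_sd = 0.05, seed = 5),
                   simulate_dose_response(noise_sd = 0.05, seed = 5))
})

test_that("planted truth ids exist in the generated tables", {
  s <- simulate_crispr_screen(n_genes = 100, seed = 2)
  expect_true(all(s$truth$gene %in% s$guide_map$gene))
  o <- simulate_orf_screen(n_orfs = 100, seed = 2)
  expect_true(all(o$truth$gene %in% o$orf_map$gene))
  b <- simulate_barcode_experiment(n_barcodes = 500, seed = 2)
  expect_true(all(b$truth$barcode %in% b$counts$feature_id))
})

test_that("non-targeting guides carry no effect and essentials the planted one", {
  s <- simulate_crispr_screen(n_genes = 500, n_control_guides = 1000,
                              depletion_effect = -1.0, seed = 3)
  lfc <- compute_guide_lfc(s$counts, paste0("final_", 1:4), paste0("etp_", 1:4))
  gm <- s$guide_map
  ntc <- lfc$lfc[gm$is_control]
  # renormalization shifts all guides up slightly when essentials deplete;
  # compare controls against non-essential targeting guides instead
  noness_genes <- s$truth$gene[!s$truth$essential]
  null_guides <- lfc$lfc[gm$gene %in% noness_genes]
  mc_se <- sqrt(sd(ntc)^2 / length(ntc) + sd(null_guides)^2 / length(null_guides))
  expect_lt(abs(mean(ntc) - mean(null_guides)), 3 * mc_se)

  # with no planted essentials there is no renormalization shift at all
  s0 <- simulate_crispr_screen(n_genes = 200, n_control_guides = 1000,
                               fraction_essential = 0, seed = 3)
  lfc0 <- compute_guide_lfc(s0$counts, paste0("final_", 1:4),
                            paste0("etp_", 1:4))
  ntc0 <- lfc0$lfc[s0$guide_map$is_control]
  expect_lt(abs(mean(ntc0)), 3 * sd(ntc0) / sqrt(length(ntc0)))

  gs <- aggregate_gene_scores(lfc, gm)
  ess <- s$truth$gene[s$truth$essential]
  d <- mean(gs$score[gs$gene %in% ess]) - mean(gs$score[!gs$gene %in% ess])
  se <- sqrt(var(gs$score[gs$gene %in% ess]) / sum(gs$gene %in% ess) +
               var(gs$score[!gs$gene %in% ess]) / sum(!gs$gene %in% ess))
  expect_lt(abs(d - (-1.0)), 3 * se)
})

test_that("ORF cross-drug concordance follows the effect-to-noise ratio", {
  lfc_for <- function(o) {
    compute_orf_lfc(o$counts, "etp_1",
                    list(drugA = paste0("drugA_", 1:2),
                         drugB = paste0("drugB_", 1:2)),
                    orf_map = o$orf_map)
  }
  # near-deterministic limit: tiny dispersion, no drift -> R^2 -> 1
  o0 <- simulate_orf_screen(n_orfs = 300, dispersion = 1e-6, drift_sd = 0,
                            arm_noise_sd = 1e-4, fraction_rescue = 0.1,
                            rescue_effect = 2, library_size = 1e7, seed = 4)
  l0 <- lfc_for(o0)
  r0 <- concordance(l0$mean_lfc_drugA, l0$mean_lfc_drugB)$r_squared
  expect_gt(r0, 0.99)
  # higher arm noise at the same seed lowers R^2
  o1 <- simulate_orf_screen(n_orfs = 300, arm_noise_sd = 0.2, seed = 4)
  o2 <- simulate_orf_screen(n_orfs = 300, arm_noise_sd = 2.0, seed = 4)
  l1 <- lfc_for(o1); l2 <- lfc_for(o2)
  expect_gt(concordance(l1$mean_lfc_drugA, l1$mean_lfc_drugB)$r_squared,
            concordance(l2$mean_lfc_drugA, l2$mean_lfc_drugB)$r_squared)
})

test_that("planted rescue ORFs rank top by mean drug-arm LFC", {
  o <- simulate_orf_screen(n_orfs = 500, fraction_rescue = 0.04, seed = 6)
  l <- compute_orf_lfc(o$counts, "etp_1",
                       list(drugA = paste0("drugA_", 1:2)),
                       orf_map = o$orf_map)
  rk <- rank(-l$mean_lfc_drugA)
  planted <- o$truth$gene[o$truth$rescue]
  expect_lt(median(rk[l$gene %in% planted]),
            median(rk[!l$gene %in% planted]))
})

test_that("barcode survival matches its closed-form expectation", {
  # all clones tolerant -> everything survives everywhere
  b1 <- simulate_barcode_experiment(n_barcodes = 300, n_reps = 4,
                                    fraction_tolerant = 1, kill_prob = 1,
                                    seed = 8)
  el1 <- filter_etp(b1$counts, "etp")
  expect_equal(surviving_fraction(b1$counts, el1, paste0("drug_", 1:4)), 100)
  # no tolerant clones, certain kill -> nothing survives
  b0 <- simulate_barcode_experiment(n_barcodes = 300, n_reps = 4,
                                    fraction_tolerant = 0, kill_prob = 1,
                                    seed = 8)
  el0 <- filter_etp(b0$counts, "etp")
  expect_equal(surviving_fraction(b0$counts, el0, paste0("drug_", 1:4)), 0)
  # shared-across-all among survivors ~ t / (t + (1-t)(1-k^R)) for s = 1-k
  t0 <- 0.25; k <- 0.8; R <- 6
  b <- simulate_barcode_experiment(n_barcodes = 20000, n_reps = R,
                                   fraction_tolerant = t0, kill_prob = k,
                                   depth = 5e6, seed = 9)
  el <- filter_etp(b$counts, "etp")
  prof <- sharing_profile(b$counts, el, paste0("drug_", 1:R))
  s <- 1 - k
  expect_surv <- t0 + (1 - t0) * (1 - k^R)
  expect_shared <- 100 * (t0 + (1 - t0) * s^R) / expect_surv
  expect_lt(abs(prof$shared_across_all - expect_shared), 2.5)
  expect_lt(abs(prof$surviving_fraction - 100 * expect_surv), 2.5)
})

test_that("dose-response generator plants recoverable Bliss structure", {
  # zero synergy, zero noise -> excess identically 0
  d0 <- simulate_dose_response(synergy_excess = 0, noise_sd = 0, seed = 1)
  b0 <- bliss_excess(d0$viability)
  expect_true(all(abs(b0$excess) < 1e-12))
  # planted excess at moderate doses recovered within 2 * noise sd
  d <- simulate_dose_response(doses_a = c(0, 1), doses_b = c(0, 1),
                              synergy_excess = 0.15, noise_sd = 0.01,
                              seed = 2)
  b <- bliss_excess(d$viability)
  expect_lt(abs(b$excess["1", "1"] - 0.15), 2 * 0.01 * sqrt(3))
})
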