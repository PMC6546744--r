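test_that("guide LFCs follow the RPM + pseudocount definition", {
  # reference: 5 reads of 1e6 total; final: 40 of 2e6 -> RPM 5 vs 20
  ct <- toy_counts(list(g1 = c(5, 40), filler = c(999995, 1999960)),
                   c("etp", "final"))
  lfc <- compute_guide_lfc(ct, "final", "etp", pseudocount = 1)
  expect_equal(lfc$lfc[lfc$feature_id == "g1"], log2(21 / 6), tolerance = 1e-12)

  # equal RPM at equal depth -> 0
  ct0 <- toy_counts(list(g1 = c(100, 100), g2 = c(900, 900)), c("a", "b"))
  expect_equal(compute_guide_lfc(ct0, "b", "a")$lfc, c(0, 0))

  # doubling all counts and totals leaves every LFC unchanged
  ct2 <- ct
  ct2[-1] <- lapply(ct[-1], function(x) 2L * x)
  expect_equal(compute_guide_lfc(ct2, "final", "etp")$lfc,
               compute_guide_lfc(ct, "final", "etp")$lfc)

  # all-zero sample column is an error
  ctz <- toy_counts(list(g1 = c(0, 5), g2 = c(0, 5)), c("a", "b"))
  expect_error(compute_guide_lfc(ctz, "b", "a"), "zero total")
})

test_that("gene scores are guide medians, controls excluded", {
  map <- tibble::tibble(
    feature_id = c(paste0("gA_sg", 1:4), "gB_sg1", "ntc1"),
    gene = c(rep("gA", 4), "gB", "NONTARGETING"),
    is_control = c(rep(FALSE, 5), TRUE))
  lfc <- tibble::tibble(feature_id = map$feature_id,
                        lfc = c(-1, -1, -1, 3, 0.7, 9))
  gs <- aggregate_gene_scores(lfc, map)
  expect_equal(gs$score[gs$gene == "gA"], -1)          # median robust to +3
  expect_equal(gs$score[gs$gene == "gB"], 0.7)         # single guide
  expect_false("NONTARGETING" %in% gs$gene)
  expect_error(aggregate_gene_scores(
    tibble::tibble(feature_id = "zz", lfc = 1), map), "unmapped")
})

test_that("gene aggregation equals a brute-force per-gene median", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:50)
  map <- tibble::tibble(feature_id = sprintf("%s_sg%d",
                                             rep(genes, each = 4), 1:4),
                        gene = rep(genes, each = 4), is_control = FALSE)
  lfc <- tibble::tibble(feature_id = map$feature_id,
                        lfc = rnorm(nrow(map)))
  gs <- aggregate_gene_scores(lfc, map)
  brute <- vapply(genes, function(g) {
    median(lfc$lfc[map$gene == g])
  }, numeric(1))
  expect_equal(gs$score[match(genes, gs$gene)], unname(brute))
})

test_that("pan-essential derivation applies the quantile-and-fraction rule", {
  sc <- tibble::tibble(
    gene = c("always", "twice", "never", paste0("f", 1:7)),
    l1 = c(-3, -3, 0, seq(-1, 1, length.out = 7)),
    l2 = c(-3, -3, 0, seq(-1, 1, length.out = 7)),
    l3 = c(-3, 0.5, 0, seq(-1, 1, length.out = 7)))
  pan <- derive_pan_essential(sc, pan_quantile = 0.26, pan_fraction = 0.90)
  expect_true("always" %in% pan)   # bottom 26% in 3/3 lines
  expect_false("twice" %in% pan)   # 2/3 = 66.7% < 90%
  expect_error(derive_pan_essential(sc[, 1:2]), ">= 2 cell lines")

  # planted always-depleted genes recovered from a 20-line synthetic panel
  set.seed(22)
  genes <- sprintf("g%03d", 1:300)
  planted <- genes[1:30]
  panel <- tibble::tibble(gene = genes)
  for (l in 1:20) {
    panel[[paste0("line_", l)]] <-
      ifelse(genes %in% planted, rnorm(300, -2, 0.2), rnorm(300, 0, 0.3))
  }
  expect_setequal(derive_pan_essential(panel), planted)
})

test_that("identical anchors with fixed pi give raw posterior 0.5", {
  set.seed(23)
  anchors <- sprintf("a%02d", 1:40)
  others <- sprintf("o%02d", 1:60)
  line <- tibble::tibble(gene = c(anchors, others),
                         score = c(rnorm(40, -0.5, 0.3), rnorm(60, -0.5, 0.3)))
  m <- fit_dependency_model(line, anchors, anchors, pi_init = 0.5,
                            fit_pi = FALSE)
  expect_true(all(abs(m$raw_prob - 0.5) < 1e-9))
})

test_that("probability curve honors clamps exactly and stays in [0,1]", {
  ft <- fitted_toy_model()
  m <- ft$model
  expect_true(all(m$prob >= 0 & m$prob <= 1))
  expect_true(all(m$prob[m$grid < -1.5] == 1))
  expect_true(all(m$prob[m$grid > 0.25] == 0))
  # smoothing leaves intermediate values only within ~3 sigma of the clamp
  inner <- m$grid > -1.5 + 3 * 0.15 & m$grid < 0.25 - 3 * 0.15
  expect_true(any(m$prob[inner] > 0 & m$prob[inner] < 1))
  # lookup helper: clamps and interior interpolation
  expect_equal(dependency_probability(m, -2), 1)
  expect_equal(dependency_probability(m, 0.5), 0)
  expect_equal(dependency_probability(m, -1.9), 1)  # outside grid -> clamp
})

test_that("probability is monotone non-increasing in score", {
  ft <- fitted_toy_model()
  sc <- seq(-2.5, 1, length.out = 400)
  p <- dependency_probability(ft$model, sc)
  expect_true(all(diff(p) <= 1e-12))
  # also without the isotonic projection for well-separated components
  ft2 <- fitted_toy_model(monotone = FALSE)
  sc2 <- seq(-1.5, 0.25, length.out = 200)
  p2 <- dependency_probability(ft2$model, sc2)
  expect_true(all(diff(p2) <= 1e-6))
})

test_that("gaussian smoothing matches a direct convolution oracle", {
  grid <- seq(-2, 1, length.out = 301)
  y <- as.numeric(grid < -0.5)  # step function
  sm <- betscreen:::gaussian_smooth(grid, y, 0.15)
  oracle <- vapply(seq_along(grid), function(i) {
    w <- dnorm(grid - grid[i], sd = 0.15)
    # same boundary handling: pad with edge values
    sum(w * y) / sum(w)
  }, numeric(1))
  interior <- grid > -1.3 & grid < 0.4
  # truncated (4 sigma) kernel vs full-grid oracle
  expect_equal(sm[interior], oracle[interior], tolerance = 1e-3)
  # intermediate only within ~3 sigma of the step, exact 1/0 beyond
  expect_true(all(sm[grid < -0.5 - 3 * 0.15] > 0.995))
  expect_true(all(sm[grid > -0.5 + 3 * 0.15] < 0.005))
})

test_that("small anchor sets are rejected with advice", {
  line <- tibble::tibble(gene = sprintf("g%02d", 1:50),
                         score = rnorm(50))
  expect_error(fit_dependency_model(line, line$gene[1:5], line$gene[40:50]),
               "anchor sets too small")
})

test_that("essential calls combine the probability and q thresholds", {
  gs <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       score = c(-2, -1.8, -1, 0))
  calls <- call_essentials(gs, probability = c(1, 1, 0.8, 0.1))
  expect_equal(calls$q, c(0, 0, 0.2 / 3, (0.2 + 0.9) / 4), tolerance = 1e-12)
  expect_equal(calls$essential, c(TRUE, TRUE, TRUE, FALSE))
  # below the probability threshold never essential, whatever q
  calls2 <- call_essentials(gs, probability = c(1, 1, 1, 0.34))
  expect_false(calls2$essential[4])
  # q nondecreasing down the ranking
  set.seed(24)
  p <- runif(200)
  c3 <- call_essentials(tibble::tibble(gene = sprintf("g%03d", 1:200),
                                       score = rnorm(200)),
                        probability = p)
  expect_true(all(diff(c3$q) >= -1e-12))
})

test_that("lowering a gene's score never decreases its probability", {
  ft <- fitted_toy_model(seed = 25)
  sc <- sort(runif(100, -2, 0.5), decreasing = TRUE)
  p <- dependency_probability(ft$model, sc)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("model tidiers expose the fitted curve and mixing weight", {
  ft <- fitted_toy_model()
  td <- tidy(ft$model)
  expect_named(td, c("score", "f_dep", "f_non", "raw_prob", "probability"))
  gl <- glance(ft$model)
  expect_true(gl$pi > 0 && gl$pi < 1)
  expect_equal(gl$clamp_low, -1.5)
  expect_s3_class(autoplot(ft$model), "ggplot")
})
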