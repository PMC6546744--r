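iv <- function(chrom, start, end, strand = "+", name = ".") {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 strand = strand)
}

cov_integral <- function(cov) sum(cov$value * (cov$end - cov$start))

test_that("read extension anchors at the 5' end in strand direction", {
  # plus-strand read: extend forward from start
  cv <- reads_to_coverage(iv("chr1", 1000, 1036), total_reads = 1)
  expect_equal(cv$start, 1000)
  expect_equal(cv$end, 1200)
  expect_equal(cv$value, 1e6)
  # minus-strand read at (1000, 1050) extends back to (850, 1050)
  cvm <- reads_to_coverage(iv("chr1", 1000, 1050, strand = "-"),
                           total_reads = 1)
  expect_equal(cvm$start, 850)
  expect_equal(cvm$end, 1050)
  # unstranded handled as plus strand
  cvd <- reads_to_coverage(iv("chr1", 1000, 1036, strand = "."),
                           total_reads = 1)
  expect_equal(cvd$end, 1200)
})

test_that("coverage is additive and conserves 200e6 rpm-bp of mass", {
  one <- iv("chr1", 500, 536)
  two <- dplyr::bind_rows(one, one)
  c1 <- reads_to_coverage(one, total_reads = 1)
  c2 <- reads_to_coverage(two, total_reads = 2)
  # two identical reads at double library size: same rpm/bp profile
  expect_equal(c2$value, c1$value)
  # doubled coverage at fixed library size
  c2b <- reads_to_coverage(two, total_reads = 1)
  expect_equal(c2b$value, 2 * c1$value)
  # genome-wide integral is 200 * 1e6 regardless of read count
  set.seed(61)
  reads <- iv(sample(c("chr1", "chr2"), 500, replace = TRUE),
              start <- sample(10000L, 500, replace = TRUE) + 500L,
              start + 36L,
              strand = sample(c("+", "-"), 500, replace = TRUE))
  cv <- reads_to_coverage(reads)
  expect_equal(cov_integral(cv), 200 * 1e6, tolerance = 1e-9)
  # extensions running off the chromosome start are clipped with a warning
  expect_warning(cl <- reads_to_coverage(iv("chr1", 40, 76, strand = "-"),
                                         total_reads = 1), "clipped")
  expect_equal(cov_integral(cl), 76 * 1e6)
})

test_that("gene scores integrate coverage over the flanked window", {
  # uniform 0.01 rpm/bp over 2000 bp inside the flanked region -> 20 rpm
  cov <- tibble::tibble(chrom = "chr1", start = 10000, end = 12000,
                        value = 0.01)
  genes <- iv("chr1", c(9000, 9000), c(13000, 13000),
              name = c("gA", "gB"))
  sc <- gene_binding_score(cov, genes, gene_flank = 5000)
  expect_equal(sc$score, c(20, 20))  # identical windows, identical scores
  # zero coverage -> 0, absent chromosome warns
  genes2 <- iv(c("chr1", "chrX"), c(0, 0), c(100, 100), name = c("a", "b"))
  expect_warning(s2 <- gene_binding_score(cov, genes2, gene_flank = 10),
                 "chrX")
  expect_equal(s2$score, c(0, 0))
  # partial overlap counts only the overlapping width
  g3 <- iv("chr1", 11000, 11500, name = "g3")
  s3 <- gene_binding_score(cov, g3, gene_flank = 0)
  expect_equal(s3$score, 0.01 * 500)
})

test_that("adding reads never decreases any gene score", {
  set.seed(62)
  base <- iv("chr1", start <- sample(50000L, 200) + 1000L, start + 36L,
             strand = sample(c("+", "-"), 200, replace = TRUE))
  extra <- iv("chr1", start2 <- sample(50000L, 50) + 1000L, start2 + 36L)
  genes <- iv("chr1", gs <- seq(2000L, 42000L, by = 4000L), gs + 1000L,
              name = sprintf("g%02d", seq_along(gs)))
  n <- 250  # fixed library size so rpm scale is shared
  s_base <- gene_binding_score(reads_to_coverage(base, n), genes,
                               gene_flank = 500)
  s_more <- gene_binding_score(
    reads_to_coverage(dplyr::bind_rows(base, extra), n), genes,
    gene_flank = 500)
  expect_true(all(s_more$score >= s_base$score - 1e-9))
})

test_that("Z-transform standardizes each sample column", {
  sc <- tibble::tibble(gene = c("a", "b", "c"),
                       s1 = c(1, 2, 3), s2 = c(5, 5, 5))
  z <- z_transform(sc)
  expect_equal(z$s1, c(-1, 0, 1))
  expect_equal(z$s2, c(0, 0, 0))  # constant-column policy
  # affine invariance of Z
  sc2 <- sc; sc2$s1 <- 10 * sc$s1 + 3
  expect_equal(z_transform(sc2)$s1, z$s1)
  expect_error(z_transform(sc[1, ]), ">= 2 genes")
  # per-sample mean 0 / sd 1 on random data
  set.seed(63)
  big <- tibble::tibble(gene = sprintf("g%03d", 1:100), s1 = rexp(100))
  zb <- z_transform(big)
  expect_equal(mean(zb$s1), 0, tolerance = 1e-6)
  expect_equal(sd(zb$s1), 1, tolerance = 1e-6)
})

test_that("gene-set comparison detects planted shifts and is calibrated", {
  set.seed(64)
  genes <- sprintf("g%04d", 1:1030)
  target <- genes[1:30]
  raw <- tibble::tibble(gene = genes,
                        s1 = rnorm(1030) + ifelse(genes %in% target, 1, 0))
  z <- z_transform(raw)
  res <- compare_gene_sets(z, target, setdiff(genes, target))
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_target, res$mean_background)
  expect_error(compare_gene_sets(z, target, target), "disjoint")
  expect_error(compare_gene_sets(z, genes[1], genes[2:20]), ">= 2 genes")
  # null calibration: mean p over 200 null draws near 0.5
  ps <- vapply(1:200, function(i) {
    x <- tibble::tibble(gene = sprintf("n%03d", 1:120), s1 = rnorm(120))
    compare_gene_sets(z_transform(x), x$gene[1:30], x$gene[31:120])$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})
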