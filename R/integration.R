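#' Classify genes by their three evidence layers and nominate mediators
#'
#' A mediator gene is (i) transcriptionally suppressed by drug, (ii)
#' essential in the knockout screen, and (iii) sufficient to rescue the drug
#' effect when overexpressed. Genes passing only the rescue q-value (not the
#' fold-change bar) are tracked separately.
#'
#' @param suppressed,essential Character vectors of gene symbols.
#' @param rescue_calls Tibble from [call_rescue()] (or a character vector of
#'   rescue genes, in which case `q_only` is empty).
#' @param universe Character vector of all assayed genes.
#' @return List with `evidence` (tibble: gene, suppressed, essential,
#'   rescue, q_only_rescue, mediator), `mediators` (character vector) and
#'   `pairwise` (tibble of pairwise intersection sizes).
#' @export
classify_genes <- function(suppressed, essential, rescue_calls, universe) {
  if (is.character(rescue_calls)) {
    rescue_genes <- rescue_calls
    q_only_genes <- character()
  } else {
    rescue_genes <- rescue_calls$gene[rescue_calls$rescue]
    q_only_genes <- rescue_calls$gene[rescue_calls$q_only]
  }
  outside <- setdiff(c(suppressed, essential, rescue_genes), universe)
  if (length(outside)) {
    abort(paste0("genes outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  evidence <- tibble::tibble(
    gene = universe,
    suppressed = universe %in% suppressed,
    essential = universe %in% essential,
    rescue = universe %in% rescue_genes,
    q_only_rescue = universe %in% q_only_genes) |>
    dplyr::mutate(mediator = .data$suppressed & .data$essential & .data$rescue)
  pairwise <- tibble::tibble(
    pair = c("suppressed&essential", "suppressed&rescue", "essential&rescue"),
    n = c(sum(evidence$suppressed & evidence$essential),
          sum(evidence$suppressed & evidence$rescue),
          sum(evidence$essential & evidence$rescue)))
  list(evidence = evidence,
       mediators = evidence$gene[evidence$mediator],
       pairwise = pairwise)
}

#' Fisher exact (hypergeometric) gene-set overlap test
#'
#' One-sided enrichment p-value: the upper-tail hypergeometric probability
#' of observing at least `k` genes common to a set of size `n_a` and a set
#' of size `n_b` drawn from a universe of `n_universe` genes.
#'
#' @param n_a,n_b Set sizes.
#' @param k Observed overlap.
#' @param n_universe Universe size.
#' @return Tibble with `n_universe`, `n_a`, `n_b`, `k`, `expected`,
#'   `p_value`, `method`.
#' @export
overlap_fisher <- function(n_a, n_b, k, n_universe) {
  check_overlap_counts(n_a, n_b, k, n_universe)
  p <- phyper(k - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
  tibble::tibble(n_universe = n_universe, n_a = n_a, n_b = n_b, k = k,
                 expected = n_a * n_b / n_universe,
                 p_value = p, method = "fisher")
}

#' Pearson chi-square gene-set overlap test
#'
#' Two-sided chi-square test (1 df, no continuity correction) on the 2x2
#' membership table implied by two gene sets within a universe.
#'
#' @inheritParams overlap_fisher
#' @return Tibble with the counts, `expected` overlap, `statistic`,
#'   `p_value`, `method`.
#' @export
overlap_chisq <- function(n_a, n_b, k, n_universe) {
  check_overlap_counts(n_a, n_b, k, n_universe)
  obs <- matrix(c(k, n_a - k, n_b - k, n_universe - n_a - n_b + k), 2)
  expd <- outer(rowSums(obs), colSums(obs)) / n_universe
  if (any(expd < 1)) abort("expected cell below 1; use overlap_fisher instead")
  stat <- sum((obs - expd)^2 / expd)
  tibble::tibble(n_universe = n_universe, n_a = n_a, n_b = n_b, k = k,
                 expected = expd[1, 1],
                 statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "chisq")
}

check_overlap_counts <- function(n_a, n_b, k, n_universe) {
  if (k > min(n_a, n_b) || n_a > n_universe || n_b > n_universe ||
      k < 0 || n_universe - n_a - n_b + k < 0) {
    abort("inconsistent overlap counts")
  }
  invisible(TRUE)
}
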