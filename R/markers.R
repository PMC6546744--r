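#' Signal-to-noise ratio statistic for a two-group comparison
#'
#' `SNR = (mu_A - mu_B) / (sd_A' + sd_B')` with each group's standard
#' deviation floored at `sigma_floor_fraction * |mean|` (and at 1e-8), the
#' variance-stabilization convention of comparative marker selection.
#' Antisymmetric under group swap.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param sigma_floor_fraction Floor on sd as a fraction of |mean| (0.2).
#' @return The SNR statistic (unitless).
#' @export
snr_statistic <- function(a, b, sigma_floor_fraction = 0.2) {
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 samples per group")
  floor_sd <- function(x) max(sd(x), sigma_floor_fraction * abs(mean(x)), 1e-8)
  (mean(a) - mean(b)) / (floor_sd(a) + floor_sd(b))
}

#' Permutation p-values for per-feature SNR statistics
#'
#' Two-sided label-permutation test of the SNR statistic per feature. When
#' the number of distinct group-A labelings is at most `max_exact`, all
#' labelings other than the observed one are enumerated and
#' `p = (1 + #\{|SNR*| >= |SNR|\}) / M` with `M = choose(n, nA)`; otherwise
#' `n_perm` random labelings are drawn and
#' `p = (1 + #\{|SNR*| >= |SNR|\}) / (1 + n_perm)`.
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param labels Character/factor vector of two group labels per column.
#' @param n_perm Random permutations when enumeration is infeasible (1000).
#' @param max_exact Enumerate exactly when `choose(n, nA) <= max_exact`
#'   (10,000).
#' @param sigma_floor_fraction Passed to [snr_statistic()].
#' @param seed Seed for the sampled mode.
#' @return Tibble with `snr` and `p` per feature.
#' @export
permutation_pvalues <- function(mat, labels, n_perm = 1000, max_exact = 10000,
                                sigma_floor_fraction = 0.2, seed = 1) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) abort("labels must define exactly two groups")
  stopifnot(ncol(mat) == length(labels), n_perm >= 100)
  mat <- as.matrix(mat)
  ia <- which(labels == groups[1])
  n <- length(labels)
  if (length(ia) < 2 || n - length(ia) < 2) {
    abort("need >= 2 samples per group")
  }
  snr_for <- function(idx_a) {
    row_snr(mat, idx_a, sigma_floor_fraction)
  }
  obs <- snr_for(ia)
  m_labelings <- choose(n, length(ia))
  if (m_labelings <= max_exact) {
    combos <- utils::combn(n, length(ia), simplify = FALSE)
    combos <- combos[!vapply(combos, function(cc) identical(sort(cc), sort(ia)),
                             logical(1))]
    perm_abs <- vapply(combos, function(cc) abs(snr_for(cc)),
                       numeric(nrow(mat)))
    perm_abs <- matrix(perm_abs, nrow = nrow(mat))
    ge <- rowSums(perm_abs >= abs(obs) - 1e-12)
    p <- (1 + ge) / m_labelings
  } else {
    set.seed(seed)
    ge <- numeric(nrow(mat))
    for (b in seq_len(n_perm)) {
      idx_a <- sample(n, length(ia))
      ge <- ge + (abs(snr_for(idx_a)) >= abs(obs) - 1e-12)
    }
    p <- (1 + ge) / (1 + n_perm)
  }
  tibble::tibble(snr = obs, p = pmin(p, 1))
}

# vectorized per-row SNR for a column split; matches snr_statistic row-wise
row_snr <- function(mat, idx_a, sigma_floor_fraction) {
  idx_b <- setdiff(seq_len(ncol(mat)), idx_a)
  stat_for <- function(idx) {
    sub <- mat[, idx, drop = FALSE]
    k <- length(idx)
    mu <- rowMeans(sub)
    s <- sqrt(pmax(rowSums((sub - mu)^2) / (k - 1), 0))
    list(mu = mu, s = pmax(s, sigma_floor_fraction * abs(mu), 1e-8))
  }
  a <- stat_for(idx_a)
  b <- stat_for(idx_b)
  (a$mu - b$mu) / (a$s + b$s)
}

#' Call differentially expressed markers
#'
#' Comparative marker selection on a two-condition expression matrix: SNR
#' statistic per gene (group A = drug, group B = vehicle by argument order),
#' permutation p-values, multiple-testing correction (Benjamini-Hochberg for
#' expression, Bonferroni for the chromatin-profiling mode), and
#' significance flags. Genes significant with negative SNR (drug below
#' vehicle) form the drug-suppressed set.
#'
#' @param expr Tibble: `gene` column then sample columns.
#' @param labels Tibble with `sample`, `condition`; `condition` must contain
#'   `drug_label` and `vehicle_label`.
#' @param drug_label,vehicle_label Condition names (defaults "drug",
#'   "vehicle").
#' @param p_threshold,q_threshold Significance cutoffs (0.05, 0.1).
#' @param correction `"BH"` (expression mode) or `"bonferroni"` (chromatin
#'   mode, threshold applied to the adjusted value only).
#' @param n_perm,seed,sigma_floor_fraction Passed to
#'   [permutation_pvalues()].
#' @return Tibble with `gene`, `snr`, `p`, `q`, `direction`, `significant`,
#'   `suppressed`.
#' @export
call_markers <- function(expr, labels, drug_label = "drug",
                         vehicle_label = "vehicle",
                         p_threshold = 0.05, q_threshold = 0.1,
                         correction = c("BH", "bonferroni"),
                         n_perm = 1000, seed = 1,
                         sigma_floor_fraction = 0.2) {
  correction <- match.arg(correction)
  stopifnot(p_threshold > 0, p_threshold < 1, q_threshold > 0, q_threshold < 1)
  samp <- labels$sample[labels$condition %in% c(drug_label, vehicle_label)]
  cond <- labels$condition[match(samp, labels$sample)]
  mat <- as.matrix(expr[, samp])
  lab <- ifelse(cond == drug_label, "A", "B")
  # group A must be the drug group so negative SNR = suppressed under drug
  ord <- order(lab)
  res <- permutation_pvalues(mat[, ord, drop = FALSE], lab[ord],
                             n_perm = n_perm, seed = seed,
                             sigma_floor_fraction = sigma_floor_fraction)
  q <- p.adjust(res$p, method = if (correction == "BH") "BH" else "bonferroni")
  sig <- if (correction == "BH") {
    res$p < p_threshold & q < q_threshold
  } else {
    q < q_threshold
  }
  tibble::tibble(
    gene = expr$gene,
    snr = res$snr,
    p = res$p,
    q = q,
    direction = ifelse(res$snr < 0, "down", "up"),
    significant = sig,
    suppressed = sig & res$snr < 0)
}

#' Top-N most-suppressed genes by SNR rank
#'
#' Alternative selection used when a fixed-size suppressed set is wanted
#' instead of a significance-thresholded one: the `n` genes with the most
#' negative SNR.
#'
#' @param marker_stats Tibble from [call_markers()].
#' @param n Set size.
#' @return Character vector of gene symbols.
#' @export
top_suppressed <- function(marker_stats, n = 5000) {
  marker_stats |>
    dplyr::arrange(.data$snr) |>
    dplyr::slice_head(n = n) |>
    dplyr::pull("gene")
}
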