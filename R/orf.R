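#' Per-ORF log2 fold changes versus the initial time point
#'
#' Read counts are normalized to reads per million and log2-transformed; the
#' LFC of each ORF in each end-of-assay replicate is taken relative to the
#' initial time point (ETP), and the per-arm mean is recorded.
#'
#' @param counts Count tibble.
#' @param etp_samples ETP sample column names (averaged as the reference).
#' @param arm_samples Named list: arm name -> character vector of end-point
#'   replicate columns.
#' @param orf_map Optional tibble `feature_id`, `gene`.
#' @param pseudocount Pseudocount added to RPM (default 1).
#' @return Tibble with `feature_id`, `gene`, one `lfc_<arm>_<rep>` column
#'   per replicate and one `mean_lfc_<arm>` per arm.
#' @export
compute_orf_lfc <- function(counts, etp_samples, arm_samples,
                            orf_map = NULL, pseudocount = 1) {
  validate_count_table(counts, "counts")
  stopifnot(is.list(arm_samples), length(arm_samples) >= 1,
            !is.null(names(arm_samples)))
  m <- count_matrix(counts)
  tot <- colSums(m)
  used <- c(etp_samples, unlist(arm_samples))
  missing <- setdiff(used, colnames(m))
  if (length(missing)) {
    abort(paste0("samples not in count table: ", paste(missing, collapse = ", ")))
  }
  if (any(tot[used] == 0)) abort("sample with zero total reads")
  lg <- log2(sweep(m, 2, tot, "/") * 1e6 + pseudocount)
  ref <- rowMeans(lg[, etp_samples, drop = FALSE])
  out <- tibble::tibble(feature_id = counts$feature_id)
  out$gene <- if (is.null(orf_map)) counts$feature_id else {
    orf_map$gene[match(counts$feature_id, orf_map$feature_id)]
  }
  for (arm in names(arm_samples)) {
    reps <- arm_samples[[arm]]
    for (i in seq_along(reps)) {
      out[[sprintf("lfc_%s_%d", arm, i)]] <- unname(lg[, reps[i]] - ref)
    }
    out[[paste0("mean_lfc_", arm)]] <-
      unname(rowMeans(lg[, reps, drop = FALSE]) - ref)
  }
  out
}

#' q-values for per-ORF enrichment within one treatment arm
#'
#' The screen-wide LFC distribution serves as the empirical null: each ORF
#' gets a robust z-score, `(lfc - median) / (1.4826 * MAD)`, a one-sided
#' upper-tail normal p-value, and a Benjamini-Hochberg q-value.
#'
#' @param mean_lfc Numeric vector of per-ORF mean LFCs for one arm.
#' @return Tibble with `z`, `p`, `q` aligned to the input.
#' @export
orf_q_values <- function(mean_lfc) {
  if (length(mean_lfc) < 20) abort("need >= 20 ORFs for a stable null")
  md <- median(mean_lfc)
  s <- mad(mean_lfc)  # 1.4826 * median absolute deviation
  if (s == 0) abort("MAD of LFCs is zero; need more variable features")
  z <- (mean_lfc - md) / s
  p <- pnorm(z, lower.tail = FALSE)
  tibble::tibble(z = z, p = p, q = p.adjust(p, method = "BH"))
}

#' Call rescue ORFs and collapse to gene-level rescue calls
#'
#' A rescue ORF confers more than `lfc_threshold` log2 enrichment under drug
#' with q below `q_threshold`. ORFs that pass only the q threshold are
#' flagged `q_only` (genes whose enrichment is reproducible but below the
#' fold-change bar). Genes with several ORFs are collapsed by their
#' best (maximum-LFC) ORF.
#'
#' @param orf_lfc Tibble from [compute_orf_lfc()].
#' @param arm Arm name whose `mean_lfc_<arm>` column is scored.
#' @param lfc_threshold Log2 enrichment cutoff (default 1.5).
#' @param q_threshold q-value cutoff (default 0.25).
#' @return Tibble with `gene`, `mean_lfc`, `q`, `rescue`, `q_only`, one row
#'   per gene.
#' @export
call_rescue <- function(orf_lfc, arm, lfc_threshold = 1.5, q_threshold = 0.25) {
  stopifnot(lfc_threshold > 0, q_threshold > 0, q_threshold < 1)
  col <- paste0("mean_lfc_", arm)
  if (!col %in% names(orf_lfc)) abort(paste0("no arm column ", col))
  qv <- orf_q_values(orf_lfc[[col]])
  per_orf <- tibble::tibble(
    gene = orf_lfc$gene,
    mean_lfc = orf_lfc[[col]],
    q = qv$q)
  per_orf |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$mean_lfc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      rescue = .data$mean_lfc > lfc_threshold & .data$q < q_threshold,
      q_only = .data$q < q_threshold & .data$mean_lfc <= lfc_threshold) |>
    dplyr::arrange(dplyr::desc(.data$mean_lfc))
}

#' Cross-treatment concordance of per-ORF log2 fold changes
#'
#' Ordinary least-squares regression of one arm's LFCs on the other's;
#' reports the coefficient of determination and the two-sided p-value for
#' the slope. Used to ask whether two structurally distinct drugs produce
#' the same rescue profile.
#'
#' @param lfc_a,lfc_b Aligned numeric LFC vectors (>= 3 ORFs).
#' @return Tibble with `r_squared`, `p_value`, `n`.
#' @export
concordance <- function(lfc_a, lfc_b) {
  stopifnot(length(lfc_a) == length(lfc_b))
  keep <- is.finite(lfc_a) & is.finite(lfc_b)
  lfc_a <- lfc_a[keep]; lfc_b <- lfc_b[keep]
  if (length(lfc_a) < 3) abort("need >= 3 shared ORFs")
  if (sd(lfc_a) == 0 || sd(lfc_b) == 0) abort("zero variance in an LFC vector")
  fit <- lm(lfc_b ~ lfc_a)
  s <- summary(fit)
  tibble::tibble(r_squared = s$r.squared,
                 p_value = s$coefficients["lfc_a", "Pr(>|t|)"],
                 n = length(lfc_a))
}
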