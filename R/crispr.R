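#' Guide-level log2 fold changes from screen counts
#'
#' Counts are normalized to reads per million (RPM), log2-transformed with a
#' pseudocount, and the per-guide LFC is the mean over final samples minus
#' the mean over reference (early-time-point) samples. LFCs are invariant to
#' uniform rescaling of sequencing depth.
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param final_samples,reference_samples Character vectors of sample column
#'   names.
#' @param pseudocount Pseudocount added to RPM before log2 (default 1).
#' @return Tibble with `feature_id` and `lfc`.
#' @export
compute_guide_lfc <- function(counts, final_samples, reference_samples,
                              pseudocount = 1) {
  validate_count_table(counts, "counts")
  missing <- setdiff(c(final_samples, reference_samples), names(counts))
  if (length(missing)) {
    abort(paste0("samples not in count table: ", paste(missing, collapse = ", ")))
  }
  m <- count_matrix(counts)
  tot <- colSums(m)
  if (any(tot[c(final_samples, reference_samples)] == 0)) {
    abort("sample with zero total reads")
  }
  rpm <- sweep(m, 2, tot, "/") * 1e6
  lg <- log2(rpm + pseudocount)
  tibble::tibble(
    feature_id = counts$feature_id,
    lfc = unname(rowMeans(lg[, final_samples, drop = FALSE]) -
                   rowMeans(lg[, reference_samples, drop = FALSE]))
  )
}

#' Aggregate guide-level LFCs into gene-level dependency scores
#'
#' The gene score is the median (default) of its guides' log2 fold changes;
#' non-targeting control guides are excluded. More negative scores indicate
#' stronger depletion, i.e. stronger dependency.
#'
#' @param guide_lfc Tibble from [compute_guide_lfc()].
#' @param guide_map Tibble with `feature_id`, `gene`, `is_control`.
#' @param method Aggregation: `"median"` (default) or `"mean"`.
#' @return Tibble with `gene` and `score`.
#' @export
aggregate_gene_scores <- function(guide_lfc, guide_map, method = c("median", "mean")) {
  method <- match.arg(method)
  unmapped <- setdiff(guide_lfc$feature_id, guide_map$feature_id)
  if (length(unmapped)) {
    abort(paste0("unmapped guides: ", paste(head(unmapped, 5), collapse = ", ")))
  }
  agg <- if (method == "median") median else mean
  out <- guide_lfc |>
    dplyr::inner_join(guide_map, by = "feature_id") |>
    dplyr::filter(!.data$is_control) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(score = agg(.data$lfc), n_guides = dplyr::n(),
                     .groups = "drop")
  if (any(out$n_guides == 0) || nrow(out) == 0) abort("gene with zero guides")
  dplyr::select(out, "gene", "score")
}

#' Derive pan-essential genes from a multi-line score panel
#'
#' Pan-essential genes are those whose dependency score falls in the bottom
#' `pan_quantile` of gene scores in at least `pan_fraction` of the cell
#' lines; they anchor the "true dependent" component of the mixture model.
#'
#' @param scores Tibble with `gene` column plus one numeric score column per
#'   cell line (>= 2 lines).
#' @param pan_quantile Bottom score quantile defining "depleted" in a line
#'   (default 0.26).
#' @param pan_fraction Minimum fraction of lines in which a gene must be
#'   depleted (default 0.90).
#' @return Character vector of pan-essential gene symbols.
#' @export
derive_pan_essential <- function(scores, pan_quantile = 0.26, pan_fraction = 0.90) {
  stopifnot(pan_quantile > 0, pan_quantile < 1,
            pan_fraction > 0, pan_fraction <= 1)
  m <- as.matrix(scores[-1])
  if (ncol(m) < 2) {
    abort("need >= 2 cell lines to derive pan-essentials; supply an explicit list instead")
  }
  cuts <- apply(m, 2, quantile, probs = pan_quantile, names = FALSE)
  in_bottom <- sweep(m, 2, cuts, "<=")
  frac <- rowMeans(in_bottom)
  scores$gene[frac >= pan_fraction]
}

#' Fit the two-component empirical dependency mixture model
#'
#' In each cell line, the distribution of gene dependency scores is modeled
#' as a mixture of (1) an empirically determined "true dependent" component,
#' estimated by kernel density from the scores of pan-essential genes in
#' that line, and (2) a "true non-dependent" component, estimated from the
#' scores of genes not expressed in that line. The mixing weight `pi` is
#' estimated by EM over all gene scores with the two densities held fixed.
#' The raw posterior probability of dependency at score x is
#' `pi * f_dep(x) / (pi * f_dep(x) + (1 - pi) * f_non(x))`. Tail clamps are
#' then applied (probability 1 below `clamp_low`, 0 above `clamp_high`), the
#' probability-versus-score curve is smoothed with a Gaussian kernel of SD
#' `smooth_sigma` in score units, re-clipped to `[0, 1]` with the clamps
#' re-imposed, and finally projected to be non-increasing in score.
#'
#' @param line_scores Tibble with `gene` and `score` for one cell line.
#' @param pan_essential Character vector anchoring the dependent component.
#' @param unexpressed Character vector anchoring the non-dependent component.
#' @param clamp_low,clamp_high Tail clamps (-1.5, 0.25).
#' @param smooth_sigma Gaussian smoothing SD in score units (0.15).
#' @param pi_init Starting (or, if `fit_pi = FALSE`, fixed) mixing weight.
#' @param fit_pi Estimate `pi` by EM (default TRUE).
#' @param min_anchor Minimum anchor-set size present in the scores (20).
#' @param n_grid Evaluation-grid size (512).
#' @param monotone Apply the non-increasing isotonic projection (default
#'   TRUE).
#' @return Object of class `dependency_model` with elements `grid`,
#'   `f_dep`, `f_non`, `pi`, `raw_prob`, `prob` (final smoothed curve) and
#'   the configuration used.
#' @export
fit_dependency_model <- function(line_scores, pan_essential, unexpressed,
                                 clamp_low = -1.5, clamp_high = 0.25,
                                 smooth_sigma = 0.15,
                                 pi_init = 0.5, fit_pi = TRUE,
                                 min_anchor = 20, n_grid = 512,
                                 monotone = TRUE) {
  stopifnot(clamp_low < clamp_high, smooth_sigma > 0,
            pi_init > 0, pi_init < 1)
  sc <- setNames(line_scores$score, line_scores$gene)
  dep_sc <- sc[names(sc) %in% pan_essential]
  non_sc <- sc[names(sc) %in% unexpressed]
  if (length(dep_sc) < min_anchor || length(non_sc) < min_anchor) {
    abort(sprintf(
      "anchor sets too small (%d dependent, %d non-dependent; need >= %d); supply explicit densities",
      length(dep_sc), length(non_sc), min_anchor))
  }
  lo <- min(sc) - 1
  hi <- max(sc) + 1
  grid <- seq(lo, hi, length.out = n_grid)
  kde <- function(x) {
    d <- density(x, bw = "nrd0", from = lo, to = hi, n = n_grid)
    d$y
  }
  f_dep <- kde(dep_sc)
  f_non <- kde(non_sc)

  pi_hat <- pi_init
  if (fit_pi) {
    fd <- approx(grid, f_dep, xout = sc, rule = 2)$y
    fn <- approx(grid, f_non, xout = sc, rule = 2)$y
    for (it in seq_len(200)) {
      r <- pi_hat * fd / (pi_hat * fd + (1 - pi_hat) * fn)
      r[!is.finite(r)] <- 0.5
      new_pi <- mean(r)
      if (abs(new_pi - pi_hat) < 1e-8) { pi_hat <- new_pi; break }
      pi_hat <- new_pi
    }
  }

  denom <- pi_hat * f_dep + (1 - pi_hat) * f_non
  raw <- ifelse(denom > 0, pi_hat * f_dep / denom, 0.5)

  clamped <- raw
  clamped[grid < clamp_low] <- 1
  clamped[grid > clamp_high] <- 0

  smoothed <- gaussian_smooth(grid, clamped, smooth_sigma)
  smoothed <- pmin(pmax(smoothed, 0), 1)
  smoothed[grid < clamp_low] <- 1
  smoothed[grid > clamp_high] <- 0
  if (monotone) {
    smoothed <- rev(cummax(rev(smoothed)))
    smoothed <- pmin(smoothed, 1)
  }

  structure(
    list(grid = grid, f_dep = f_dep, f_non = f_non, pi = pi_hat,
         raw_prob = raw, prob = smoothed,
         config = list(clamp_low = clamp_low, clamp_high = clamp_high,
                       smooth_sigma = smooth_sigma, fit_pi = fit_pi,
                       monotone = monotone,
                       n_dep_anchor = length(dep_sc),
                       n_non_anchor = length(non_sc))),
    class = "dependency_model")
}

# discrete Gaussian convolution of y(x) with kernel sd sigma, renormalized
# at the boundaries so the smoothed curve stays a weighted average
gaussian_smooth <- function(x, y, sigma) {
  step <- x[2] - x[1]
  half <- ceiling(4 * sigma / step)
  k <- dnorm(seq(-half, half) * step, sd = sigma)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  sm <- stats::filter(ypad, k / sum(k), sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Dependency probability for a score
#'
#' Linear interpolation on a fitted model's smoothed probability curve;
#' scores below the low clamp return 1, above the high clamp 0, and scores
#' outside the grid take the nearest grid value.
#'
#' @param model A `dependency_model`.
#' @param score Numeric vector of gene scores.
#' @return Probabilities in `[0, 1]`.
#' @export
dependency_probability <- function(model, score) {
  stopifnot(inherits(model, "dependency_model"))
  p <- approx(model$grid, model$prob, xout = score, rule = 2)$y
  p[score < model$config$clamp_low] <- 1
  p[score > model$config$clamp_high] <- 0
  pmin(pmax(p, 0), 1)
}

#' Call essential genes from dependency probabilities
#'
#' Genes are ranked by descending probability; the q-value of the gene at
#' rank i is the running mean of `1 - probability` over ranks 1..i (the
#' standard local-FDR to q-value aggregation), so q is nondecreasing down
#' the ranking. A gene is called essential when probability exceeds
#' `prob_threshold` and q is below `fdr_threshold`.
#'
#' @param gene_scores Tibble with `gene` and `score`.
#' @param model A fitted `dependency_model` (or NULL if `probability` given).
#' @param probability Optional pre-computed probabilities aligned to
#'   `gene_scores`.
#' @param prob_threshold Probability cutoff (default 0.35).
#' @param fdr_threshold FDR cutoff (default 0.2).
#' @return Tibble `gene, score, probability, q, essential`, sorted by
#'   descending probability.
#' @export
call_essentials <- function(gene_scores, model = NULL, probability = NULL,
                            prob_threshold = 0.35, fdr_threshold = 0.2) {
  stopifnot(prob_threshold > 0, prob_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  if (is.null(probability)) {
    if (is.null(model)) abort("supply either a fitted model or probabilities")
    probability <- dependency_probability(model, gene_scores$score)
  }
  stopifnot(all(probability >= 0 & probability <= 1))
  out <- gene_scores |>
    dplyr::mutate(probability = probability) |>
    dplyr::arrange(dplyr::desc(.data$probability)) |>
    dplyr::mutate(q = cumsum(1 - .data$probability) / dplyr::row_number(),
                  essential = .data$probability > prob_threshold &
                    .data$q < fdr_threshold)
  out
}

#' @export
print.dependency_model <- function(x, ...) {
  cat("Two-component empirical dependency mixture model\n")
  cat(sprintf("  mixing weight pi: %.3f%s\n", x$pi,
              if (x$config$fit_pi) " (EM)" else " (fixed)"))
  cat(sprintf("  anchors: %d pan-essential, %d unexpressed\n",
              x$config$n_dep_anchor, x$config$n_non_anchor))
  cat(sprintf("  clamps: prob = 1 below %.2f, 0 above %.2f; smoothing sd %.2f\n",
              x$config$clamp_low, x$config$clamp_high, x$config$smooth_sigma))
  invisible(x)
}

#' @rdname fit_dependency_model
#' @param x A `dependency_model`.
#' @param ... Unused.
#' @export
tidy.dependency_model <- function(x, ...) {
  tibble::tibble(score = x$grid, f_dep = x$f_dep, f_non = x$f_non,
                 raw_prob = x$raw_prob, probability = x$prob)
}

#' @rdname fit_dependency_model
#' @export
glance.dependency_model <- function(x, ...) {
  tibble::tibble(pi = x$pi,
                 n_dep_anchor = x$config$n_dep_anchor,
                 n_non_anchor = x$config$n_non_anchor,
                 clamp_low = x$config$clamp_low,
                 clamp_high = x$config$clamp_high,
                 smooth_sigma = x$config$smooth_sigma)
}

#' @rdname fit_dependency_model
#' @param object A `dependency_model`.
#' @export
autoplot.dependency_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$probability), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw_prob), linetype = "dashed",
                       alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(object$config$clamp_low,
                                       object$config$clamp_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "gene dependency score",
                  y = "probability of dependency",
                  title = "Dependency mixture model",
                  subtitle = "solid: smoothed curve; dashed: raw posterior") +
    ggplot2::theme_minimal()
}
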