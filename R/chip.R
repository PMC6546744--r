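#' Build an rpm/bp coverage track from aligned-read intervals
#'
#' Each read is replaced by a `read_extension`-bp interval anchored at its
#' 5' end in strand direction (unstranded reads are treated as plus-strand),
#' and the per-bp coverage is `1e6 / total_reads` summed over overlapping
#' extended reads, i.e. reads per million mapped reads per bp. Extensions
#' running off the chromosome start are clipped and counted as warnings.
#'
#' @param reads Interval tibble (see [read_intervals()]) of aligned reads.
#' @param total_reads Total mapped reads in the library (defaults to
#'   `nrow(reads)`).
#' @param read_extension Extension length in bp (default 200).
#' @return Tibble with `chrom`, `start`, `end`, `value` (rpm/bp): a sorted,
#'   non-overlapping step function per chromosome (zero runs omitted).
#' @export
reads_to_coverage <- function(reads, total_reads = nrow(reads),
                              read_extension = 200) {
  stopifnot(read_extension > 0)
  if (total_reads <= 0) abort("total mapped reads must be > 0")
  if (nrow(reads) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = double()))
  }
  minus <- reads$strand == "-"
  ext_start <- ifelse(minus, reads$end - read_extension, reads$start)
  ext_end <- ext_start + read_extension
  clipped <- sum(ext_start < 0)
  if (clipped > 0) {
    warn(sprintf("%d extended reads clipped at chromosome start", clipped))
    ext_start <- pmax(ext_start, 0)
  }
  scale <- 1e6 / total_reads
  ext <- tibble::tibble(chrom = reads$chrom, start = ext_start, end = ext_end)
  ext |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(start = df$start + 1, end = df$end)
      cov <- IRanges::coverage(ir)
      runs <- S4Vectors::runValue(cov)
      lens <- S4Vectors::runLength(cov)
      ends <- cumsum(lens)
      starts <- ends - lens
      keep <- runs > 0
      tibble::tibble(start = starts[keep], end = ends[keep],
                     value = runs[keep] * scale)
    }) |>
    dplyr::ungroup()
}

#' Aggregate coverage into gene-level binding scores
#'
#' For each gene the rpm/bp coverage is integrated over the gene body
#' extended by `gene_flank` bp in each direction (clipped at position 0),
#' giving a raw binding score in rpm units. Genes on chromosomes absent
#' from the track score 0 with a warning.
#'
#' @param coverage Coverage tibble from [reads_to_coverage()].
#' @param genes Interval tibble of gene spans.
#' @param gene_flank Flank in bp (default 500,000).
#' @return Tibble with `gene` and `score`.
#' @export
gene_binding_score <- function(coverage, genes, gene_flank = 5e5) {
  stopifnot(gene_flank >= 0)
  missing_chr <- setdiff(unique(genes$chrom), unique(coverage$chrom))
  if (length(missing_chr)) {
    warn(paste0("genes on chromosomes without coverage score 0: ",
                paste(missing_chr, collapse = ", ")))
  }
  score_one <- function(chrom, start, end) {
    cv <- coverage[coverage$chrom == chrom, ]
    if (nrow(cv) == 0) return(0)
    lo <- max(0, start - gene_flank)
    hi <- end + gene_flank
    ov <- pmin(cv$end, hi) - pmax(cv$start, lo)
    sum(cv$value[ov > 0] * ov[ov > 0])
  }
  tibble::tibble(
    gene = genes$name,
    score = purrr::pmap_dbl(
      list(genes$chrom, genes$start, genes$end), score_one))
}

#' Z-transform binding scores within each sample
#'
#' Each sample column is centered and scaled by its sample standard
#' deviation (n - 1 denominator) across genes; constant columns map to all
#' zeros.
#'
#' @param scores Tibble with `gene` column then one numeric score column per
#'   sample (>= 2 genes).
#' @return Tibble of the same shape with Z-transformed columns.
#' @export
z_transform <- function(scores) {
  if (nrow(scores) < 2) abort("need >= 2 genes to Z-transform")
  out <- scores
  for (j in seq(2, ncol(out))) {
    x <- out[[j]]
    s <- sd(x)
    out[[j]] <- if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out
}

#' Compare binding of a target gene set versus background
#'
#' Welch two-sample t-test (two-tailed, unpaired) on per-gene Z-scores,
#' averaged over the chosen sample columns, between a target set (e.g.
#' rescue genes) and a disjoint background set.
#'
#' @param z_scores Tibble from [z_transform()].
#' @param target,background Character vectors of gene names (disjoint, each
#'   with >= 2 members present).
#' @param samples Sample columns to average (default: all).
#' @return Tibble with means, `t_statistic`, `p_value` and set sizes.
#' @export
compare_gene_sets <- function(z_scores, target, background, samples = NULL) {
  if (length(intersect(target, background))) {
    abort("target and background sets must be disjoint")
  }
  if (is.null(samples)) samples <- names(z_scores)[-1]
  z <- rowMeans(as.matrix(z_scores[, samples, drop = FALSE]))
  zt <- z[z_scores$gene %in% target]
  zb <- z[z_scores$gene %in% background]
  if (length(zt) < 2 || length(zb) < 2) {
    abort("each set needs >= 2 genes present in the score table")
  }
  tt <- t.test(zt, zb)
  tibble::tibble(mean_target = mean(zt), mean_background = mean(zb),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_target = length(zt), n_background = length(zb))
}
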