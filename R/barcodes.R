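#' Filter barcodes on early-time-point abundance
#'
#' Only clonal barcodes sequenced to at least `min_etp_count` reads at the
#' early time point are considered reliably labeled and eligible for the
#' survival and sharing analyses.
#'
#' @param counts Barcode count tibble.
#' @param etp_sample ETP column name.
#' @param min_etp_count Minimum ETP reads (default 3, boundary inclusive).
#' @return Character vector of eligible barcode ids.
#' @export
filter_etp <- function(counts, etp_sample = "etp", min_etp_count = 3) {
  stopifnot(min_etp_count >= 1)
  if (!etp_sample %in% names(counts)) {
    abort(paste0("ETP sample column missing: ", etp_sample))
  }
  counts$feature_id[counts[[etp_sample]] >= min_etp_count]
}

#' Fraction of eligible barcodes surviving drug treatment
#'
#' Percentage of eligible barcodes detected (count >=
#' `detection_threshold`) in at least one treated replicate.
#'
#' @param counts Barcode count tibble.
#' @param eligible Eligible barcode ids from [filter_etp()].
#' @param treated_samples Treated replicate column names.
#' @param detection_threshold Presence cutoff in a post-treatment sample (1).
#' @return Percentage in `[0, 100]`.
#' @export
surviving_fraction <- function(counts, eligible, treated_samples,
                               detection_threshold = 1) {
  stopifnot(length(treated_samples) >= 1, detection_threshold >= 1)
  if (length(eligible) == 0) abort("empty eligible barcode set")
  sub <- counts[counts$feature_id %in% eligible, ]
  m <- as.matrix(sub[, treated_samples, drop = FALSE])
  100 * sum(rowSums(m >= detection_threshold) >= 1) / length(eligible)
}

#' Cross-replicate barcode sharing profile
#'
#' For every surviving barcode (present in at least one treated replicate),
#' counts in how many treated replicates it appears; summarizes, per
#' replicate, how many of its barcodes are shared with exactly j other
#' treated replicates, the percentage of survivors present in all treated
#' replicates, and the percentage of those fully shared survivors absent
#' from every vehicle replicate (the predetermined-tolerance signature).
#'
#' @param counts Barcode count tibble.
#' @param eligible Eligible barcode ids.
#' @param treated_samples Treated replicate columns (>= 2).
#' @param vehicle_samples Vehicle replicate columns (optional).
#' @param detection_threshold Presence cutoff (1).
#' @return List with `per_replicate` (tibble: replicate, shared_with_j,
#'   n_barcodes), `surviving_fraction`, `shared_across_all` (% of
#'   survivors), `n_surviving`, and `drug_specific_fraction` (% of fully
#'   shared survivors absent from all vehicle replicates; `NA` when no
#'   vehicle samples given).
#' @export
sharing_profile <- function(counts, eligible, treated_samples,
                            vehicle_samples = character(),
                            detection_threshold = 1) {
  stopifnot(length(treated_samples) >= 2)
  if (length(eligible) == 0) abort("empty eligible barcode set")
  sub <- counts[counts$feature_id %in% eligible, ]
  pres <- as.matrix(sub[, treated_samples, drop = FALSE]) >= detection_threshold
  n_reps_with <- rowSums(pres)
  surviving <- n_reps_with >= 1
  r <- length(treated_samples)

  per_replicate <- purrr::map_dfr(seq_len(r), function(i) {
    in_rep <- pres[, i]
    j <- n_reps_with[in_rep] - 1L
    tibble::tibble(replicate = treated_samples[i],
                   shared_with_j = seq(0L, r - 1L),
                   n_barcodes = vapply(seq(0L, r - 1L),
                                       function(k) sum(j == k), integer(1)))
  })

  shared_all <- n_reps_with == r
  n_surv <- sum(surviving)
  drug_specific <- NA_real_
  if (length(vehicle_samples) > 0 && sum(shared_all) > 0) {
    veh <- as.matrix(sub[, vehicle_samples, drop = FALSE]) >= detection_threshold
    drug_specific <- 100 * sum(shared_all & rowSums(veh) == 0) / sum(shared_all)
  }
  list(
    per_replicate = per_replicate,
    surviving_fraction = 100 * n_surv / length(eligible),
    shared_across_all = if (n_surv == 0) 0 else 100 * sum(shared_all) / n_surv,
    n_surviving = n_surv,
    drug_specific_fraction = drug_specific)
}

#' Plot a cross-replicate sharing profile
#'
#' Stacked bars per treated replicate showing how many of its barcodes are
#' shared with j other replicates.
#'
#' @param profile List from [sharing_profile()].
#' @return A ggplot object.
#' @export
plot_sharing_profile <- function(profile) {
  df <- profile$per_replicate
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate, y = .data$n_barcodes,
                                   fill = factor(.data$shared_with_j))) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = NULL, y = "% of barcodes in replicate",
                  fill = "shared with\nj other reps",
                  title = "Clonal barcode sharing across treated replicates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
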