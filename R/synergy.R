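#' Normalize raw luminescence to a viability dose matrix
#'
#' Viability is raw signal over the mean of vehicle wells, clipped to
#' `[0, 1.05]` to tolerate assay noise, then capped at 1 for inhibition
#' math.
#'
#' @param raw Numeric matrix of raw luminescence, doses of drug A in rows
#'   and drug B in columns, both axes including dose 0; `raw[1, 1]` is the
#'   double-vehicle well.
#' @param vehicle Numeric vector of vehicle-well signals (defaults to
#'   `raw[1, 1]`).
#' @return Viability matrix in `[0, 1]` with `[1, 1] == 1`.
#' @export
normalize_viability <- function(raw, vehicle = raw[1, 1]) {
  vm <- mean(vehicle)
  if (!is.finite(vm) || vm <= 0) abort("non-positive vehicle mean")
  v <- pmin(pmax(raw / vm, 0), 1.05)
  v <- pmin(v, 1)
  v[1, 1] <- 1
  v
}

#' Bliss-independence excess over a combination dose matrix
#'
#' For each well (i, j) the single-agent inhibitions `fa` (drug A alone,
#' column of dose-B = 0) and `fb` (drug B alone, row of dose-A = 0) give the
#' Bliss expected inhibition `e = fa + fb - fa * fb`; the excess is the
#' observed combination inhibition minus `e`. Positive mean excess over the
#' double-nonzero-dose wells indicates synergy.
#'
#' @param viability Viability matrix in `[0, 1]`; first row and column are
#'   the single-agent axes (dose 0 of the partner).
#' @param synergy_tolerance Minimum mean excess to flag synergy (0.05).
#' @return Object of class `bliss_result`: list with `excess` (matrix),
#'   `expected`, `observed_inhibition`, `mean_excess` (over combination
#'   wells) and `synergy` flag.
#' @export
bliss_excess <- function(viability, synergy_tolerance = 0.05) {
  if (nrow(viability) < 2 || ncol(viability) < 2) {
    abort("dose matrix must include single-agent row and column (dose 0)")
  }
  inhib <- 1 - viability
  fa <- inhib[, 1]  # drug A alone
  fb <- inhib[1, ]  # drug B alone
  e <- outer(fa, fb, function(x, y) x + y - x * y)
  excess <- inhib - e
  comb <- matrix(FALSE, nrow(viability), ncol(viability))
  comb[-1, -1] <- TRUE
  mean_excess <- mean(excess[comb])
  structure(
    list(excess = excess, expected = e, observed_inhibition = inhib,
         mean_excess = mean_excess,
         synergy = mean_excess > synergy_tolerance,
         synergy_tolerance = synergy_tolerance),
    class = "bliss_result")
}

#' @export
print.bliss_result <- function(x, ...) {
  cat("Bliss-independence synergy analysis\n")
  cat(sprintf("  combination wells: %d\n", sum(!is.na(x$excess)) -
                nrow(x$excess) - ncol(x$excess) + 1))
  cat(sprintf("  mean excess inhibition: %.4f (tolerance %.2f)\n",
              x$mean_excess, x$synergy_tolerance))
  cat(sprintf("  synergy: %s\n", if (x$synergy) "YES" else "no"))
  invisible(x)
}

#' @rdname bliss_excess
#' @param x A `bliss_result`.
#' @param ... Unused.
#' @export
tidy.bliss_result <- function(x, ...) {
  df <- as.data.frame(as.table(x$excess), stringsAsFactors = FALSE)
  names(df) <- c("dose_a", "dose_b", "excess")
  df$expected <- as.vector(x$expected)
  df$observed_inhibition <- as.vector(x$observed_inhibition)
  tibble::as_tibble(df)
}

#' @rdname bliss_excess
#' @export
glance.bliss_result <- function(x, ...) {
  tibble::tibble(mean_excess = x$mean_excess, synergy = x$synergy,
                 synergy_tolerance = x$synergy_tolerance)
}

#' @rdname bliss_excess
#' @param object A `bliss_result`.
#' @export
autoplot.bliss_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_b, y = .data$dose_a,
                                   fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red3",
                                  midpoint = 0) +
    ggplot2::labs(x = "dose drug B", y = "dose drug A",
                  fill = "Bliss excess",
                  title = "Excess over Bliss independence") +
    ggplot2::theme_minimal()
}
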