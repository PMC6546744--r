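#' Read a feature-by-sample count table
#'
#' Reads a tab-separated count table whose first column holds feature
#' identifiers (sgRNA, ORF or clonal-barcode ids) and whose remaining columns
#' hold non-negative integer read counts, one column per sample. This is the
#' on-disk carrier for raw screen and barcode sequencing counts.
#'
#' @param path Path to a TSV file. First column: feature id; header row:
#'   sample ids.
#' @param meta_path Optional path to a TSV mapping `feature_id` to
#'   `gene` and `is_control` (logical), e.g. a guide-to-gene map.
#' @return A tibble with a `feature_id` character column followed by one
#'   integer column per sample. When `meta_path` is given the feature
#'   metadata tibble is attached as attribute `"feature_meta"`.
#' @export
read_count_table <- function(path, meta_path = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) {
    abort("count table needs a feature-id column plus >= 1 sample column")
  }
  feature_col <- names(raw)[1]
  names(raw)[1] <- "feature_id"
  if (anyDuplicated(raw$feature_id)) {
    abort(paste0("duplicate feature ids: ",
                 paste(unique(raw$feature_id[duplicated(raw$feature_id)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(names(raw))) {
    abort("duplicate sample ids in header")
  }
  for (j in seq(2, ncol(raw))) {
    cell <- raw[[j]]
    ok <- grepl("^[0-9]+$", cell)
    if (!all(ok)) {
      i <- which(!ok)[1]
      abort(sprintf(
        "non-integer or negative count '%s' at feature '%s', sample '%s'",
        cell[i], raw$feature_id[i], names(raw)[j]))
    }
    raw[[j]] <- as.integer(cell)
  }
  out <- tibble::as_tibble(raw)
  attr(out, "feature_col") <- feature_col
  if (!is.null(meta_path)) {
    meta <- readr::read_tsv(meta_path, col_types = readr::cols(), progress = FALSE)
    names(meta)[1] <- "feature_id"
    attr(out, "feature_meta") <- tibble::as_tibble(meta)
  }
  out
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; `read_count_table(write_count_table(x, f))`
#' reproduces `x`.
#'
#' @param x Count tibble as returned by [read_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  validate_count_table(x)
  orig <- attr(x, "feature_col")
  if (!is.null(orig)) names(x)[1] <- orig
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

validate_count_table <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2 || names(x)[1] != "feature_id") {
    abort(sprintf("`%s` must be a count tibble with a leading feature_id column", arg))
  }
  mat <- as.matrix(x[-1])
  if (!is.numeric(mat) || any(mat < 0) || any(mat != trunc(mat))) {
    abort("counts must be non-negative integers")
  }
  if (anyDuplicated(x$feature_id)) abort("feature ids must be unique")
  invisible(x)
}

#' Extract the count matrix from a count tibble
#'
#' @param x Count tibble.
#' @return Integer matrix with feature ids as rownames.
#' @export
count_matrix <- function(x) {
  m <- as.matrix(x[-1])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; records are returned unchanged under that
#' convention. Missing name and strand columns are filled with `"."`.
#'
#' @param path Path to a BED file with >= 3 columns (chrom, start, end, then
#'   optionally name, score, strand).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_intervals <- function(path) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character())
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t| +")
  n <- lengths(fields)
  if (any(n < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns", which(n < 3)[1]))
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  out <- tibble::tibble(
    chrom = get(1, "."),
    start = suppressWarnings(as.integer(get(2, NA_character_))),
    end = suppressWarnings(as.integer(get(3, NA_character_))),
    name = get(4, "."),
    strand = get(6, ".")
  )
  out$strand[!out$strand %in% c("+", "-")] <- "."
  if (anyNA(out$start) || anyNA(out$end)) {
    abort(sprintf("non-numeric coordinate at BED line %d",
                  which(is.na(out$start) | is.na(out$end))[1]))
  }
  bad <- which(out$end <= out$start | out$start < 0)
  if (length(bad)) {
    abort(sprintf("invalid interval (end <= start or start < 0) at BED line %d", bad[1]))
  }
  out
}

#' Write intervals to a BED file
#'
#' @param x Interval tibble from [read_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  score <- rep(0L, nrow(x))
  readr::write_tsv(
    tibble::tibble(x$chrom, x$start, x$end, x$name, score, x$strand),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a dose-response viability matrix from CSV
#'
#' Expects a CSV whose first column holds doses of drug A (rows) and whose
#' header holds doses of drug B (columns), both including dose 0.
#'
#' @param path CSV path.
#' @return Numeric matrix with dose rownames/colnames.
#' @export
read_dose_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
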