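#' Call piRNA clusters from genomic piRNA loci
#'
#' A cluster is a maximal genomic run of unique piRNA loci in which the gap
#' between adjacent loci (next start minus previous end) is strictly less
#' than `max_gap`, containing at least `min_loci` unique loci. Unique loci
#' are distinct (chrom, start, end, strand) tuples regardless of read count;
#' clusters span both strands, with per-strand locus counts reported.
#'
#' @param loci Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, and optionally `name` and a `source` column
#'   (`repeat_associated` / `non_repeat_associated`).
#' @param min_loci Minimum unique loci per cluster (default 10).
#' @param max_gap Adjacent-gap bound in bp, strict (default 1000).
#' @param per_strand Cluster each strand separately (default FALSE).
#' @return Tibble of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `n_unique_loci`, `n_plus`, `n_minus`, `n_repeat_associated`, and
#'   list-column `locus_rows` (row indices into the sorted unique loci,
#'   attached as attribute `"loci"`).
#' @export
cluster_pirna_loci <- function(loci, min_loci = 10, max_gap = 1000,
                               per_strand = FALSE) {
  u <- tibble::as_tibble(loci) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand)
  groups <- if (per_strand) c("chrom", "strand") else "chrom"
  u <- dplyr::group_by(u, dplyr::across(dplyr::all_of(groups)))
  u <- dplyr::mutate(
    u,
    gap = .data$start - dplyr::lag(.data$end),
    new_run = is.na(.data$gap) | .data$gap >= max_gap,
    run = cumsum(.data$new_run)
  )
  u <- dplyr::ungroup(u)
  cl <- u |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "run")))) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_unique_loci = dplyr::n(),
      n_plus = sum(.data$strand == "+"),
      n_minus = sum(.data$strand == "-"),
      n_repeat_associated = if ("source" %in% names(u))
        sum(.data$source == "repeat_associated") else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_unique_loci >= min_loci) |>
    dplyr::arrange(.data$chrom, .data$start)
  cl$cluster_id <- sprintf("cluster_%03d", seq_len(nrow(cl)))
  out <- dplyr::relocate(dplyr::select(cl, -"run"), "cluster_id")
  attr(out, "loci") <- u
  out
}

#' Length histogram of piRNA sequences
#'
#' @param x Tibble with a `sequence` column and optionally `source`.
#' @return Tibble with `source` (if present), `length`, `n`, `prop`
#'   (proportions summing to 1 within each source).
#' @export
pirna_length_histogram <- function(x) {
  x <- tibble::as_tibble(x)
  x$length <- nchar(x$sequence)
  groups <- intersect("source", names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "length")))) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' 5'-end nucleotide-preference matrix
#'
#' Per-position A/C/G/U frequencies of the first `k` nucleotides of a
#' sequence set (the input for sequence-logo rendering; piRNAs typically
#' show a strong position-1 U bias). Sequences shorter than `k` are
#' dropped and reported via attribute `"n_dropped"`.
#'
#' @param sequences Character vector of RNA sequences, or a tibble with a
#'   `sequence` column.
#' @param k Number of 5' positions (default 15).
#' @return Tibble with `position` (1..k) and columns `A`, `C`, `G`, `U`;
#'   each row sums to 1.
#' @export
five_prime_logo_matrix <- function(sequences, k = 15) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  s <- norm_rna(sequences)
  keep <- nchar(s) >= k
  if (!any(keep)) stop("no sequences of length >= ", k)
  s <- substr(s[keep], 1L, k)
  mat <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  freq <- t(apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = NUC))
    as.numeric(tab) / length(col)
  }))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(freq), NUC))
  out <- dplyr::bind_cols(tibble::tibble(position = seq_len(k)), out)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
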