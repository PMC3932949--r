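#' Concatenate CDS records and fragment into non-overlapping segments
#'
#' Coding sequences are joined in a seeded random order and cut, left to
#' right, into non-overlapping segments whose length multiset equals the
#' supplied draw (typically the length distribution of the known-precursor
#' positive set).
#'
#' @param cds Tibble with `id`, `sequence` (CDS records, FASTA-derived).
#' @param lengths Integer vector of segment lengths to cut (one per desired
#'   segment, with multiplicity).
#' @param seed Integer seed controlling the concatenation order and the
#'   order in which lengths are cut.
#' @return Tibble with `id`, `sequence`, `origin_start`, `origin_end`
#'   (0-based half-open offsets on the concatenated sequence).
#' @export
concat_and_fragment <- function(cds, lengths, seed = 1L) {
  cds <- tibble::as_tibble(cds)
  lengths <- as.integer(lengths)
  stopifnot(all(lengths > 0))
  total <- sum(nchar(cds$sequence))
  if (total < sum(lengths)) {
    stop("insufficient CDS sequence: have ", total, " nt, need ",
         sum(lengths), " nt (short by ", sum(lengths) - total, ")")
  }
  set.seed(seed)
  cat_seq <- paste(norm_rna(cds$sequence[sample(nrow(cds))]), collapse = "")
  cut_len <- sample(lengths)
  ends <- cumsum(cut_len)
  starts <- ends - cut_len
  tibble::tibble(
    id = sprintf("seg_%04d", seq_along(cut_len)),
    sequence = substring(cat_seq, starts + 1L, ends),
    origin_start = starts,
    origin_end = ends
  )
}

#' Filter folded segments into acceptable pseudo-hairpins
#'
#' A segment qualifies as a pseudo precursor when its predicted structure
#' has at least `min_basepairs` base pairs (the dot-bracket structure
#' already includes GU wobble pairs) and its free energy is at most
#' `max_mfe` kcal/mol.
#'
#' @param hairpins Tibble with `id`, `sequence`, `structure`, `mfe`.
#' @param min_basepairs Minimum base pairs (default 19).
#' @param max_mfe Maximum (i.e. least negative) MFE in kcal/mol
#'   (default -15.79).
#' @return The input tibble plus `n_basepairs`, `n_hairpin_loops`,
#'   `multi_stem`, `accept` (logical) and `reason`
#'   (`NA`, `"basepairs"` or `"mfe"`; base pairing is checked first).
#' @export
filter_pseudo <- function(hairpins, min_basepairs = 19, max_mfe = -15.79) {
  h <- validate_hairpins(hairpins)
  info <- purrr::map(h$structure, function(s) {
    pt <- parse_dot_bracket(s)
    el <- decompose_structure(pt)
    list(bp = pt$n_basepairs, loops = el$n_hairpin_loops)
  })
  h$n_basepairs <- vapply(info, `[[`, integer(1), "bp")
  h$n_hairpin_loops <- vapply(info, `[[`, integer(1), "loops")
  h$multi_stem <- h$n_hairpin_loops > 1L
  h$accept <- h$n_basepairs >= min_basepairs & h$mfe <= max_mfe
  h$reason <- dplyr::case_when(
    h$n_basepairs < min_basepairs ~ "basepairs",
    h$mfe > max_mfe ~ "mfe",
    TRUE ~ NA_character_
  )
  h
}

#' Sample the pseudo-hairpin negative set
#'
#' Seeded sampling without replacement of `n_single` single-stem and
#' `n_multi` multi-stem accepted pseudo-hairpins (the published training
#' composition is 325 + 19, mirroring the known-precursor set).
#'
#' @param accepted Output of [filter_pseudo()] (rows with `accept = FALSE`
#'   are dropped).
#' @param n_single Number of single-stem negatives (default 325).
#' @param n_multi Number of multi-stem negatives (default 19).
#' @param seed Integer seed.
#' @return Tibble of the selected negatives with a `topology` column
#'   (`"single"`/`"multi"`).
#' @export
sample_negatives <- function(accepted, n_single = 325, n_multi = 19, seed = 1L) {
  a <- dplyr::filter(tibble::as_tibble(accepted), .data$accept)
  singles <- dplyr::filter(a, !.data$multi_stem)
  multis <- dplyr::filter(a, .data$multi_stem)
  if (nrow(singles) < n_single || nrow(multis) < n_multi) {
    stop("insufficient accepted pool: ", nrow(singles), " single-stem (need ",
         n_single, "), ", nrow(multis), " multi-stem (need ", n_multi, ")")
  }
  set.seed(seed)
  out <- dplyr::bind_rows(
    dplyr::mutate(dplyr::slice_sample(singles, n = n_single), topology = "single"),
    dplyr::mutate(dplyr::slice_sample(multis, n = n_multi), topology = "multi")
  )
  out
}

#' Build a pseudo-hairpin negative set end to end
#'
#' Fragments CDS sequence to the positive set's length distribution, folds
#' via the supplied folder, filters on the base-pair and MFE thresholds and
#' samples the requested composition. An audit table (origin offsets, base
#' pairs, MFE, topology, accept/reason) is attached as attribute `"audit"`.
#'
#' @param cds CDS tibble (`id`, `sequence`).
#' @param positive_lengths Integer lengths of the positive precursors.
#' @param folder Function `(tibble with id, sequence) -> tibble with added
#'   structure, mfe` — e.g. [fold_hairpins()] or a synthetic assigner.
#' @param n_single,n_multi Target composition (defaults 325/19).
#' @param min_basepairs,max_mfe Acceptance thresholds (19 / -15.79).
#' @param seed Integer seed.
#' @return Tibble of negatives (see [sample_negatives()]).
#' @export
build_negative_set <- function(cds, positive_lengths, folder,
                               n_single = 325, n_multi = 19,
                               min_basepairs = 19, max_mfe = -15.79,
                               seed = 1L) {
  seg <- concat_and_fragment(cds, positive_lengths, seed = seed)
  folded <- folder(seg)
  flt <- filter_pseudo(folded, min_basepairs = min_basepairs, max_mfe = max_mfe)
  out <- sample_negatives(flt, n_single = n_single, n_multi = n_multi,
                          seed = seed)
  attr(out, "audit") <- flt
  out
}

#' Fold sequences with an external RNA-folding tool
#'
#' Thin adapter around the `RNAfold` executable (default parameters); the
#' package itself implements no thermodynamic folding. Requires the tool on
#' the PATH.
#'
#' @param x Tibble with `id`, `sequence`.
#' @param binary Name/path of the folding executable (default `"RNAfold"`).
#' @return The input with `structure` and `mfe` columns appended.
#' @export
fold_hairpins <- function(x, binary = "RNAfold") {
  if (Sys.which(binary) == "") stop("folding tool not found on PATH: ", binary)
  x <- tibble::as_tibble(x)
  inp <- tempfile(fileext = ".fa")
  writeLines(paste0(">", x$id, "\n", x$sequence), inp)
  out <- system2(binary, c("--noPS", "--infile", inp), stdout = TRUE)
  sl <- out[seq(3, length(out), by = 3)]
  m <- regmatches(sl, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", sl))
  x$structure <- vapply(m, `[[`, character(1), 2)
  x$mfe <- as.numeric(vapply(m, `[[`, character(1), 3))
  x
}
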