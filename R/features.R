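NUC <- c("A", "C", "G", "U")

triplet_patterns <- function() {
  # left/middle/right paired ('(') vs unpaired ('.'), binary order
  states <- expand.grid(r = c(".", "("), m = c(".", "("), l = c(".", "("),
                        stringsAsFactors = FALSE)
  paste0(states$l, states$m, states$r)
}

#' Names of the 65 hairpin features, in catalogue order
#'
#' Order: GC percentage; 16 dinucleotide percentages; 9 pairing-topology
#' scalars; 32 triplet structure-sequence element frequencies; MFE and 6
#' MFE-derived values.
#'
#' @return Character vector of length 65.
#' @export
feature_names <- function() {
  dinuc <- paste0("pct_", as.vector(t(outer(NUC, NUC, paste0))))
  trip <- as.vector(vapply(NUC, function(n) paste0(n, triplet_patterns()),
                           character(8)))
  c("pct_GC_content", dinuc,
    "MCPN", "r_p_n", "r_unp_n", "r_p_unp", "avg_bp_stem", "dP",
    "n_bulge", "r_unp_bulge", "r_bulge_l",
    trip,
    "MFE", "dG", "MFE1", "MFE2", "MFE3", "MFE4", "MFE5")
}

#' Sequence-composition features (GC and dinucleotide percentages)
#'
#' @param sequence RNA string (length >= 2).
#' @return Named numeric vector of 17 values in percent: `pct_GC` =
#'   (|G|+|C|)/L\*100 and the 16 overlapping dinucleotide percentages
#'   |XY|/(L-1)\*100.
#' @export
composition_features <- function(sequence) {
  s <- norm_rna(sequence)
  L <- nchar(s)
  if (L < 2L) stop("composition features need sequence length >= 2")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C")) / L * 100
  di <- paste0(chars[-L], chars[-1L])
  lev <- as.vector(t(outer(NUC, NUC, paste0)))
  cnt <- table(factor(di, levels = lev))
  out <- c(gc, as.numeric(cnt) / (L - 1L) * 100)
  names(out) <- c("pct_GC_content", paste0("pct_", lev))
  out
}

#' Pairing-topology features
#'
#' The nine secondary-structure scalars: maximum consecutive paired
#' nucleotides, paired/unpaired ratios, base pairs per stem, normalised base
#' pairs, bulge counts and ratios. Ratios with a zero denominator are 0.
#'
#' @param pt A `pair_table`.
#' @param elems Matching `structure_elements` (computed if missing).
#' @return Named numeric vector of 9 values (`MCPN`, `r_p_n`, `r_unp_n`,
#'   `r_p_unp`, `avg_bp_stem`, `dP`, `n_bulge`, `r_unp_bulge`, `r_bulge_l`).
#' @export
pairing_features <- function(pt, elems = decompose_structure(pt)) {
  L <- length(pt$pairs)
  div0 <- function(a, b) if (b == 0) 0 else a / b
  c(
    MCPN = as.numeric(elems$mcpn),
    r_p_n = div0(pt$n_paired, L),
    r_unp_n = div0(pt$n_unpaired, L),
    r_p_unp = div0(pt$n_paired, pt$n_unpaired),
    avg_bp_stem = div0(pt$n_basepairs, elems$n_stems),
    dP = div0(pt$n_basepairs, L),
    n_bulge = as.numeric(elems$n_bulges),
    r_unp_bulge = div0(pt$n_unpaired, elems$n_bulges),
    r_bulge_l = div0(elems$n_bulges, L)
  )
}

#' Triplet structure-sequence element frequencies
#'
#' For each interior position i the pairing states of (i-1, i, i+1) --
#' paired (either bracket) vs unpaired -- combine with the nucleotide at i
#' into 32 categories; frequencies are counts over the L-2 windows.
#'
#' @param sequence RNA string (length >= 3).
#' @param structure Matching dot-bracket string.
#' @return Named numeric vector of 32 frequencies summing to 1.
#' @export
triplet_features <- function(sequence, structure) {
  s <- norm_rna(sequence)
  L <- nchar(s)
  if (L < 3L) stop("triplet features need sequence length >= 3")
  if (nchar(structure) != L) stop("sequence/structure length mismatch")
  st <- chartr(")", "(", structure)
  sc <- strsplit(st, "", fixed = TRUE)[[1]]
  nc <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 2:(L - 1L)
  pat <- paste0(sc[i - 1L], sc[i], sc[i + 1L])
  lev <- as.vector(vapply(NUC, function(n) paste0(n, triplet_patterns()),
                          character(8)))
  cnt <- table(factor(paste0(nc[i], pat), levels = lev))
  out <- as.numeric(cnt) / (L - 2L)
  names(out) <- lev
  out
}

#' Free-energy features
#'
#' MFE and its six derived values; ratios with a zero denominator are 0.
#'
#' @param mfe Minimum free energy (kcal/mol).
#' @param L Sequence length (nt).
#' @param pct_gc GC content in percent.
#' @param pt A `pair_table`.
#' @param elems Matching `structure_elements`.
#' @return Named numeric vector of 7 values (`MFE`, `dG`, `MFE1`..`MFE5`).
#' @export
energy_features <- function(mfe, L, pct_gc, pt, elems = decompose_structure(pt)) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  dG <- div0(mfe, L)
  c(
    MFE = mfe,
    dG = dG,
    MFE1 = div0(dG, pct_gc),
    MFE2 = div0(dG, elems$n_stems),
    MFE3 = div0(dG, elems$n_hairpin_loops),
    MFE4 = div0(mfe, pt$n_basepairs),
    MFE5 = div0(dG, elems$n_bulges)
  )
}

extract_one <- function(sequence, structure, mfe) {
  pt <- parse_dot_bracket(structure)
  el <- decompose_structure(pt)
  comp <- composition_features(sequence)
  c(comp,
    pairing_features(pt, el),
    triplet_features(sequence, structure),
    energy_features(mfe, nchar(sequence), comp[["pct_GC_content"]], pt, el))
}

#' Compute the 65 hairpin features for a table of candidate precursors
#'
#' The full feature catalogue: GC content, 16 dinucleotide percentages,
#' 9 pairing-topology scalars, 32 triplet structure-sequence elements, MFE
#' and 6 MFE ratios.
#'
#' @param hairpins Data frame with `id`, `sequence`, `structure`, `mfe`.
#' @return A tibble: `id` plus the 65 feature columns of [feature_names()],
#'   one row per hairpin, deterministic in row order.
#' @examples
#' h <- tibble::tibble(id = "h1", sequence = "GGGGCAAAAGCC",
#'                     structure = "((((....))))", mfe = -8.5)
#' hairpin_features(h)
#' @export
hairpin_features <- function(hairpins) {
  h <- validate_hairpins(hairpins)
  m <- purrr::pmap(h[c("sequence", "structure", "mfe")],
                   function(sequence, structure, mfe)
                     extract_one(sequence, structure, mfe))
  fm <- tibble::as_tibble(do.call(rbind, m))
  stopifnot(identical(names(fm), feature_names()))
  dplyr::bind_cols(tibble::tibble(id = h$id), fm)
}

#' Write / read a feature matrix as TSV
#'
#' The header row carries the feature names; an `id` column and, optionally,
#' a `label` column (+1/-1) are kept.
#'
#' @param x Feature tibble from [hairpin_features()] (optionally with `label`).
#' @param path Output path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_feature_tsv <- function(x, path) write_tsv_v(x, path)

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) read_tsv_v(path)
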