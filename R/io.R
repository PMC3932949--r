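#' Read a Vienna-style FASTA + dot-bracket file
#'
#' The dialect is the one RNA-folding tools emit: a `>id` header line, the
#' sequence on one line, then the dot-bracket structure followed by the
#' minimum free energy in parentheses, e.g. `"((((...)))) (-15.79)"`.
#'
#' @param path Path to the file.
#' @return A tibble with columns `id`, `sequence`, `structure`, `mfe`.
#' @export
read_vienna <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, "#")]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no FASTA headers in ", path)
  if (any(diff(c(hdr, length(lines) + 1L)) != 3L)) {
    stop("malformed Vienna file (expected header, sequence, structure triples): ", path)
  }
  rec <- purrr::map_dfr(hdr, function(i) {
    sline <- lines[i + 2L]
    m <- regmatches(sline, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sline))[[1]]
    if (length(m) != 3L) stop("cannot parse structure line: '", sline, "'")
    tibble::tibble(
      id = sub("^>\\s*", "", lines[i]),
      sequence = norm_rna(lines[i + 1L]),
      structure = m[2],
      mfe = as.numeric(m[3])
    )
  })
  validate_hairpins(rec)
}

#' Write hairpin records in the Vienna dialect
#'
#' @param hairpins Tibble with `id`, `sequence`, `structure`, `mfe`.
#' @param path Output path.
#' @param digits Decimal places for the MFE annotation (default 2, the
#'   folding-tool convention).
#' @return `path`, invisibly.
#' @export
write_vienna <- function(hairpins, path, digits = 2) {
  h <- validate_hairpins(hairpins)
  lines <- purrr::pmap(h[c("id", "sequence", "structure", "mfe")],
    function(id, sequence, structure, mfe) {
      c(paste0(">", id), sequence,
        sprintf("%s (%.*f)", structure, digits, mfe))
    })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (plain-text) FASTA file.
#' @param rna Convert T to U (default TRUE).
#' @return Tibble with `id` (first word of the header) and `sequence`.
#' @export
read_fasta_tbl <- function(path, rna = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (rna) seqs <- norm_rna(seqs)
  tibble::tibble(
    id = sub("\\s.*$", "", names(ss)),
    sequence = unname(seqs)
  )
}

#' Write a tibble of sequences as FASTA
#'
#' @param x Tibble with `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path) {
  ss <- Biostrings::BStringSet(stats::setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a BED file (BED6 or BED6+) into a tibble
#'
#' Intervals are kept 0-based half-open as in the file.
#'
#' @param path Path to a BED file.
#' @param extra_names Optional names for columns beyond the sixth.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (+ any extra columns).
#' @export
read_bed_tbl <- function(path, extra_names = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- base[seq_len(min(ncol(x), 6L))]
  if (ncol(x) > 6L) {
    ex <- if (is.null(extra_names)) paste0("V", seq_len(ncol(x) - 6L)) else extra_names
    nm <- c(nm, ex)
  }
  names(x) <- nm
  tibble::as_tibble(x)
}

#' Write intervals as BED
#'
#' @param x Tibble with at least `chrom`, `start`, `end`; `name`, `score`,
#'   `strand` and any further columns are appended in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_tbl <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  rest <- setdiff(names(x), cols)
  readr::write_tsv(x[c(cols, rest)], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# versioned TSV: every exported table declares its format in a header
# comment; readers reject unknown versions.
FORMAT_TAG <- "srnakit-tsv/1"

#' Write a tibble as a versioned TSV
#'
#' The first line is a comment declaring the format version; [read_tsv_v()]
#' rejects files whose declared version it does not know.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_v <- function(x, path) {
  readr::write_lines(paste0("# ", FORMAT_TAG), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a versioned TSV written by [write_tsv_v()]
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_tsv_v <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (!identical(first, paste0("# ", FORMAT_TAG))) {
    stop("unknown or missing format version in ", path,
         " (expected '# ", FORMAT_TAG, "')")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Read a collapsed tag-count table
#'
#' A plain TSV with a `sequence` column and one numeric count column per
#' library. A `tag_id` column is added if absent (sequence-derived).
#'
#' @param path Path to the TSV.
#' @return Tibble with `tag_id`, `sequence` and count columns.
#' @export
read_tag_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"sequence" %in% names(x)) stop("tag table needs a 'sequence' column")
  x$sequence <- norm_rna(x$sequence)
  if (!"tag_id" %in% names(x)) {
    x$tag_id <- paste0("t", seq_len(nrow(x)))
  }
  dplyr::relocate(tibble::as_tibble(x), "tag_id", "sequence")
}
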