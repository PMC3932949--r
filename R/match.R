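#' Match read tags against a reference sequence set
#'
#' Reports every position (both strands by default) at which a tag occurs
#' as a substring of a reference sequence with at most `max_mismatch`
#' substitutions. Designed for desk-scale references; genome-scale
#' alignments can instead be imported with [read_sam_hits()] or
#' [read_bed_tbl()] and fed to downstream steps directly.
#'
#' @param tags Tibble with `tag_id` and `sequence`.
#' @param reference Tibble with `id` and `sequence`.
#' @param max_mismatch Maximum substitutions (default 1).
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return Tibble with `tag_id`, `ref_id`, `start`, `end` (0-based
#'   half-open on the reference forward strand), `strand`, `mismatches`.
#' @export
match_tags <- function(tags, reference, max_mismatch = 1, both_strands = TRUE) {
  tags <- tibble::as_tibble(tags)
  reference <- tibble::as_tibble(reference)
  stopifnot(all(c("tag_id", "sequence") %in% names(tags)),
            all(c("id", "sequence") %in% names(reference)))
  if (nrow(tags) == 0L || nrow(reference) == 0L) {
    return(tibble::tibble(tag_id = character(), ref_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), mismatches = integer()))
  }
  hits <- .match_tags_cpp(tags$sequence, reference$sequence,
                          max_mm = as.integer(max_mismatch),
                          both_strands = both_strands)
  tibble::tibble(
    tag_id = tags$tag_id[hits$tag_idx],
    ref_id = reference$id[hits$ref_idx],
    start = hits$start - 1L,
    end = hits$start - 1L + nchar(tags$sequence[hits$tag_idx]),
    strand = hits$strand,
    mismatches = hits$mismatches
  )
}

#' Import precomputed alignments from a SAM file
#'
#' Reads primary fields of a (plain-text) SAM file and converts them to the
#' hit-table layout of [match_tags()]. Only unmapped-flag filtering is done;
#' the mismatch count is taken from the `NM` tag when present (0 otherwise).
#'
#' @param path Path to a SAM file.
#' @return Tibble with `tag_id`, `ref_id`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`.
#' @export
read_sam_hits <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble::tibble(tag_id = character(), ref_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), mismatches = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  len <- vapply(f, function(x) nchar(x[10]), integer(1))
  tibble::tibble(
    tag_id = vapply(f, `[[`, character(1), 1),
    ref_id = vapply(f, `[[`, character(1), 3),
    start = start,
    end = start + len,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mismatches = nm
  )
}
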