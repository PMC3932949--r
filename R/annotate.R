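RESERVED_COLS <- c("tag_id", "sequence", "length", "start", "end", "strand",
                   "mismatches", "n_positions", "category", "subcategory",
                   "recalled_ncRNA", "repeat_associated_piRNA")

#' Names of the per-library count columns of a tag table
#'
#' Every numeric column that is not a structural column is taken to be a
#' library's observation counts.
#'
#' @param tags A tag tibble.
#' @return Character vector of library column names.
#' @export
library_cols <- function(tags) {
  num <- names(tags)[vapply(tags, is.numeric, logical(1))]
  setdiff(num, RESERVED_COLS)
}

#' Quality-filter a collapsed tag table
#'
#' Keeps unique reads of 18-35 nt (boundaries inclusive) observed at least
#' `min_count` times in at least one library; shorter/longer or rarer tags
#' are dropped. The counts per filter are attached as attribute `"qc"`.
#'
#' @param tags Tibble with `tag_id`, `sequence` and per-library counts.
#' @param min_len,max_len Length bounds in nt (defaults 18 and 35).
#' @param min_count Minimum per-library count in the best library (default 3).
#' @return The retained tags (with a `length` column added); attribute
#'   `"qc"` holds a tibble of input/dropped/retained tag and read counts.
#' @export
preprocess_tags <- function(tags, min_len = 18, max_len = 35, min_count = 3) {
  x <- tibble::as_tibble(tags)
  libs <- library_cols(x)
  if (length(libs) == 0L) stop("tag table has no count columns")
  x$length <- nchar(x$sequence)
  len_ok <- x$length >= min_len & x$length <= max_len
  best <- if (nrow(x)) do.call(pmax, x[libs]) else numeric(0)
  cnt_ok <- best >= min_count
  keep <- len_ok & cnt_ok
  qc <- tibble::tibble(
    filter = c("input", "length_out_of_range", "below_min_count", "retained"),
    tags = c(nrow(x), sum(!len_ok), sum(len_ok & !cnt_ok), sum(keep)),
    reads = c(sum(x[libs]), sum(x[!len_ok, libs]),
              sum(x[len_ok & !cnt_ok, libs]), sum(x[keep, libs]))
  )
  out <- x[keep, , drop = FALSE]
  attr(out, "qc") <- qc
  out
}

NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA/snoRNA")

assign_level <- function(remaining, reference, max_mismatch) {
  if (is.null(reference) || nrow(reference) == 0L || nrow(remaining) == 0L) {
    return(list(hit = remaining[0, ], rest = remaining, hits = NULL))
  }
  hits <- match_tags(remaining, reference, max_mismatch = max_mismatch)
  hit_ids <- unique(hits$tag_id)
  list(
    hit = remaining[remaining$tag_id %in% hit_ids, , drop = FALSE],
    rest = remaining[!remaining$tag_id %in% hit_ids, , drop = FALSE],
    hits = hits
  )
}

#' Hierarchically annotate read tags into small-RNA categories
#'
#' Tags are assigned in the fixed priority order miRNA, Rfam ncRNA (rRNA /
#' tRNA / snRNA/snoRNA), genomic repeat, mRNA, piRNA; a tag assigned at one
#' level is removed from all later levels, so every tag receives exactly one
#' category (or `"unclassified"`). Repeat-level hits whose repeat class
#' names an ncRNA are recalled to that ncRNA category; the remaining
#' repeat-level tags are re-matched against the piRNA reference and, on
#' success, categorised as piRNA with the `repeat_associated_piRNA` flag.
#'
#' @param tags Retained tag tibble (see [preprocess_tags()]).
#' @param references Named list of reference tibbles (each `id`, `sequence`;
#'   `class` additionally for `rfam` and `repeats`): elements `mirna`,
#'   `rfam`, `repeats`, `mrna`, `pirna`. Missing/NULL elements are treated
#'   as empty.
#' @param max_mismatch Maximum substitutions when matching (default 1).
#' @return Tibble: the tag columns plus `category` (one of miRNA, rRNA,
#'   tRNA, snRNA/snoRNA, repeat, mRNA, piRNA, unclassified),
#'   `recalled_ncRNA` and `repeat_associated_piRNA` flags. The per-level
#'   hit tables are attached as attribute `"hits"`.
#' @export
hierarchical_annotate <- function(tags, references, max_mismatch = 1) {
  x <- tibble::as_tibble(tags)
  if (!"length" %in% names(x)) x$length <- nchar(x$sequence)
  ref <- function(nm) references[[nm]]
  res <- list()
  hit_tables <- list()
  remaining <- x

  label <- function(d, category, recalled = FALSE, repeat_assoc = FALSE) {
    if (nrow(d) == 0L) return(NULL)
    d$category <- category
    d$recalled_ncRNA <- recalled
    d$repeat_associated_piRNA <- repeat_assoc
    d
  }

  # 1. miRNA
  lv <- assign_level(remaining, ref("mirna"), max_mismatch)
  res$mirna <- label(lv$hit, "miRNA")
  hit_tables$mirna <- lv$hits
  remaining <- lv$rest

  # 2. Rfam ncRNA, categorised by the class of the best hit
  lv <- assign_level(remaining, ref("rfam"), max_mismatch)
  if (!is.null(lv$hits) && nrow(lv$hits) > 0L) {
    cls <- lv$hits |>
      dplyr::left_join(dplyr::select(ref("rfam"), ref_id = "id", "class"),
                       by = "ref_id") |>
      dplyr::arrange(.data$mismatches) |>
      dplyr::distinct(.data$tag_id, .keep_all = TRUE)
    for (cl in unique(cls$class)) {
      ids <- cls$tag_id[cls$class == cl]
      res[[paste0("rfam_", cl)]] <-
        label(lv$hit[lv$hit$tag_id %in% ids, ], cl)
    }
  }
  hit_tables$rfam <- lv$hits
  remaining <- lv$rest

  # 3. repeats: ncRNA recall, then repeat-associated piRNA rescue
  lv <- assign_level(remaining, ref("repeats"), max_mismatch)
  hit_tables$repeats <- lv$hits
  if (nrow(lv$hit) > 0L) {
    cls <- lv$hits |>
      dplyr::left_join(dplyr::select(ref("repeats"), ref_id = "id", "class"),
                       by = "ref_id")
    recall_cls <- cls |>
      dplyr::filter(.data$class %in% NCRNA_CLASSES) |>
      dplyr::mutate(prio = match(.data$class, NCRNA_CLASSES)) |>
      dplyr::arrange(.data$prio, .data$mismatches) |>
      dplyr::distinct(.data$tag_id, .keep_all = TRUE)
    for (cl in unique(recall_cls$class)) {
      ids <- recall_cls$tag_id[recall_cls$class == cl]
      res[[paste0("recalled_", cl)]] <-
        label(lv$hit[lv$hit$tag_id %in% ids, ], cl, recalled = TRUE)
    }
    rep_rest <- lv$hit[!lv$hit$tag_id %in% recall_cls$tag_id, , drop = FALSE]
    rescue <- assign_level(rep_rest, ref("pirna"), max_mismatch)
    res$repeat_pirna <- label(rescue$hit, "piRNA", repeat_assoc = TRUE)
    hit_tables$repeat_pirna <- rescue$hits
    res$repeat_plain <- label(rescue$rest, "repeat")
  }
  remaining <- lv$rest

  # 4. mRNA
  lv <- assign_level(remaining, ref("mrna"), max_mismatch)
  res$mrna <- label(lv$hit, "mRNA")
  hit_tables$mrna <- lv$hits
  remaining <- lv$rest

  # 5. piRNA (non-repeat-associated)
  lv <- assign_level(remaining, ref("pirna"), max_mismatch)
  res$pirna <- label(lv$hit, "piRNA")
  hit_tables$pirna <- lv$hits

  res$unclassified <- label(lv$rest, "unclassified")

  out <- dplyr::bind_rows(res)
  out <- out[match(x$tag_id[x$tag_id %in% out$tag_id], out$tag_id), ]
  attr(out, "hits") <- hit_tables
  out
}

#' Fractional per-position counts for multi-mapped tags
#'
#' Each tag's observed count is divided evenly over its mapping positions,
#' so that the fractional counts of a tag sum exactly to its raw count in
#' every library.
#'
#' @param tags Tag tibble with counts.
#' @param hits Hit table for those tags (e.g. genome hits from
#'   [match_tags()]).
#' @return The hit table joined with `n_positions` and fractional per-library
#'   counts.
#' @export
fractional_counts <- function(tags, hits) {
  libs <- library_cols(tags)
  np <- dplyr::count(hits, .data$tag_id, name = "n_positions")
  out <- hits |>
    dplyr::left_join(np, by = "tag_id") |>
    dplyr::left_join(tags[c("tag_id", libs)], by = "tag_id")
  for (l in libs) out[[l]] <- out[[l]] / out$n_positions
  out
}

#' Annotate a study: genome mapping, categories, fractional counts
#'
#' Full annotation of a retained tag table: tags are mapped to the genome
#' (tags without a genomic hit are set aside as unmapped), mapped tags are
#' hierarchically categorised, and per-library genome-mapped totals are
#' computed for RPM normalisation.
#'
#' @param tags Retained tag tibble.
#' @param references Reference list, see [hierarchical_annotate()].
#' @param genome Genome tibble (`id`, `sequence`), or NULL to skip mapping
#'   (all tags treated as mapped).
#' @param max_mismatch Maximum substitutions (default 1).
#' @return List with `assignments` (categorised mapped tags),
#'   `genome_hits` (with `n_positions` and fractional counts), `unmapped`
#'   (tags without genomic hits) and `mapped_totals` (named per-library
#'   genome-mapped read totals).
#' @export
annotate_study <- function(tags, references, genome = NULL, max_mismatch = 1) {
  x <- tibble::as_tibble(tags)
  libs <- library_cols(x)
  if (!is.null(genome)) {
    ghits <- match_tags(x, genome, max_mismatch = max_mismatch)
    mapped <- x[x$tag_id %in% ghits$tag_id, , drop = FALSE]
    unmapped <- x[!x$tag_id %in% ghits$tag_id, , drop = FALSE]
    ghits <- fractional_counts(mapped, ghits)
  } else {
    ghits <- NULL
    mapped <- x
    unmapped <- x[0, ]
  }
  assignments <- hierarchical_annotate(mapped, references, max_mismatch)
  totals <- vapply(mapped[libs], sum, numeric(1))
  list(assignments = assignments, genome_hits = ghits,
       unmapped = unmapped, mapped_totals = totals)
}

#' isomiR-aware quantification of annotated miRNA precursors
#'
#' Genomic hits of miRNA-category tags are grouped per annotated precursor
#' within a tolerance window of 2 nt upstream and 5 nt downstream of the
#' precursor locus (strand-aware, 0-based half-open coordinates). Within a
#' window the member tags are the miRNA's isomiRs; the expression of the
#' miRNA in each library is the count of its most abundant isomiR.
#'
#' @param mirna_hits Genome hits of miRNA tags carrying per-library counts
#'   (e.g. the miRNA rows of `genome_hits` from [annotate_study()] — counts
#'   may be fractional for multi-mapped tags).
#' @param precursors Tibble of precursor loci: `name`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @param window Upstream/downstream tolerance in nt (default `c(2, 5)`).
#' @return Tibble with one row per precursor and library: `name`, `library`,
#'   `expression` (most abundant isomiR count), `n_isomirs`, `total_reads`.
#'   Tags falling in the windows of several (overlapping) precursors count
#'   for each and are flagged in attribute `"overlaps"`.
#' @export
quantify_mirnas <- function(mirna_hits, precursors, window = c(2, 5)) {
  libs <- library_cols(mirna_hits)
  p <- tibble::as_tibble(precursors)
  h <- dplyr::rename(tibble::as_tibble(mirna_hits), chrom = "ref_id")
  joined <- dplyr::inner_join(h, p, by = "chrom", suffix = c("", ".pre"),
                              relationship = "many-to-many")
  up <- window[1]; down <- window[2]
  lo <- ifelse(joined$strand.pre == "+", joined$start.pre - up,
               joined$start.pre - down)
  hi <- ifelse(joined$strand.pre == "+", joined$end.pre + down,
               joined$end.pre + up)
  members <- joined[joined$start >= lo & joined$end <= hi, , drop = FALSE]
  n_hits_per_tag <- dplyr::count(members, .data$tag_id, name = "n_windows")
  overlaps <- dplyr::filter(n_hits_per_tag, .data$n_windows > 1L)
  long <- tidyr::pivot_longer(members, dplyr::all_of(libs),
                              names_to = "library", values_to = "count")
  out <- long |>
    dplyr::group_by(.data$name, .data$library) |>
    dplyr::summarise(
      expression = max(.data$count),
      n_isomirs = dplyr::n_distinct(.data$tag_id[.data$count > 0]),
      total_reads = sum(.data$count),
      .groups = "drop"
    )
  attr(out, "overlaps") <- overlaps
  out
}

#' Reads-per-million normalisation
#'
#' @param counts Tibble with per-library count columns.
#' @param totals Named numeric vector of per-library totals (the
#'   genome-mapped read count of each library); all > 0.
#' @return The tibble with count columns replaced by count / total * 1e6.
#' @export
rpm_normalize <- function(counts, totals) {
  x <- tibble::as_tibble(counts)
  libs <- intersect(library_cols(x), names(totals))
  if (length(libs) == 0L) stop("no count columns matching 'totals' names")
  if (any(totals[libs] <= 0)) stop("library totals must be > 0")
  for (l in libs) x[[l]] <- x[[l]] / totals[[l]] * 1e6
  x
}

#' Per-library length-by-category summary
#'
#' Total reads and unique tag counts per read length and category for each
#' library, with within-library proportions — the input for bimodal length
#' distribution and category-composition displays.
#'
#' @param assignments Output of [hierarchical_annotate()].
#' @return Long tibble: `library`, `length`, `category`, `reads`,
#'   `unique_tags`, `prop_reads` (per-library proportion of reads),
#'   `prop_unique`.
#' @export
length_category_summary <- function(assignments) {
  libs <- library_cols(assignments)
  long <- tidyr::pivot_longer(assignments, dplyr::all_of(libs),
                              names_to = "library", values_to = "count")
  long |>
    dplyr::group_by(.data$library, .data$length, .data$category) |>
    dplyr::summarise(
      reads = sum(.data$count),
      unique_tags = sum(.data$count > 0),
      .groups = "drop_last"
    ) |>
    dplyr::group_by(.data$library) |>
    dplyr::mutate(
      prop_reads = .data$reads / sum(.data$reads),
      prop_unique = .data$unique_tags / sum(.data$unique_tags)
    ) |>
    dplyr::ungroup()
}
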