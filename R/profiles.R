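#' Group mature miRNAs into seed families
#'
#' The family key is the seed: nucleotides 2-8 (1-based, inclusive; 7 nt)
#' of the mature sequence. Sequences shorter than 8 nt are skipped and
#' reported via attribute `"skipped"`.
#'
#' @param matures Tibble with `id` and `sequence` (mature miRNAs).
#' @return Tibble with `family` (the 7-nt seed), `n_members` and
#'   list-column `members` (member ids).
#' @export
seed_family <- function(matures) {
  x <- tibble::as_tibble(matures)
  x$sequence <- norm_rna(x$sequence)
  short <- x[nchar(x$sequence) < 8L, , drop = FALSE]
  x <- x[nchar(x$sequence) >= 8L, , drop = FALSE]
  x$family <- substr(x$sequence, 2L, 8L)
  out <- x |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_members = dplyr::n(),
                     members = list(.data$id), .groups = "drop")
  attr(out, "skipped") <- short
  out
}

#' Positionwise nucleotide preferences of a sequence set
#'
#' Frequencies of A/C/G/U at each 5'-anchored position; ragged 3' ends are
#' handled by per-position denominators (only sequences reaching a position
#' contribute to it).
#'
#' @param sequences Character vector, or a tibble with a `sequence` column.
#' @return Tibble with `position`, `n` (sequences covering the position)
#'   and frequency columns `A`, `C`, `G`, `U` summing to 1 per row.
#' @export
position_preferences <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  s <- norm_rna(sequences)
  kmax <- max(nchar(s))
  purrr::map_dfr(seq_len(kmax), function(p) {
    covered <- s[nchar(s) >= p]
    tab <- table(factor(substr(covered, p, p), levels = NUC))
    dplyr::bind_cols(
      tibble::tibble(position = p, n = length(covered)),
      tibble::as_tibble(stats::setNames(
        as.list(as.numeric(tab) / length(covered)), NUC))
    )
  })
}

#' Top-k most abundant miRNA families per stage
#'
#' @param expression Long tibble with `family`, `library` and `rpm` (or
#'   `expression`) columns — e.g. family-summed RPM from
#'   [quantify_mirnas()] joined with [seed_family()].
#' @param k Families per stage (default 5); `k = 0` gives an empty result,
#'   `k` above the family count returns all families.
#' @return Tibble with `library`, `rank`, `family`, `value`, ranked by
#'   descending value with stable ties broken by family id.
#' @export
top_families <- function(expression, k = 5) {
  x <- tibble::as_tibble(expression)
  val <- if ("rpm" %in% names(x)) "rpm" else "expression"
  x$value <- x[[val]]
  x |>
    dplyr::group_by(.data$library) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$family, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("library", "rank", "family", "value")
}

#' Sum member expression into family expression
#'
#' @param mirna_expression Long tibble `name`, `library`, `expression` (per
#'   mature miRNA / precursor arm).
#' @param membership Tibble `id`, `family` mapping members to families.
#' @return Long tibble `family`, `library`, `expression` (summed over
#'   members).
#' @export
family_expression <- function(mirna_expression, membership) {
  tibble::as_tibble(mirna_expression) |>
    dplyr::inner_join(dplyr::rename(membership, name = "id"), by = "name") |>
    dplyr::group_by(.data$family, .data$library) |>
    dplyr::summarise(expression = sum(.data$expression), .groups = "drop")
}

#' Filter novel miRNA candidates with the hairpin classifier
#'
#' Each candidate precursor is scored by the trained SVM on its 65
#' sequence/structure features; candidates scoring at least `cutoff`
#' (default 0.8, inclusive) are accepted. Rows whose structure fails to
#' parse or whose sequence/structure lengths disagree are skipped with a
#' reason. The audit table of rejected/skipped candidates (with scores) is
#' attached as attribute `"audit"`.
#'
#' @param candidates Tibble with `id`, `precursor_seq`, `structure`, `mfe`
#'   (and any further columns, e.g. mature arm coordinates and per-stage
#'   counts, which are carried through).
#' @param model A `hairpin_model` from [train_hairpin_svm()].
#' @param cutoff Acceptance score (default 0.8).
#' @return The accepted candidates with a `score` column, in descending
#'   score order.
#' @export
filter_novel <- function(candidates, model, cutoff = 0.8) {
  x <- tibble::as_tibble(candidates)
  need <- c("id", "precursor_seq", "structure", "mfe")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("candidate table missing: ", paste(miss, collapse = ", "))
  ok <- purrr::map_chr(seq_len(nrow(x)), function(i) {
    if (nchar(x$precursor_seq[i]) != nchar(x$structure[i])) {
      return("length mismatch")
    }
    tryCatch({
      parse_dot_bracket(x$structure[i])
      NA_character_
    }, error = function(e) conditionMessage(e))
  })
  skipped <- x[!is.na(ok), , drop = FALSE]
  if (nrow(skipped)) skipped$skip_reason <- ok[!is.na(ok)]
  x <- x[is.na(ok), , drop = FALSE]
  if (nrow(x)) {
    fv <- hairpin_features(tibble::tibble(
      id = x$id, sequence = x$precursor_seq,
      structure = x$structure, mfe = x$mfe
    ))
    x$score <- predict_score(model, fv)
  } else {
    x$score <- numeric(0)
  }
  accepted <- dplyr::arrange(x[x$score >= cutoff, , drop = FALSE],
                             dplyr::desc(.data$score))
  audit <- dplyr::arrange(x[x$score < cutoff, , drop = FALSE],
                          dplyr::desc(.data$score))
  attr(accepted, "audit") <- list(rejected = audit, skipped = skipped)
  accepted
}
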