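#' Fisher-style F-score of one feature for a two-class sample
#'
#' F = ((m+ - m)^2 + (m- - m)^2) / (s+^2 + s-^2), where m is the overall
#' mean, m+/m- the class means and s+^2/s-^2 the unbiased within-class
#' variances. Larger F means better class discrimination. When both
#' within-class variances are zero, F is `Inf` if the class means differ and
#' 0 otherwise.
#'
#' @param x Numeric vector of feature values.
#' @param label Class labels, coercible to +1/-1 (see [as_pm1()]).
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' fscore(c(2, 0, -2, 0), c(1, 1, -1, -1)) # 0.5
#' @export
fscore <- function(x, label) {
  y <- as_pm1(label)
  xp <- x[y == 1]
  xn <- x[y == -1]
  if (length(xp) < 2L || length(xn) < 2L) {
    stop("fscore needs at least two samples in each class")
  }
  m <- mean(x)
  num <- (mean(xp) - m)^2 + (mean(xn) - m)^2
  den <- stats::var(xp) + stats::var(xn)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' Coerce labels to +1 / -1
#'
#' Accepts numeric +1/-1, 0/1, logicals, or a two-level factor/character
#' (first sorted level = -1).
#'
#' @param label Label vector.
#' @return Integer vector of +1/-1.
#' @export
as_pm1 <- function(label) {
  if (is.logical(label)) return(ifelse(label, 1L, -1L))
  if (is.numeric(label)) {
    u <- sort(unique(label))
    if (all(u %in% c(-1, 1))) return(as.integer(label))
    if (all(u %in% c(0, 1))) return(ifelse(label == 1, 1L, -1L))
    stop("numeric labels must be in {-1,+1} or {0,1}")
  }
  f <- factor(label)
  if (nlevels(f) != 2L) stop("labels must have exactly two levels")
  ifelse(f == levels(f)[2], 1L, -1L)
}

#' The default feature-set catalogue
#'
#' Features are grouped into sets for selection: one set of the 16
#' dinucleotide percentages, one set of the 32 triplet elements, and each
#' remaining scalar as a singleton set (19 sets over the 65 implemented
#' features). A further multi-stem-specific feature block used by earlier
#' single/multi-stem predictors is excluded from the shipped catalogue on
#' account of its poor discrimination for mixed training sets.
#'
#' @return A tibble with `set_id`, `set_name` and list-column `features`.
#' @export
feature_set_catalog <- function() {
  fn <- feature_names()
  dinuc <- fn[startsWith(fn, "pct_") & fn != "pct_GC_content"]
  trip <- fn[grepl("[.(]", fn, fixed = FALSE)]
  singles <- setdiff(fn, c(dinuc, trip))
  sets <- c(list(dinucleotides = dinuc, triplet_elements = trip),
            stats::setNames(as.list(singles), singles))
  tibble::tibble(
    set_id = seq_along(sets),
    set_name = names(sets),
    features = unname(sets)
  )
}

#' Rank feature sets by mean F-score and keep the top k
#'
#' Singleton sets are scored directly; multi-feature sets by the mean of
#' their members' F-scores.
#'
#' @param features Feature tibble (`id` column optional, feature columns
#'   numeric).
#' @param label Class labels (+1/-1 coercible), one per row.
#' @param catalog Feature-set catalogue (default [feature_set_catalog()]);
#'   must cover only columns present in `features`, with no empty set.
#' @param k Number of top sets to keep (default 19).
#' @return A tibble of the top-`k` sets in descending mean-F order:
#'   `rank`, `set_id`, `set_name`, `n_features`, `mean_fscore`, plus the
#'   list-column `features`. The attribute `"per_feature"` carries the
#'   per-feature F-scores.
#' @export
rank_feature_sets <- function(features, label, catalog = feature_set_catalog(),
                              k = 19) {
  x <- dplyr::select(tibble::as_tibble(features),
                     -dplyr::any_of(c("id", "label")))
  if (any(lengths(catalog$features) == 0L)) stop("catalog contains an empty set")
  members <- unlist(catalog$features)
  miss <- setdiff(members, names(x))
  if (length(miss)) stop("catalog names absent from matrix: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  fs <- vapply(members, function(f) fscore(x[[f]], label), numeric(1))
  ranked <- catalog |>
    dplyr::mutate(
      n_features = lengths(.data$features),
      mean_fscore = vapply(.data$features,
                           function(m) mean(fs[m]), numeric(1))
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_fscore), .data$set_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
  out <- utils::head(ranked, k)
  attr(out, "per_feature") <- tibble::tibble(feature = names(fs), fscore = unname(fs))
  out
}

#' Features selected by the top-ranked sets
#'
#' @param ranked Output of [rank_feature_sets()].
#' @return Character vector of feature names, in catalogue order.
#' @export
selected_features <- function(ranked) {
  sel <- unlist(ranked$features)
  intersect(feature_names(), sel)
}
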