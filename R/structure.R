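#' Parse a dot-bracket secondary structure into a pair table
#'
#' Stack-based parsing of Vienna dot-bracket notation. Matched parentheses
#' are base pairs, dots are unpaired nucleotides. Pseudoknots (and hence any
#' bracket other than `(` and `)`) are rejected.
#'
#' @param structure A single dot-bracket string over `(`, `)`, `.`.
#' @return An object of class `pair_table`: a list with `pairs` (integer
#'   vector, 1-based partner position or `0L` if unpaired), `n_paired`,
#'   `n_unpaired`, `n_basepairs` and the original `structure` string.
#' @examples
#' pt <- parse_dot_bracket("((((...))))")
#' pt$n_basepairs
#' @export
parse_dot_bracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L, !is.na(structure))
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("invalid structure character '", chars[bad[1]], "' at position ", bad[1])
  }
  n <- length(chars)
  pairs <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced structure: unmatched ')' at position ", i)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced structure: unmatched '(' at position ", stack[length(stack)])
  }
  n_paired <- sum(pairs > 0L)
  structure(
    list(
      pairs = pairs,
      n_paired = n_paired,
      n_unpaired = n - n_paired,
      n_basepairs = n_paired %/% 2L,
      structure = structure
    ),
    class = "pair_table"
  )
}

#' @export
print.pair_table <- function(x, ...) {
  cat("<pair_table> L=", length(x$pairs), " basepairs=", x$n_basepairs,
      " unpaired=", x$n_unpaired, "\n", sep = "")
  invisible(x)
}

#' Rebuild the dot-bracket string from a pair table
#'
#' @param pt A `pair_table` from [parse_dot_bracket()].
#' @return The dot-bracket string.
#' @export
pair_table_to_dot_bracket <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  p <- pt$pairs
  out <- rep(".", length(p))
  out[p > seq_along(p)] <- "("
  out[p > 0L & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

#' Decompose a pair table into stems, hairpin loops and bulges
#'
#' A stem is a maximal run of stacked pairs (i,j), (i+1,j-1), ...; a hairpin
#' loop is an unpaired region closed directly by a single pair; a bulge is a
#' maximal internal unpaired region that is neither a hairpin loop nor part of
#' the exterior (dangling) ends. The two unpaired strands of an interior loop
#' count as one bulge whose size is their total length; in a multibranch loop
#' each unpaired gap counts as one bulge. Exterior unpaired nucleotides are
#' neither loops nor bulges.
#'
#' @param pt A `pair_table`.
#' @return An object of class `structure_elements`: list with `n_stems`,
#'   `n_hairpin_loops`, `n_bulges`, `largest_bulge`, `bulge_sizes`,
#'   `n_exterior`, `n_hairpin_loop_nt`, `mcpn` and `multi_stem` (TRUE when
#'   more than one hairpin loop is present).
#' @examples
#' decompose_structure(parse_dot_bracket("((..((...))..))"))
#' @export
decompose_structure <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  p <- pt$pairs
  n <- length(p)

  empty <- structure(
    list(n_stems = 0L, n_hairpin_loops = 0L, n_bulges = 0L,
         largest_bulge = 0L, bulge_sizes = integer(0),
         n_exterior = pt$n_unpaired, n_hairpin_loop_nt = 0L,
         mcpn = 0L, multi_stem = FALSE),
    class = "structure_elements"
  )
  if (pt$n_basepairs == 0L) return(empty)

  # stems: opening pair (i, p[i]) with i < p[i] starts a stem unless stacked
  # on (i-1, p[i]+1)
  opens <- which(p > seq_len(n))
  starts_stem <- vapply(opens, function(i) {
    !(i > 1L && p[i - 1L] == p[i] + 1L)
  }, logical(1))
  n_stems <- sum(starts_stem)

  # recursive loop decomposition over the pairing tree
  n_hairpin <- 0L
  hairpin_nt <- 0L
  bulge_sizes <- integer(0)

  # children of the interval (i+1 .. j-1): direct unpaired runs and helices
  walk <- function(i, j) {
    # i..j paired to each other (or 0,n+1 sentinel for exterior)
    k <- i + 1L
    gaps <- integer(0)
    gap <- 0L
    children <- list()
    while (k <= j - 1L) {
      if (p[k] == 0L) {
        gap <- gap + 1L
        k <- k + 1L
      } else {
        gaps <- c(gaps, gap)
        gap <- 0L
        children[[length(children) + 1L]] <- c(k, p[k])
        k <- p[k] + 1L
      }
    }
    gaps <- c(gaps, gap)
    list(gaps = gaps, children = children)
  }

  visit <- function(i, j, exterior) {
    w <- walk(i, j)
    nchild <- length(w$children)
    if (exterior) {
      # exterior gaps are dangling ends / linkers: not bulges
    } else if (nchild == 0L) {
      n_hairpin <<- n_hairpin + 1L
      hairpin_nt <<- hairpin_nt + sum(w$gaps)
    } else if (nchild == 1L) {
      tot <- sum(w$gaps)           # interior loop / bulge: one region
      if (tot > 0L) bulge_sizes <<- c(bulge_sizes, tot)
    } else {
      nz <- w$gaps[w$gaps > 0L]    # multibranch: each gap separately
      bulge_sizes <<- c(bulge_sizes, nz)
    }
    for (ch in w$children) {
      # descend through the helix to its innermost pair, then recurse
      a <- ch[1]; b <- ch[2]
      while (a + 1L <= n && p[a + 1L] == b - 1L) {
        a <- a + 1L; b <- b - 1L
      }
      visit(a, b, exterior = FALSE)
    }
  }
  visit(0L, n + 1L, exterior = TRUE)

  n_exterior <- pt$n_unpaired - hairpin_nt - sum(bulge_sizes)
  structure(
    list(
      n_stems = as.integer(n_stems),
      n_hairpin_loops = n_hairpin,
      n_bulges = length(bulge_sizes),
      largest_bulge = if (length(bulge_sizes)) max(bulge_sizes) else 0L,
      bulge_sizes = bulge_sizes,
      n_exterior = as.integer(n_exterior),
      n_hairpin_loop_nt = hairpin_nt,
      mcpn = max_consecutive_paired(pt$structure),
      multi_stem = n_hairpin > 1L
    ),
    class = "structure_elements"
  )
}

#' @export
print.structure_elements <- function(x, ...) {
  cat("<structure_elements> stems=", x$n_stems, " hairpin_loops=",
      x$n_hairpin_loops, " bulges=", x$n_bulges, " largest_bulge=",
      x$largest_bulge, " mcpn=", x$mcpn, "\n", sep = "")
  invisible(x)
}

#' Maximum number of consecutive paired nucleotides
#'
#' Length of the longest run of positions whose dot-bracket character is
#' `(` or `)`.
#'
#' @param structure A dot-bracket string.
#' @return Integer count (0 for a fully unpaired structure).
#' @export
max_consecutive_paired <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  runs <- strsplit(gsub("[()]", "|", structure), ".", fixed = TRUE)[[1]]
  if (length(runs) == 0L) return(0L)
  max(c(0L, nchar(runs)))
}

#' Validate a table of hairpin records
#'
#' Checks the invariants of a hairpin record table: sequence over
#' A/C/G/U (T is accepted and treated as U), structure of equal length and
#' parseable, MFE non-positive.
#'
#' @param hairpins A data frame with columns `id`, `sequence`, `structure`,
#'   `mfe`.
#' @return The input as a tibble, invisibly errors on violation.
#' @export
validate_hairpins <- function(hairpins) {
  h <- tibble::as_tibble(hairpins)
  need <- c("id", "sequence", "structure", "mfe")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("missing hairpin columns: ", paste(miss, collapse = ", "))
  if (any(nchar(h$sequence) != nchar(h$structure))) {
    stop("sequence/structure length mismatch for: ",
         paste(utils::head(h$id[nchar(h$sequence) != nchar(h$structure)], 3),
               collapse = ", "))
  }
  if (any(grepl("[^ACGUTacgut]", h$sequence))) {
    stop("sequences must be over A/C/G/U")
  }
  purrr::walk(h$structure, parse_dot_bracket)
  h
}

norm_rna <- function(x) chartr("Tt", "Uu", toupper(x))
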