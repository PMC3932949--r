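# exhaustive O(n^2) oracle: a cluster is a maximal contiguous run of sorted
# unique loci whose adjacent gaps (next start - previous end) are all < max_gap
oracle_clusters <- function(loci, min_loci = 10, max_gap = 1000) {
  u <- unique(loci[c("chrom", "start", "end", "strand")])
  out <- list()
  for (ch in unique(u$chrom)) {
    d <- u[u$chrom == ch, ]
    d <- d[order(d$start, d$end, d$strand), ]
    n <- nrow(d)
    gap_ok <- function(i) d$start[i + 1] - d$end[i] < max_gap
    for (i in seq_len(n)) {
      for (j in i:n) {
        run_ok <- j == i || all(vapply(i:(j - 1), gap_ok, logical(1)))
        left_max <- i == 1 || !gap_ok(i - 1)
        right_max <- j == n || !gap_ok(j)
        if (run_ok && left_max && right_max && (j - i + 1) >= min_loci) {
          out[[length(out) + 1L]] <- tibble::tibble(
            chrom = ch, start = min(d$start[i:j]), end = max(d$end[i:j]),
            n_unique_loci = j - i + 1L)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_unique_loci = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

mk_loci <- function(starts, width = 28, chrom = "chr1", strand = "+") {
  tibble::tibble(chrom = chrom, start = starts, end = starts + width,
                 strand = strand,
                 name = paste0("L", seq_along(starts)))
}

test_that("cluster calling satisfies the definition on worked examples", {
  # 10 loci of width 28 spaced 500 bp apart: one cluster of 10
  c1 <- cluster_pirna_loci(mk_loci(seq(0, by = 500, length.out = 10)))
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$n_unique_loci, 10L)
  expect_equal(c1$n_plus, 10L)

  # 9 such loci: none
  expect_equal(nrow(cluster_pirna_loci(mk_loci(seq(0, by = 500,
                                                   length.out = 9)))), 0L)

  # 12 loci with a gap of exactly 1000 bp after the 6th: split into two
  # runs of 6, neither reaching 10 ("less than 1 kb" is strict)
  starts <- c(seq(0, by = 300, length.out = 6),
              seq(5 * 300 + 28 + 1000, by = 300, length.out = 6))
  expect_equal(nrow(cluster_pirna_loci(mk_loci(starts))), 0L)
  # the same layout with a 999-bp gap merges into one cluster of 12
  starts2 <- c(seq(0, by = 300, length.out = 6),
               seq(5 * 300 + 28 + 999, by = 300, length.out = 6))
  c2 <- cluster_pirna_loci(mk_loci(starts2))
  expect_equal(c2$n_unique_loci, 12L)
})

test_that("cluster calling equals the exhaustive oracle on random loci", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    loci <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample(0:30000, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
    loci$end <- loci$start + sample(26:30, n, replace = TRUE)
    min_loci <- sample(2:10, 1)
    got <- cluster_pirna_loci(loci, min_loci = min_loci)
    want <- oracle_clusters(loci, min_loci = min_loci)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_unique_loci, want$n_unique_loci)
  }
})

test_that("clustering is order-invariant, duplicate-safe and idempotent", {
  set.seed(23)
  loci <- mk_loci(sort(sample(0:20000, 40)))
  shuffled <- loci[sample(nrow(loci)), ]
  a <- cluster_pirna_loci(loci, min_loci = 3)
  b <- cluster_pirna_loci(shuffled, min_loci = 3)
  expect_equal(a[names(a) != "cluster_id"], b[names(b) != "cluster_id"])
  # read-count duplicates of the same locus do not inflate unique counts
  dup <- dplyr::bind_rows(loci, loci[rep(1, 5), ])
  expect_equal(cluster_pirna_loci(dup, min_loci = 3)$n_unique_loci,
               a$n_unique_loci)
})

test_that("per-strand mode clusters each strand separately", {
  starts <- seq(0, by = 400, length.out = 20)
  loci <- mk_loci(starts, strand = rep(c("+", "-"), 10))
  both <- cluster_pirna_loci(loci, min_loci = 10)
  expect_equal(nrow(both), 1L)
  expect_equal(both$n_plus, 10L)
  expect_equal(both$n_minus, 10L)
  per <- cluster_pirna_loci(loci, min_loci = 10, per_strand = TRUE)
  expect_equal(nrow(per), 2L)  # 800-bp same-strand gaps still < 1 kb
})

test_that("piRNA length histograms and 5' logos summarise sequence sets", {
  x <- tibble::tibble(sequence = rep(strrep("ACGU", 7), 5))
  h <- pirna_length_histogram(x)
  expect_equal(h$length, 28L)
  expect_equal(h$prop, 1)

  by_src <- tibble::tibble(
    sequence = c(rep(strrep("A", 28), 3), rep(strrep("C", 26), 2)),
    source = c(rep("repeat_associated", 3), rep("non_repeat_associated", 2))
  )
  h2 <- pirna_length_histogram(by_src)
  expect_equal(sum(h2$prop[h2$source == "repeat_associated"]), 1)

  lg <- five_prime_logo_matrix(rep(paste0("U", strrep("ACGU", 5)), 10), k = 15)
  expect_equal(lg$U[1], 1)
  expect_equal(unname(rowSums(lg[, c("A", "C", "G", "U")])), rep(1, 15))
  # short sequences are dropped and reported; all-short input errors
  lg2 <- five_prime_logo_matrix(c(strrep("A", 20), "ACGU"), k = 15)
  expect_equal(attr(lg2, "n_dropped"), 1L)
  expect_error(five_prime_logo_matrix("ACGU", k = 15), "length >= 15")

  # near-uniform random composition recovers ~0.25 everywhere
  set.seed(5)
  rnd <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE), collapse = "")
  }, character(1))
  lg3 <- five_prime_logo_matrix(rnd, k = 15)
  expect_true(all(abs(as.matrix(lg3[, c("A", "C", "G", "U")]) - 0.25) < 0.05))
})
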