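mini_refs <- function() {
  repB <- "CCAUGGAUCCGGAAUUCCUGCAGGCAUGCAAGCUUGAGUA"
  list(
    mirna = tibble::tibble(id = "mir1",
                           sequence = "UGAGGUAGUAGGUUGUAUAGUUAGCCUAAC"),
    rfam = tibble::tibble(id = "rf1", class = "rRNA",
                          sequence = "GCCUACGGCCAUACCACCCUGAACGCGCCCGAUCUCGUCU"),
    repeats = tibble::tibble(
      id = c("repA", "repB", "repC"),
      class = c("tRNA", "LINE", "LINE"),
      sequence = c("GCGGAUUUAGCUCAGUUGGGAGAGCGCCAGACUGAA",
                   repB,
                   "AUCGAUAGGCCUAGGCAUAAGCUAGCAUCGGAUCGAUCAA")
    ),
    mrna = tibble::tibble(id = "m1",
                          sequence = "AUGGCCAUUGUAAUGGGCCGCUGAAAGGGUGCCCGAUAGC"),
    pirna = tibble::tibble(id = c("p1", "p2"),
                           sequence = c(substr(repB, 4, 29),
                                        "UAAGGUUACAAGGCAGUGUAGCUUAGGCUU"))
  )
}

tag_tbl <- function(seqs, counts) {
  tibble::tibble(tag_id = paste0("t", seq_along(seqs)), sequence = seqs,
                 lib1 = counts)
}

test_that("preprocessing applies length and abundance filters inclusively", {
  tags <- tibble::tibble(
    tag_id = paste0("t", 1:5),
    sequence = c(strrep("A", 17), strrep("C", 18), strrep("G", 35),
                 strrep("U", 36), strrep("A", 22)),
    lib1 = c(50, 3, 3, 50, 2),
    lib2 = c(50, 0, 1, 50, 2)
  )
  kept <- preprocess_tags(tags)
  expect_equal(kept$tag_id, c("t2", "t3"))  # boundaries 18 and 35 retained
  qc <- attr(kept, "qc")
  expect_equal(qc$tags, c(5L, 2L, 1L, 2L))
  expect_equal(qc$reads[1], sum(tags$lib1) + sum(tags$lib2))
  # empty input: empty output with a report
  empty <- preprocess_tags(tags[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "qc")$tags, c(0L, 0L, 0L, 0L))
})

test_that("tag matching finds 0- and 1-mismatch hits on both strands", {
  probe <- "GCUUAGGCAUCGAUCGG"
  ref <- tibble::tibble(id = "r",
                        sequence = paste0("AAAAA", probe, "AAAAA"))
  exact <- match_tags(tag_tbl(probe, 1), ref)
  plus <- exact[exact$strand == "+" & exact$mismatches == 0, ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 5L)
  expect_equal(plus$end, 5L + nchar(probe))

  onemm <- match_tags(tag_tbl("GCUUAGGAAUCGAUCGG", 1), ref)
  expect_equal(min(onemm$mismatches), 1L)
  expect_equal(nrow(match_tags(tag_tbl("GCUUAGGAAUCUAUCGG", 1), ref)), 0L)
  # reverse-complement hit reported on forward coordinates
  rc <- match_tags(tag_tbl("CCGAUCGAUGCCUAAGC", 1), ref)
  expect_true(any(rc$strand == "-" & rc$mismatches == 0))
  expect_equal(rc$start[rc$strand == "-" & rc$mismatches == 0], 5L)
  # mismatch budget configurable
  expect_equal(nrow(match_tags(tag_tbl("GCUUAGGAAUCGAUCGG", 1), ref,
                               max_mismatch = 0, both_strands = FALSE)), 0L)
})

test_that("hierarchical annotation follows the priority order with recall and rescue", {
  refs <- mini_refs()
  t1 <- substr(refs$mirna$sequence, 2, 23)
  # plant the miRNA tag inside a repeat too: priority must still say miRNA
  refs$repeats$sequence[2] <- paste0(refs$repeats$sequence[2], t1)
  tags <- tag_tbl(
    c(t1,
      substr(refs$rfam$sequence, 3, 24),          # rRNA via Rfam
      substr(refs$repeats$sequence[1], 5, 26),    # repeat classed tRNA -> recall
      refs$pirna$sequence[1],                     # in repB and piRNA bank -> rescue
      substr(refs$repeats$sequence[3], 4, 27),    # plain repeat
      substr(refs$mrna$sequence, 6, 27),          # mRNA
      refs$pirna$sequence[2],                     # piRNA direct
      strrep("ACU", 8)),                          # unclassified
    counts = rep(10, 8)
  )
  ann <- hierarchical_annotate(tags, refs)
  expect_equal(nrow(ann), nrow(tags))
  got <- ann$category[match(paste0("t", 1:8), ann$tag_id)]
  expect_equal(got, c("miRNA", "rRNA", "tRNA", "piRNA", "repeat", "mRNA",
                      "piRNA", "unclassified"))
  expect_true(ann$recalled_ncRNA[ann$tag_id == "t3"])
  expect_true(ann$repeat_associated_piRNA[ann$tag_id == "t4"])
  expect_false(ann$repeat_associated_piRNA[ann$tag_id == "t7"])

  # conservation: every tag appears exactly once
  expect_equal(sum(table(ann$category)), nrow(tags))

  # priority property: removing the miRNA reference moves tags downstream only
  ann2 <- hierarchical_annotate(tags, c(refs[-1], list(mirna = NULL)))
  for (cat in c("rRNA", "tRNA", "repeat", "mRNA", "piRNA", "unclassified")) {
    expect_gte(sum(ann2$category == cat), sum(ann$category == cat))
  }
  expect_equal(sum(ann2$category == "miRNA"), 0L)
})

test_that("fractional counts split multi-mapped tags and conserve totals", {
  probe <- "GCUUAGGCAUCGAUCGGAUACCA"
  genome <- tibble::tibble(
    id = "chr1",
    sequence = paste0(strrep("A", 30), probe, strrep("C", 30), probe,
                      strrep("G", 30))
  )
  tags <- tag_tbl(probe, 9)
  hits <- match_tags(tags, genome, max_mismatch = 0, both_strands = FALSE)
  expect_equal(nrow(hits), 2L)
  fr <- fractional_counts(tags, hits)
  expect_equal(fr$n_positions, c(2L, 2L))
  expect_equal(sum(fr$lib1), 9)     # exact conservation
  expect_equal(fr$lib1, c(4.5, 4.5))
})

test_that("isomiR windows group reads -2/+5 around the precursor", {
  pre <- tibble::tibble(name = "pre1", chrom = "chr1", start = 100, end = 180,
                        strand = "+")
  hits <- tibble::tibble(
    tag_id = c("a", "b", "c", "d"),
    ref_id = "chr1",
    start = c(98, 97, 100, 101), end = c(120, 120, 122, 123),
    strand = "+", mismatches = 0L,
    lib1 = c(120, 999, 30, 7)
  )
  q <- quantify_mirnas(hits, pre)
  expect_equal(nrow(q), 1L)
  expect_equal(q$expression, 120)       # [98,120) in; [97,120) out
  expect_equal(q$n_isomirs, 3L)
  expect_equal(q$total_reads, 120 + 30 + 7)
  # minus-strand precursor: the 5-nt tolerance moves to the start side
  pre_m <- dplyr::mutate(pre, strand = "-")
  hits_m <- dplyr::mutate(hits, start = c(95, 94, 160, 150),
                          end = c(117, 116, 182, 172))
  q_m <- quantify_mirnas(hits_m, pre_m)
  expect_equal(q_m$n_isomirs, 3L)       # [94,116) starts before start-5 -> out
})

test_that("RPM normalisation rescales by library totals", {
  x <- tibble::tibble(tag_id = "t", sequence = "A", lib1 = 5, lib2 = 0)
  r <- rpm_normalize(x, c(lib1 = 2e6, lib2 = 1e6))
  expect_equal(r$lib1, 2.5)
  expect_equal(r$lib2, 0)
  expect_error(rpm_normalize(x, c(lib1 = 0, lib2 = 1)), "> 0")
  big <- tibble::tibble(tag_id = paste0("t", 1:100), sequence = "A",
                        lib1 = runif(100, 1, 50))
  rb <- rpm_normalize(big, c(lib1 = sum(big$lib1)))
  expect_equal(sum(rb$lib1), 1e6)
})

test_that("length-by-category summaries report per-library proportions", {
  ann <- tibble::tibble(
    tag_id = paste0("t", 1:4), sequence = "x",
    length = c(22L, 22L, 28L, 28L),
    category = c("miRNA", "miRNA", "piRNA", "piRNA"),
    lib1 = c(10, 5, 30, 15), lib2 = c(1, 2, 3, 4)
  )
  sm <- length_category_summary(ann)
  per_lib <- tapply(sm$prop_reads, sm$library, sum)
  expect_equal(unname(per_lib), c(1, 1), ignore_attr = TRUE)
  mi <- sm[sm$library == "lib1" & sm$category == "miRNA", ]
  expect_equal(mi$reads, 15)
  expect_equal(mi$unique_tags, 2L)
})
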