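# brute-force region-labelling oracle for structure decomposition:
# flat scan over maximal unpaired runs + pairwise interior-loop merging,
# algorithmically unrelated to the recursive tree walk in the package
oracle_decompose <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  p <- integer(n); stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") { p[i] <- stack[length(stack)]
                           p[stack[length(stack)]] <- i
                           stack <- stack[-length(stack)] }
  }
  opens <- which(p > seq_len(n))
  n_stems <- sum(vapply(opens, function(i)
    !(i > 1 && p[i - 1] == p[i] + 1), logical(1)))
  # hairpin-loop closing pairs: interior entirely unpaired (possibly empty)
  hp <- vapply(opens, function(i) {
    j <- p[i]
    j == i + 1 || all(p[(i + 1):(j - 1)] == 0)
  }, logical(1))
  n_hairpin <- sum(hp)
  # maximal unpaired runs
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (p[i] == 0L) {
      j <- i
      while (j < n && p[j + 1L] == 0L) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  classify <- vapply(runs, function(r) {
    a <- r[1]; b <- r[2]
    if (a > 1 && b < n && p[a - 1] == b + 1) return("hairpin")
    enclosed <- any(vapply(opens, function(i) i < a && p[i] > b, logical(1)))
    if (!enclosed) "exterior" else "bulge"
  }, character(1))
  bulges <- runs[classify == "bulge"]
  sizes <- vapply(bulges, function(r) r[2] - r[1] + 1L, integer(1))
  # merge the two strands of an interior loop into one bulge
  if (length(bulges) >= 2L) {
    merged <- rep(FALSE, length(bulges))
    for (u in seq_along(bulges)) {
      for (v in seq_along(bulges)) {
        if (u == v || merged[u] || merged[v]) next
        a1 <- bulges[[u]][1]; b1 <- bulges[[u]][2]
        a2 <- bulges[[v]][1]; b2 <- bulges[[v]][2]
        if (a1 > 1 && b1 < n && a2 > 1 && b2 < n &&
            p[b1 + 1] == a2 - 1 && p[a1 - 1] == b2 + 1) {
          sizes[u] <- sizes[u] + sizes[v]
          merged[v] <- TRUE
        }
      }
    }
    sizes <- sizes[!merged]
  }
  list(n_stems = n_stems, n_hairpin_loops = n_hairpin,
       n_bulges = length(sizes),
       largest_bulge = if (length(sizes)) max(sizes) else 0L)
}

test_that("dot-bracket parsing builds the correct pair table", {
  pt <- parse_dot_bracket("((((...))))")
  expect_equal(pt$n_basepairs, 4L)
  expect_equal(pt$n_paired, 8L)
  expect_equal(pt$n_unpaired, 3L)
  expect_equal(pt$pairs[1:4], c(11L, 10L, 9L, 8L))
  expect_equal(pt$pairs[8:11], c(4L, 3L, 2L, 1L))

  pt0 <- parse_dot_bracket("......")
  expect_equal(pt0$n_basepairs, 0L)
  expect_equal(pt0$n_unpaired, 6L)
})

test_that("parsing rejects malformed structures with the offending position", {
  expect_error(parse_dot_bracket("(((..)"), "unbalanced")
  expect_error(parse_dot_bracket("...))"), "position 4")
  expect_error(parse_dot_bracket("((x))"), "position 3")
})

test_that("pair tables are involutions and round-trip to dot-bracket", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_structure(sample(1:60, 1))
    pt <- parse_dot_bracket(s)
    paired <- which(pt$pairs > 0L)
    expect_identical(pt$pairs[pt$pairs[paired]], paired)
    expect_false(any(pt$pairs[paired] == paired))
    expect_identical(pair_table_to_dot_bracket(pt), s)
    expect_equal(pt$n_paired + pt$n_unpaired, nchar(s))
  }
})

test_that("decomposition matches hand-traced examples", {
  el <- decompose_structure(parse_dot_bracket("((..((...))..))"))
  expect_equal(el$n_stems, 2L)
  expect_equal(el$n_hairpin_loops, 1L)
  expect_equal(el$n_bulges, 1L)
  expect_equal(el$largest_bulge, 4L)
  expect_false(el$multi_stem)

  el2 <- decompose_structure(parse_dot_bracket("((((...))))"))
  expect_equal(el2$n_stems, 1L)
  expect_equal(el2$n_hairpin_loops, 1L)
  expect_equal(el2$n_bulges, 0L)
  expect_equal(el2$largest_bulge, 0L)

  el3 <- decompose_structure(parse_dot_bracket("...."))
  expect_equal(el3$n_stems, 0L)
  expect_equal(el3$n_hairpin_loops, 0L)
  expect_equal(el3$n_bulges, 0L)
  expect_equal(el3$n_exterior, 4L)

  # two stem-loops joined by a linker: multi-stem, exterior linker not a bulge
  el4 <- decompose_structure(parse_dot_bracket("((...))..((...))"))
  expect_equal(el4$n_hairpin_loops, 2L)
  expect_true(el4$multi_stem)
  expect_equal(el4$n_bulges, 0L)

  # multibranch loop: each gap is its own bulge
  el5 <- decompose_structure(parse_dot_bracket("((.((...)).((...)).))"))
  expect_equal(el5$n_hairpin_loops, 2L)
  expect_equal(el5$n_stems, 3L)
  expect_equal(el5$n_bulges, 3L)
})

test_that("unpaired nucleotides partition into loops, bulges and exterior", {
  set.seed(7)
  for (i in 1:200) {
    s <- random_structure(sample(4:50, 1))
    pt <- parse_dot_bracket(s)
    el <- decompose_structure(pt)
    expect_equal(sum(el$bulge_sizes) + el$n_hairpin_loop_nt + el$n_exterior,
                 pt$n_unpaired)
    expect_gte(el$n_stems, el$n_hairpin_loops)
    expect_lte(el$mcpn, pt$n_paired)
  }
})

test_that("decomposition agrees with the region-labelling oracle exhaustively", {
  for (n in 0:12) {
    for (s in enumerate_structures(n)) {
      got <- decompose_structure(parse_dot_bracket(s))
      want <- oracle_decompose(s)
      expect_identical(
        list(got$n_stems, got$n_hairpin_loops, got$n_bulges,
             as.integer(got$largest_bulge)),
        list(as.integer(want$n_stems), as.integer(want$n_hairpin_loops),
             as.integer(want$n_bulges), as.integer(want$largest_bulge)),
        label = paste0("structure '", s, "'")
      )
    }
  }
})

test_that("maximum consecutive paired nucleotides counts bracket runs", {
  expect_equal(max_consecutive_paired("((((...))))"), 4L)
  expect_equal(max_consecutive_paired("((.((((...))))))"), 6L)
  expect_equal(max_consecutive_paired("......"), 0L)
  expect_equal(max_consecutive_paired(""), 0L)
})
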