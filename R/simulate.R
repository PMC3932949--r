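revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", norm_rna(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rand_seq <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(NUC, n, replace = TRUE, prob = prob), collapse = "")
}

#' Synthesise one stem-loop (or two-stem) hairpin with its structure
#'
#' Positive-class precursors for testing: an arm, a terminal loop, the
#' reverse complement of the arm, and short dangling ends, folding by
#' construction into a single stem of at least `arm` base pairs. With
#' `multi = TRUE` two such stem-loops are joined by a linker (two hairpin
#' loops). The free energy is assigned from a pairing-dependent linear model
#' with noise rather than thermodynamic folding, so fixtures need no
#' external tool; see [fold_hairpins()] for real folding.
#'
#' @param arm Base pairs in each stem (single draw from the range).
#' @param loop Terminal-loop length range (nt).
#' @param dangle Dangling-end length range (nt).
#' @param multi Build a two-stem structure (default FALSE).
#' @return List with `sequence`, `structure`, `mfe`.
#' @export
synth_hairpin <- function(arm = c(25, 35), loop = c(6, 10), dangle = c(0, 3),
                          multi = FALSE) {
  one <- function() {
    a <- sample(arm[1]:arm[2], 1)
    l <- sample(loop[1]:loop[2], 1)
    arm1 <- rand_seq(a, prob = c(A = .2, C = .3, G = .3, U = .2))
    list(
      seq = paste0(arm1, rand_seq(l), revcomp_rna(arm1)),
      str = paste0(strrep("(", a), strrep(".", l), strrep(")", a)),
      bp = a
    )
  }
  d1 <- sample(dangle[1]:dangle[2], 1)
  d2 <- sample(dangle[1]:dangle[2], 1)
  if (multi) {
    s1 <- one(); s2 <- one()
    link <- sample(3:6, 1)
    seq <- paste0(rand_seq(d1), s1$seq, rand_seq(link), s2$seq, rand_seq(d2))
    str <- paste0(strrep(".", d1), s1$str, strrep(".", link), s2$str,
                  strrep(".", d2))
    bp <- s1$bp + s2$bp
  } else {
    s1 <- one()
    seq <- paste0(rand_seq(d1), s1$seq, rand_seq(d2))
    str <- paste0(strrep(".", d1), s1$str, strrep(".", d2))
    bp <- s1$bp
  }
  list(sequence = seq, structure = str,
       mfe = min(-5, -1.1 * bp + stats::rnorm(1, 0, 2)))
}

synth_nonhairpin <- function(len) {
  # composition-shuffled, sparsely paired decoy with a weak synthetic MFE
  k <- sample(3:8, 1)
  a <- sample(2:6, 1)
  b <- max(3L, len - 2L * k - a - sample(2:6, 1))
  c_ <- len - 2L * k - a - b
  if (c_ < 0L) { b <- b + c_; c_ <- 0L }
  list(
    sequence = rand_seq(len, prob = c(A = .3, C = .2, G = .2, U = .3)),
    structure = paste0(strrep(".", a), strrep("(", k), strrep(".", b),
                       strrep(")", k), strrep(".", c_)),
    mfe = min(0, -0.4 * k + stats::rnorm(1, 0, 1.5))
  )
}

#' Generate labelled hairpin training sets with known classes
#'
#' Positives are synthetic stem-loops (high pairing, low assigned MFE);
#' negatives are composition-shuffled sequences of matching lengths with
#' sparse pairing and near-zero MFE. The two classes are separated by
#' construction on many pairing and energy features; with `check = TRUE`
#' the generator verifies that at least 5 features differ by >= 2 pooled
#' standard deviations.
#'
#' @param n_pos,n_neg Class sizes (defaults 200/200).
#' @param seed Integer seed.
#' @param multi_frac Fraction of two-stem positives (default 0.055,
#'   mirroring the minority of multibranch precursors in real training
#'   sets).
#' @param check Verify feature-level class separation (default TRUE).
#' @return Tibble with `id`, `sequence`, `structure`, `mfe`,
#'   `label` (+1/-1) and `multi_stem`.
#' @export
simulate_hairpins <- function(n_pos = 200, n_neg = 200, seed = 1L,
                              multi_frac = 0.055, check = TRUE) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  set.seed(seed)
  n_multi <- round(multi_frac * n_pos)
  pos <- purrr::map(seq_len(n_pos), function(i) {
    synth_hairpin(multi = i <= n_multi)
  })
  pos_len <- vapply(pos, function(p) nchar(p$sequence), integer(1))
  neg <- purrr::map(seq_len(n_neg), function(i) {
    synth_nonhairpin(sample(pos_len, 1))
  })
  tbl <- function(x, label, prefix) {
    tibble::tibble(
      id = sprintf("%s_%03d", prefix, seq_along(x)),
      sequence = vapply(x, `[[`, character(1), "sequence"),
      structure = vapply(x, `[[`, character(1), "structure"),
      mfe = vapply(x, `[[`, numeric(1), "mfe"),
      label = label
    )
  }
  out <- dplyr::bind_rows(tbl(pos, 1L, "pos"), tbl(neg, -1L, "neg"))
  out$multi_stem <- vapply(out$structure, function(s) {
    decompose_structure(parse_dot_bracket(s))$multi_stem
  }, logical(1), USE.NAMES = FALSE)
  if (check) {
    fv <- hairpin_features(out)
    sep <- vapply(feature_names(), function(f) {
      xp <- fv[[f]][out$label == 1]; xn <- fv[[f]][out$label == -1]
      sd_p <- stats::sd(xp); sd_n <- stats::sd(xn)
      pooled <- sqrt((sd_p^2 + sd_n^2) / 2)
      if (pooled == 0) 0 else abs(mean(xp) - mean(xn)) / pooled
    }, numeric(1))
    if (sum(sep >= 2) < 5L) {
      stop("generator failed its separation contract (", sum(sep >= 2),
           " features at >= 2 SD)")
    }
  }
  out
}

#' Generate a random valid dot-bracket structure
#'
#' Uniform-ish random nested structure for property testing: a random
#' sequence of balanced bracket insertions and dots.
#'
#' @param n Structure length.
#' @return A valid dot-bracket string of length `n`.
#' @export
random_structure <- function(n) {
  out <- character(0)
  open <- 0L
  left <- n
  while (left > 0L) {
    can_open <- left - 1L >= open + 1L  # room to close everything later
    must_close <- left == open
    choice <- if (must_close) ")" else {
      opts <- c(".", if (can_open) "(", if (open > 0L) ")")
      sample(opts, 1)
    }
    out <- c(out, choice)
    if (choice == "(") open <- open + 1L
    if (choice == ")") open <- open - 1L
    left <- left - 1L
  }
  paste(out, collapse = "")
}

default_stage_props <- function(stages = 8) {
  pirna <- seq(0.80, 0.10, length.out = stages)
  fixed <- c(rRNA = 0.03, tRNA = 0.02, `snRNA/snoRNA` = 0.02,
             `repeat` = 0.03, mRNA = 0.03, unclassified = 0.02)
  t(vapply(seq_len(stages), function(s) {
    c(miRNA = 1 - pirna[s] - sum(fixed), piRNA = pirna[s], fixed)
  }, numeric(8)))
}

#' Simulate a complete small RNA-seq study with known ground truth
#'
#' Builds a toy genome with planted pre-miRNA stem-loops, piRNA clusters,
#' ncRNA genes, class-annotated repeats (some harbouring piRNAs), mRNAs and
#' intergenic space; then draws stage-wise tag libraries whose category
#' proportions follow a programmable piRNA-to-miRNA shift, with miRNA reads
#' emitted as isomiR variants (~22 nt) and piRNA reads at ~28 nt. Every tag
#' carries its true category in the truth table.
#'
#' @param seed Integer seed (byte-identical outputs per seed).
#' @param n_premirna Planted precursors (default 30).
#' @param n_pirna_clusters,loci_per_cluster,locus_spacing piRNA cluster
#'   layout (defaults 8 clusters of 12 loci, 300 bp start-to-start).
#' @param stages Number of stage libraries (default 8).
#' @param reads_per_stage Total reads per library (default 50000).
#' @param stage_props Stage-by-category proportion matrix (rows = stages,
#'   columns miRNA, piRNA, rRNA, tRNA, snRNA/snoRNA, repeat, mRNA,
#'   unclassified, each row summing to 1). Default: piRNA declining 0.80 to
#'   0.10 with miRNA absorbing the change.
#' @param mismatch_rate Fraction of tags carrying one planted substitution
#'   (default 0).
#' @return List with `genome`, `references` (list: mirna, rfam, repeats,
#'   mrna, pirna), `precursors` (loci with mature arms), `matures`,
#'   `pirna_loci`, `tags` (tag table with one count column per stage),
#'   `truth` (per-tag true category/origin), `stage_props` and `seed`.
#' @export
simulate_srna_study <- function(seed = 1L, n_premirna = 30,
                                n_pirna_clusters = 8, loci_per_cluster = 12,
                                locus_spacing = 300, stages = 8,
                                reads_per_stage = 50000,
                                stage_props = default_stage_props(stages),
                                mismatch_rate = 0) {
  set.seed(seed)
  stopifnot(nrow(stage_props) == stages,
            all(abs(rowSums(stage_props) - 1) < 1e-9))
  libs <- paste0("stage", seq_len(stages))

  pieces <- list()       # genome pieces in order
  feats <- list()        # planted feature coordinates
  pos <- 0L
  spacer <- function(lo = 400, hi = 1200) {
    n <- sample(lo:hi, 1)
    pieces[[length(pieces) + 1L]] <<- rand_seq(n)
    pos <<- pos + n
  }
  plant <- function(seqs, type, meta = NULL) {
    for (i in seq_along(seqs)) {
      spacer()
      start <- pos
      pieces[[length(pieces) + 1L]] <<- seqs[i]
      pos <<- pos + nchar(seqs[i])
      feats[[length(feats) + 1L]] <<- tibble::tibble(
        type = type, name = if (is.null(meta)) paste0(type, "_", i) else meta[i],
        start = start, end = pos, strand = "+"
      )
    }
  }

  # pre-miRNAs: arm + loop + revcomp(arm); mature = 5' arm, 22 nt
  pre <- purrr::map(seq_len(n_premirna), function(i) synth_hairpin())
  pre_names <- sprintf("pre_mir_%03d", seq_len(n_premirna))
  plant(vapply(pre, `[[`, character(1), "sequence"), "premirna", pre_names)

  # piRNA clusters: loci at fixed spacing, >= 2 kb between clusters
  pirna_seqs <- character(0); pirna_meta <- list()
  for (cl in seq_len(n_pirna_clusters)) {
    spacer(2200, 3000)
    for (j in seq_len(loci_per_cluster)) {
      w <- pmin(30L, pmax(26L, round(stats::rnorm(1, 28, 1))))
      s <- paste0(sample(c("U", "A", "C", "G"), 1, prob = c(.8, .1, .05, .05)),
                  rand_seq(w - 1L))
      start <- pos
      pieces[[length(pieces) + 1L]] <- s
      pos <- pos + w
      gap_to_next <- locus_spacing - w
      if (j < loci_per_cluster) {
        pieces[[length(pieces) + 1L]] <- rand_seq(gap_to_next)
        pos <- pos + gap_to_next
      }
      nm <- sprintf("pirna_c%02d_%02d", cl, j)
      feats[[length(feats) + 1L]] <- tibble::tibble(
        type = "pirna", name = nm, start = start, end = start + w,
        strand = sample(c("+", "-"), 1)
      )
      pirna_seqs <- c(pirna_seqs, s)
      names(pirna_seqs)[length(pirna_seqs)] <- nm
    }
  }

  # Rfam ncRNA genes (3 per class), repeats (3 ncRNA-classed, 3 with an
  # embedded piRNA, 6 plain), mRNAs
  rfam_classes <- rep(NCRNA_CLASSES, each = 3)
  rfam_seqs <- vapply(seq_along(rfam_classes), function(i) rand_seq(120),
                      character(1))
  plant(rfam_seqs, "rfam", sprintf("rfam_%02d", seq_along(rfam_seqs)))

  rep_class <- c("rRNA", "tRNA", "snRNA/snoRNA", rep("LTR", 3), rep("LINE", 6))
  embedded_idx <- 4:6   # the LTR repeats harbour a piRNA
  embedded <- vapply(seq_along(embedded_idx), function(i) {
    paste0("U", rand_seq(27))
  }, character(1))
  rep_seqs <- vapply(seq_along(rep_class), function(i) {
    body <- rand_seq(200)
    if (i %in% embedded_idx) {
      k <- which(embedded_idx == i)
      paste0(substr(body, 1, 80), embedded[k], substr(body, 109, 200))
    } else body
  }, character(1))
  plant(rep_seqs, "repeat", sprintf("repeat_%02d", seq_along(rep_seqs)))

  mrna_seqs <- vapply(seq_len(10), function(i) rand_seq(400), character(1))
  plant(mrna_seqs, "mrna", sprintf("mrna_%02d", seq_len(10)))
  spacer(3000, 4000)  # intergenic pool for unclassified reads
  inter_start <- pos - 3000L
  spacer()

  genome_seq <- paste(unlist(pieces), collapse = "")
  genome <- tibble::tibble(id = "chr1", sequence = genome_seq)
  feats <- dplyr::bind_rows(feats)

  pre_feats <- feats[feats$type == "premirna", ]
  precursors <- tibble::tibble(
    name = pre_feats$name, chrom = "chr1",
    start = pre_feats$start, end = pre_feats$end, strand = "+",
    sequence = vapply(pre, `[[`, character(1), "sequence"),
    structure = vapply(pre, `[[`, character(1), "structure"),
    mfe = vapply(pre, `[[`, numeric(1), "mfe")
  )
  matures <- tibble::tibble(
    id = sub("^pre_", "", pre_names),
    sequence = substr(precursors$sequence, 1, 22)
  )

  pirna_feats <- feats[feats$type == "pirna", ]
  pirna_loci <- tibble::tibble(
    name = pirna_feats$name, chrom = "chr1", start = pirna_feats$start,
    end = pirna_feats$end, strand = pirna_feats$strand,
    sequence = unname(pirna_seqs[pirna_feats$name]),
    source = "non_repeat_associated"
  )

  references <- list(
    mirna = tibble::tibble(id = pre_names, sequence = precursors$sequence),
    rfam = tibble::tibble(id = sprintf("rfam_%02d", seq_along(rfam_seqs)),
                          sequence = rfam_seqs, class = rfam_classes),
    repeats = tibble::tibble(id = sprintf("repeat_%02d", seq_along(rep_seqs)),
                             sequence = rep_seqs, class = rep_class),
    mrna = tibble::tibble(id = sprintf("mrna_%02d", seq_len(10)),
                          sequence = mrna_seqs),
    pirna = tibble::tibble(
      id = c(names(pirna_seqs), paste0("bank_rep_", seq_along(embedded))),
      sequence = c(unname(pirna_seqs), embedded)
    )
  )

  # ---- tag pools with true categories --------------------------------
  pool <- list()
  add_tags <- function(seqs, category, origin) {
    pool[[length(pool) + 1L]] <<- tibble::tibble(
      sequence = seqs, category = category, origin = origin
    )
  }
  # miRNA isomiRs: shifts/lengths inside the -2/+5 precursor window
  iso <- purrr::map_dfr(seq_len(n_premirna), function(i) {
    s <- precursors$sequence[i]
    tibble::tibble(
      sequence = c(substr(s, 1, 22), substr(s, 2, 23), substr(s, 1, 21)),
      category = "miRNA", origin = precursors$name[i]
    )
  })
  pool[[length(pool) + 1L]] <- iso
  add_tags(unname(pirna_seqs), "piRNA", names(pirna_seqs))
  add_tags(embedded, "piRNA", paste0("bank_rep_", seq_along(embedded)))
  sub_tags <- function(seqs, per, lens) {
    unlist(lapply(seqs, function(s) {
      vapply(seq_len(per), function(j) {
        w <- sample(lens, 1)
        st <- sample(nchar(s) - w + 1L, 1)
        substr(s, st, st + w - 1L)
      }, character(1))
    }))
  }
  for (cl in NCRNA_CLASSES) {
    add_tags(sub_tags(rfam_seqs[rfam_classes == cl], 4, 25:32), cl,
             paste0("rfam:", cl))
  }
  plain_rep <- rep_seqs[-(1:6)]
  add_tags(sub_tags(plain_rep, 5, 24:30), "repeat", "repeat")
  add_tags(sub_tags(rep_seqs[1:3], 3, 24:30),
           rep(rep_class[1:3], each = 3), "repeat_recall")
  add_tags(sub_tags(mrna_seqs, 4, 20:30), "mRNA", "mrna")
  inter <- substr(genome_seq, inter_start + 1L, inter_start + 3000L)
  add_tags(sub_tags(inter, 40, 18:35), "unclassified", "intergenic")

  pool <- dplyr::bind_rows(pool)
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  if (mismatch_rate > 0) {
    hit <- stats::runif(nrow(pool)) < mismatch_rate
    pool$sequence[hit] <- vapply(pool$sequence[hit], function(s) {
      p <- sample(nchar(s), 1)
      substr(s, p, p) <- sample(setdiff(NUC, substr(s, p, p)), 1)
      s
    }, character(1), USE.NAMES = FALSE)
  }
  pool$tag_id <- sprintf("tag_%05d", seq_len(nrow(pool)))
  pool$weight <- stats::rlnorm(nrow(pool), 0, 1)

  # ---- stage-wise counts ---------------------------------------------
  cat_names <- colnames(stage_props)
  counts <- matrix(0, nrow(pool), stages,
                   dimnames = list(pool$tag_id, libs))
  for (s in seq_len(stages)) {
    alloc <- round(stage_props[s, ] * reads_per_stage)
    for (cat in cat_names) {
      rows <- which(pool$category == cat)
      if (length(rows) == 0L || alloc[[cat]] == 0) next
      counts[rows, s] <- as.numeric(
        stats::rmultinom(1, alloc[[cat]], prob = pool$weight[rows])
      )
    }
  }
  tags <- dplyr::bind_cols(
    pool[c("tag_id", "sequence")],
    tibble::as_tibble(counts)
  )
  truth <- pool[c("tag_id", "sequence", "category", "origin")]

  list(genome = genome, references = references, precursors = precursors,
       matures = matures, pirna_loci = pirna_loci, tags = tags,
       truth = truth, stage_props = stage_props, seed = seed, libs = libs)
}
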