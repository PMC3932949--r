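---
title: "Methods: hairpin classification and small-RNAome annotation with srnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin classification and small-RNAome annotation with srnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakit)
library(dplyr)
```

srnakit does two connected jobs. First, it decides whether a candidate RNA
stem-loop looks like a genuine microRNA precursor (pre-miRNA): a support
vector machine scores each hairpin on 65 sequence and secondary-structure
features. Second, it annotates collapsed small RNA-seq read tags into the
small-RNA classes of an embryonic small-RNAome — miRNA, rRNA, tRNA,
snRNA/snoRNA, genomic repeat, mRNA and piRNA — with isomiR-aware miRNA
quantification, piRNA cluster calling and family-level expression profiles.
This vignette explains the models, the parameters that matter, the numerical
conventions, and what the synthetic-data generator does and does not emulate.

## Secondary-structure topology

All structure features are computed from a dot-bracket string (as produced
by standard thermodynamic folding tools; the package performs no folding
itself, see `fold_hairpins()` for the adapter). `parse_dot_bracket()` builds
a pair table by stack matching and rejects unbalanced input and pseudoknot
notation outright. `decompose_structure()` then labels the topology:

* a **stem** is a maximal run of stacked pairs (i,j), (i+1,j−1), …;
* a **hairpin loop** is an unpaired region closed directly by one pair
  (a structure with more than one hairpin loop is flagged multi-stem);
* a **bulge** is any maximal internal unpaired region. The two strands of
  an interior loop are counted as *one* bulge whose size is their combined
  length — the bulge count is a single scalar in the feature catalogue, and
  treating an interior loop as two independent bulges would double-count a
  single structural interruption. In a multibranch loop, each unpaired gap
  between branches counts separately, since the gaps are not two sides of
  one interruption.
* exterior (dangling) unpaired ends belong to no loop and no bulge;
  otherwise every sequence with unpaired termini would carry a spurious
  bulge.

Positions are 1-based internally; every exported interval (BED, hit tables)
is 0-based half-open, the interchange convention.

## The 65-feature catalogue

`hairpin_features()` emits, per hairpin and in fixed order:

1. overall G+C percentage, (|G|+|C|)/L·100;
2. 16 overlapping dinucleotide percentages |XY|/(L−1)·100 — they sum to 100
   by construction;
3. nine pairing-topology scalars: the maximum run of consecutive paired
   nucleotides (MCPN), paired and unpaired fractions r_p_n and r_unp_n,
   their ratio r_p_unp, base pairs per stem, normalised base pairs
   dP = bp/L, the bulge count, unpaired nucleotides per bulge, and bulges
   per length;
4. 32 triplet structure-sequence elements: for each interior position the
   paired/unpaired states of (i−1, i, i+1) — both bracket directions are one
   "paired" state — combined with the nucleotide at i, normalised by the
   L−2 windows so the block sums to 1. Windows span the whole sequence; no
   region is excluded, as the construction defines no exclusion;
5. the minimum free energy (MFE, kcal/mol) and six derived quantities:
   dG = MFE/L and dG or MFE divided by GC percentage, stem count, hairpin
   loop count, base-pair count and bulge count.

Ratios with a vanishing denominator (no stems, loops, bulges, pairs, or a
fully paired sequence) are defined as 0: an unfolded degenerate input would
get a vanishing MFE anyway, the vectors stay finite, and such hairpins are
rejected upstream by the ≥ 19-bp filter. The "n_loops" denominator is the
hairpin-loop count — the terminal loop is the unambiguous "loop" of a
hairpin classifier.

Feature names are machine-safe forms of the catalogue's printed names
(`pct_GC_content`, `pct_AA` … `pct_UU`, `MCPN`, …, triplets as `A(((` etc.);
export order is catalogue order, so model files and feature TSVs are
reproducible.

## Feature-set selection by F-score

Features are grouped into sets — the 16 dinucleotides as one set, the 32
triplets as one set, each remaining scalar as a singleton (19 sets over the
65 implemented features; a further multi-stem-specific block used by older
split single-/multi-stem predictors is excluded, since mixed training sets
score it poorly). `fscore()` implements, per feature,

$$F_i = \frac{(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar x_i)^2}
{\tfrac{1}{n_+-1}\sum_k (x^+_{k,i} - \bar x_i^+)^2 +
 \tfrac{1}{n_--1}\sum_k (x^-_{k,i} - \bar x_i^-)^2},$$

and `rank_feature_sets()` ranks sets by the mean member F-score, keeping the
top k (default 19). When both within-class variances vanish, F is defined as
+∞ for separated means and 0 for equal means, which keeps perfectly
discriminating and perfectly useless degenerate features at the two ends of
the ranking. The exact membership of the singleton sets is configurable
(`catalog` argument) because the original 206-feature partition is not fully
enumerable from the published description; the shipped default is the
catalogue above.

## The SVM layer

`train_hairpin_svm()` rescales every feature linearly onto [−1, 1] from the
training minima/maxima (constant features map to 0; unseen values
extrapolate without clipping), then fits a C-classification SVM with an RBF
kernel through libsvm (e1071). The shipped defaults C = 8.0 and
γ = 0.03125 are the grid-searched operating point for zebrafish precursor
training data; `tune_svm`-style re-optimisation is deliberately out of
scope. Scores in [0, 1] come from a sigmoid (Platt) calibration of the
decision values, fitted as a quasi-binomial GLM with Platt's smoothed
targets (n+1)/(n+2) and 1/(n+2) — the smoothing keeps the fit finite on
separable data, and a GLM on decision values is deterministic, unlike
calibration schemes that re-partition the data internally. The slope of the
calibration absorbs the decision-value sign convention, so scores are always
positive-class probabilities.

`cross_validate()` uses stratified folds drawn from the supplied seed,
refits the scaler and the calibration inside each training fold (no
leakage), pools held-out confusion counts, and computes the ROC from pooled
scores. Leave-one-out is exactly k = n fold CV — every fold is one sample,
so the result is seed-independent. `confusion_metrics()` reports Sn, Sp, Ac
(percent) and the Matthews correlation coefficient, with MCC ≡ 0 when its
denominator vanishes (the conventional continuity choice).

## Pseudo-hairpin negatives from coding sequence

Protein-coding sequence provides realistic negatives: CDS records are joined
in seeded random order, fragmented left-to-right into non-overlapping
segments whose length multiset *equals* the positive set's lengths (one
segment per positive-set length value — the strongest reading of a matched
length distribution, and exactly reproducible), folded externally, and
filtered: at least 19 base pairs in the hairpin (the dot-bracket structure
already counts GU wobble pairs) and MFE ≤ −15.79 kcal/mol. From the
accepted pool, `sample_negatives()` draws 325 single-stem and 19 multi-stem
pseudo-hairpins by default, mirroring the composition of the known zebrafish
precursor set. If the pool cannot supply the requested topology mix the
function reports the available counts rather than silently relaxing.

## Hierarchical small-RNAome annotation

`preprocess_tags()` keeps unique reads of 18–35 nt observed at least 3 times
in some library (both boundaries inclusive). Retained tags are mapped to the
genome and to the category references with at most one substitution — the
same tolerance at every level, configurable; a hand-written C++ scan
reports *all* positions on both strands, which genome-scale aligners
deliberately do not, and precomputed SAM/BED hits can be imported instead.

Categories are assigned in fixed priority order: miRNA → Rfam ncRNA
(rRNA, tRNA, snRNA/snoRNA) → repeat → mRNA → piRNA; a tag assigned at one
level never reaches later levels, so each tag has exactly one category or is
left unclassified (and thereby eligible for novel-miRNA candidacy). Two
repeat-level refinements matter for completeness: repeat hits whose repeat
class itself names an ncRNA are *recalled* to that ncRNA category, and the
remaining repeat-level tags are re-matched against the piRNA reference —
successes are piRNAs flagged repeat-associated. Without these steps both
the ncRNA and the piRNA complement would be substantially undercounted,
because many such RNAs live inside annotated repeats.

Counting conventions: a multi-mapped tag contributes its count divided by
its number of mapping positions (fractional counts sum exactly to the raw
count); expression is normalised to reads per million where the denominator
is the library's *genome-mapped* read total, which makes categories
comparable across libraries with different mapping rates. miRNA expression
is isomiR-aware: tags are grouped per annotated precursor inside a window of
2 nt upstream and 5 nt downstream of the precursor locus (strand-aware,
0-based half-open after conversion), and the expression of the miRNA is the
count of its most abundant isomiR — end-variants of one miRNA are one
molecule species, and the dominant isoform is its least biased estimator.
Antisense hits count toward a category with the strand recorded, since
piRNAs in particular arise from both genomic strands.

## piRNA clusters and sequence summaries

A piRNA cluster is a maximal genomic run of at least 10 unique piRNA loci
in which the distance between adjacent loci — next start minus previous
end, for interval loci the defensible reading — is strictly below 1 kb.
Unique loci are distinct (chrom, start, end, strand) tuples regardless of
read count. Clusters span both strands by default (per-strand locus counts
are reported; a per-strand mode exists because a mixed cluster has no
canonical single-strand assignment). `five_prime_logo_matrix()` tabulates
the nucleotide frequencies of the first 15 nt for logo rendering — piRNA
sets show the expected strong position-1 U bias — and
`pirna_length_histogram()` summarises length distributions by
repeat-associated vs non-repeat-associated source.

## miRNA families and novel-candidate triage

Families are keyed on the seed, mature positions 2–8 (1-based, inclusive;
the canonical 7-nt target-recognition determinant). Family expression is the
sum of member expression — summation keeps the conservation law "family
total = member total" exact, where a representative-member convention would
not. `filter_novel()` scores candidate precursors (TSV rows with sequence,
structure, MFE — the neutral interchange that outputs of standard candidate
generators convert to) with the trained SVM and accepts scores ≥ 0.8
(inclusive); rejected and malformed rows are returned in an audit table
rather than dropped silently.

## The synthetic-data generator

`simulate_srna_study()` builds every input with known truth: a random
genome with planted precursor stem-loops (arm + loop + reverse-complement
arm, ≥ 19 bp by construction), piRNA clusters (10+ loci, ~28 nt,
80% 5′-U, spaced well under 1 kb within and over 2 kb between clusters),
Rfam-style ncRNA genes, class-annotated repeats — some carrying an ncRNA
class, some harbouring a planted piRNA — mRNAs, and intergenic space for
unclassified reads. Stage libraries (default eight of 50,000 reads) draw
tag counts multinomially under a programmable category-proportion schedule
whose default moves piRNA from 80% down to 10% with miRNA absorbing the
change — the piRNA-to-miRNA class transition of early embryogenesis — with
miRNA reads emitted as ~22-nt isomiR variants inside the −2/+5 windows and
piRNAs at ~28 nt, giving the familiar bimodal length profile.

Two deliberate simplifications: synthetic MFE values come from a
pairing-dependent linear model with noise (structures are emitted directly),
so the test suite needs no folding tool and is bit-reproducible; and the
generator plants no adaptor contamination, quality errors, or sequence
families with realistic homology. Passing tests therefore demonstrate the
*bookkeeping* of the pipeline — conservation, priority, windows, clustering,
normalisation — and the classifier's behaviour on well-separated classes;
they do not certify real-data accuracy, for which the classifier must be
retrained on curated precursors and CDS-derived negatives
(`build_negative_set()` + `fold_hairpins()`).

`simulate_hairpins()` generates the classifier's study conditions: 200
positives (5.5% of them two-stem, matching the small multi-stem minority of
real precursor sets) and 200 composition-shuffled, sparsely paired negatives
of matching lengths, and verifies at generation that at least five features
separate the classes by two pooled standard deviations.

## Problem sizes and numerical notes

The shipped tests run the pipeline at 8 × 50,000 reads on a ~100-kb genome,
cross-validation at n = 400 with 20 permutation repeats, and exhaustive
structure-decomposition checks against an independent region-labelling
oracle over *all* valid dot-bracket strings up to length 12 (~26,000
structures) — sizes chosen so the whole suite completes in a few minutes on
one core while still exercising every code path at meaningful scale.
Determinism throughout comes from explicit seeds: fold assignment, negative
sampling, the generator, and the calibration are all pure functions of
(data, seed). Ties in family ranking break lexicographically; stratified
fold assignment distributes each class round-robin after a seeded shuffle.

## Known limitations

* No thermodynamic folding: structures and MFEs are inputs. Pseudoknots are
  rejected, not modelled.
* The 1-mismatch matcher is exhaustive and desk-scale; genome-scale studies
  should import aligner output (`read_sam_hits()`).
* The shipped feature-set partition beyond the two multi-feature blocks is
  a best reading of the catalogue; it is configurable where a different
  partition is preferred.
* Ping-pong signature analysis (the 10-nt 5′ overlap of piRNA pairs) is out
  of scope.
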