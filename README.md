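# srnakit

Small RNA-seq annotation and pre-miRNA hairpin classification for
developmental small-RNAome studies.

Early vertebrate embryos hand control from maternally deposited transcripts
to the zygotic genome, and their small-RNA complement shifts with it:
Piwi-interacting RNAs (piRNAs, ~28 nt, genomically clustered) dominate the
earliest stages and give way to microRNAs (~22 nt) as development proceeds.
Quantifying that transition from small RNA-seq requires two things this
package provides as one tested toolkit:

1. **A hairpin classifier.** Candidate precursor miRNAs (pre-miRNAs) are
   scored by an RBF-kernel support vector machine on 65 sequence and
   secondary-structure features — G+C and dinucleotide composition, pairing
   topology (stems, hairpin loops, bulges, maximum paired run), 32 triplet
   structure–sequence elements, and minimum-free-energy ratios — with
   F-score feature-set selection,

   F = [(x̄⁺−x̄)² + (x̄⁻−x̄)²] / [s⁺² + s⁻²],

   features rescaled to [−1, 1], C = 8.0, γ = 0.03125, sigmoid-calibrated
   scores in [0, 1], and negatives built from coding sequence under the
   classic pseudo-hairpin constraints (≥ 19 base pairs, MFE ≤ −15.79
   kcal/mol, length distribution matched to the positives).

2. **A hierarchical small-RNAome annotator.** Collapsed read tags
   (18–35 nt, observed ≥ 3×) are assigned in fixed priority order
   miRNA → rRNA/tRNA/snRNA/snoRNA → repeat → mRNA → piRNA, with ncRNAs
   recalled out of repeat annotations, repeat-associated piRNAs rescued by
   re-matching leftover repeat tags against a piRNA reference, fractional
   counts for multi-mapped reads, isomiR-aware miRNA quantification
   (−2/+5 nt windows, most-abundant-isomiR expression), reads-per-million
   normalisation, piRNA cluster calling (≥ 10 unique loci, adjacent gaps
   < 1 kb), seed-based (nt 2–8) miRNA families, and SVM triage of novel
   miRNA candidates at a 0.8 score cutoff.

A seeded synthetic-data generator (`simulate_srna_study()`,
`simulate_hairpins()`) produces every input with known ground truth, so the
whole pipeline is testable offline. Everything is data-frame-in /
tibble-out and pipe-friendly; `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` helpers cover the result types. A thin CLI
(`exec/srnakit`) exposes the same functions as subcommands
(`simulate`, `features`, `build-negatives`, `select-features`, `train`,
`cross-validate`, `predict`, `annotate`, `pirna-clusters`, `profiles`,
`filter-novel`).

## Worked example

Train and cross-validate the hairpin classifier on generated study
conditions, then annotate a simulated eight-stage study:

```r
library(srnakit)

h  <- simulate_hairpins(n_pos = 200, n_neg = 200, seed = 1)
fv <- hairpin_features(h)          # 400 x 65 feature tibble
cross_validate(fv, h$label, folds = 10, seed = 1)
#> <hairpin_cv> 10-fold: Ac=100.00% Sn=100.00% Sp=100.00% MCC=1.0000 AUC=1.0000
```

The generated classes are separated by construction (≥ 5 features at ≥ 2
SD), so cross-validation recovers them perfectly; on real precursor/CDS
training data the same machinery reports its published-scale performance.
The metric layer itself is exact — reconstructing a balanced 344/344
evaluation from a printed sensitivity/specificity pair:

```r
confusion_metrics(tp = 329, fp = 4, tn = 340, fn = 15)
#> # A tibble: 1 x 8
#>      tp    fp    tn    fn    sn    sp    ac   mcc
#> 1   329     4   340    15  95.6  98.8  97.2 0.945
```

Annotation of a simulated study with a programmed piRNA-to-miRNA shift:

```r
sim  <- simulate_srna_study(seed = 1, stages = 3, reads_per_stage = 20000)
tags <- preprocess_tags(sim$tags)                  # 18-35 nt, >= 3 reads
ann  <- annotate_study(tags, sim$references, sim$genome)
sm   <- length_category_summary(ann$assignments)
dplyr::slice_max(dplyr::filter(sm, library == "stage1"), reads, n = 5)
#> # A tibble: 5 x 7
#>   library length category reads unique_tags prop_reads prop_unique
#> 1 stage1      28 piRNA     6655          41     0.333       0.126
#> 2 stage1      29 piRNA     5055          27     0.253       0.0828
#> 3 stage1      27 piRNA     2927          21     0.146       0.0644
#> 4 stage1      26 piRNA     1271           8     0.0636      0.0245
#> 5 stage1      22 miRNA      617          53     0.0309      0.163
```

Stage 1 is piRNA-dominated at ~28 nt, exactly as planted; by the last stage
the 22-nt miRNA peak dominates. `plot_length_distribution(sm)` and
`plot_category_composition(sm)` draw the standard summaries, and
`cluster_pirna_loci()`, `seed_family()`, `top_families()` and
`filter_novel()` continue the downstream analysis.

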