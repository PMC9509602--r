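---
title: "Tag-based urobiome profiling: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based urobiome profiling: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`urotag` implements species-level taxonomic profiling of low-biomass urine
samples from iso-length BcgI restriction tags, and the paired two-group
statistics used to compare the stone-bearing and non-stone-bearing renal
pelvis. This vignette explains the model, every tunable that matters, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one reading was defensible.

## The digestion model

BcgI is a type IIB enzyme: it binds the interrupted recognition site
CGA-N6-TGC and cleaves both strands on both sides, excising a fragment of
essentially fixed length. We model the released fragment as a 32-bp tag —
10 bp upstream flank, the 12-bp recognition core (CGA at tag positions
11–13 and TGC at 20–22, 1-based), 10 bp downstream flank. Both strands are
scanned (the reverse-strand core reads GCA-N6-TCG on the forward strand),
occurrences closer than 10 bp to a contig end are skipped, and tags
containing N are dropped because exact matching could never recover them. A
tag and its reverse complement denote the same double-stranded fragment, so
every tag is stored and compared in *canonical orientation*: the
lexicographically smaller of the sequence and its reverse complement.
Canonicalisation is idempotent and strand-symmetric, and the digest of a
reverse-complemented genome is identical to that of the genome — both
properties are exercised in the test suite against a brute-force
both-orientation scanner.

Within one genome, duplicate tags count once: the per-species tag total
`T_i` is the number of *distinct* species-specific markers. The alternative
(copy counting) would let repeated loci inflate both `T_i` and `S_i`
jointly; under the ratio `S_i/T_i` the two readings differ only for
repeat-heavy genomes, and distinct counting is the cleaner marker
semantics.

## Two-pass profiling and the G score

Reads are matched to tags by exact identity of the canonical 32-mer —
mismatch-tolerant matching would erode the species specificity the
database was built to guarantee. Error-bearing reads simply go unmatched
(and are tallied as diagnostics; they enter no normalisation).

Detection is screened by the G score, `G = sqrt(S * t)`, where `S` counts
every read assigned to any tag of the species and `t` the distinct tags
observed. The screen demands *breadth* of evidence: a genuine species with
20+ markers accumulates reads across many of them, while index-hopping or
contaminant pile-ups concentrate on one or two tags. The threshold is 10
and the boundary is inclusive (G ≥ 10 is retained): the phrase "minimum
threshold" names 10 as the smallest admissible value. A species with 3
reads on 3 tags scores 3 and can never be reported.

The second pass rebuilds the database over the per-sample candidates only.
Restricting the species pool can only move tags from "shared" to
"specific", so every candidate's `T_i` is at least its primary value — a
monotonicity property tested explicitly. With all species as candidates the
secondary database equals the primary one and the two passes agree to
numerical identity, which pins the two-pass machinery down as a pure
re-quantification (no hidden renormalisation).

Relative abundance is the normalised ratio `(S_i/T_i) / sum_j (S_j/T_j)`.
Dividing by `T_i` removes the head start that marker-rich species would
otherwise get: in the generator, read counts are drawn with probability
proportional to `abundance × tag count`, exactly the structure this
normalisation inverts, and on error-free simulations the estimate converges
to the truth as reads grow (the L1 error roughly halves when reads
quadruple).

## Read QC

Raw reads are first filtered to *enzyme reads* — exactly 32 bp with the
core at the expected positions in either orientation, N matching nothing —
and then to *clean reads* by two criteria applied verbatim: more than 8%
unknown bases, or more than 20% of bases at Phred Q ≤ 20, removes a read.
Both boundaries are strict (a 32-bp read with exactly 2 N, 6.25%,
survives; 3 N, 9.375%, does not), and Q = 20 itself counts as low quality.
The raw → enzyme → clean ordering follows the description of the original
workflow; the two clean-read filters are order-independent, so only the
position of the enzyme screen is a real choice.

## The synthetic cohort

The generator exists so that every downstream claim can be tested against
known truth. It emulates:

* a three-rank taxonomy (phylum > genus > species) with every species in
  exactly one lineage;
* one genome per species (default 50 kb, ±10%), clade-correlated GC so
  related species share composition, and 20–200 planted BcgI core sites per
  species at uniform non-overlapping positions — the tag-count regime the
  profiling model assumes, and a guarantee that no species is undetectable;
* a paired design: per-species community log-means drawn N(0, σ²) with
  σ = 1.5 (a standard log-normal rank-abundance curve), a per-subject
  random effect (sd 0.5 on the log scale) *shared by the two sides of a
  subject*, and planted stone-side fold changes applied before
  renormalisation — so within-subject ratios carry the planted signal
  exactly;
* reads as pure 32-bp inserts (Phred+33), drawn species-proportionally to
  `abundance × tag count`, uniformly across a species' tags and strands,
  with per-base substitution errors (default 0.1%) and N substitutions
  (default 0.05%); base qualities encode the nominal substitution rate,
  with N bases at Q2.

It does **not** emulate adaptor content, indels, PCR amplification bias,
paired-end layouts, host-DNA background, or cross-sample contamination.
Passing recovery tests therefore demonstrates correctness of the
computational chain under its own assumptions — not robustness to
library-chemistry artefacts absent from the model. Default sizes (30
subjects × 2 sides, ~300 species over 10 phyla, 20k reads per sample)
mirror the cohort scale the analysis stack is aimed at.

## Statistics

**Alpha diversity.** Chao1 needs integer singleton/doubleton counts and is
therefore computed on per-sample pass-2 read counts `S_i`; Shannon (natural
log) and Gini–Simpson are computed on relative abundances. Chao1 uses the
bias-corrected form `S_obs + F1(F1−1)/(2(F2+1))`, so it is defined when no
doubletons exist and always ≥ `S_obs`.

**Beta diversity.** Bray–Curtis and Euclidean on abundances and binary
Jaccard on presence/absence (via `vegan::vegdist`); PCoA by Gower
double-centering and eigendecomposition (`stats::cmdscale`), with negative
eigenvalues reported untouched rather than corrected — on genuinely
Euclidean distances the configuration is recovered up to
rotation/reflection, which the tests check by Procrustes residual.

**PERMANOVA** uses the two-group distance-based pseudo-F with the
`(1 + count)/(1 + n_perm)` p-value convention (p = 0 is impossible under a
sampled null). Labels permute freely by default — the original analysis
shows no sign of restricted permutation — with an optional `strata`
argument that permutes only within subject for a strictly paired reading.
The statistic is cross-checked against `vegan::adonis2` in the tests, and
its type-I error is verified by a 200-replicate null calibration.

**Differential abundance** is the paired Wilcoxon signed-rank test per
taxon: zero differences dropped, exact null when ≤ 25 nonzero differences
without ties, otherwise the tie- and continuity-corrected normal
approximation. Raw p-values are reported without multiple-testing
correction, matching the conventional presentation of such tables;
direction is assigned by the higher group mean. Taxa whose paired
differences are all zero are reported with `p = NA` rather than dropped. A
taxon with nonzero abundance on one side only and a mean of exactly zero on
the other can still test significant — zeros within pairs are dropped as
Wilcoxon convention requires, and the remaining informative pairs decide.

**LDA effect sizes** follow the published two-stage recipe: a
Kruskal–Wallis screen at α = 0.05 (retained as KW even though the
two-class case reduces to a rank-sum test, for fidelity to the cited
procedure), then, on per-sample totals rescaled to 10⁶, thirty
class-balanced two-thirds subsamples each fit a single-discriminant LDA;
a feature's effect averages its raw between-class mean difference with its
contribution along the discriminant axis, and the score is
`sign × log10(1 + |effect|)` with reporting threshold 2.0. Exact numeric
parity with the original LEfSe tool is out of scope; the contract is the
threshold semantics (monotone: raising the threshold never adds taxa) and
that non-overlapping class supports of meaningful magnitude always clear
2.0 on the 10⁶ scale.

**Markers.** The candidate pool is the top 30 species by overall mean
abundance. A random forest (500 trees, √p features per split, Gini
impurity) provides one global importance ranking; repeated stratified
tenfold CV (10 repeats) over nested top-k sets yields the error curve;
the cut-off is the minimum mean error plus the SD at that minimum, and the
optimal set is the smallest k whose error beats the cut-off (when the SD
at the minimum is zero, only the minimum itself qualifies — the rule is
scale-free). Feature sets are nested along the single global ranking
rather than re-ranked per fold, matching the "sets of biomarkers indexed
by size" construction. The POD index is defined as the *fraction* of trees
voting for the stone side — the literal stone/non-stone vote ratio is
unbounded and undefined under unanimity — computed from out-of-bag votes
for training samples to avoid resubstitution optimism (with a flagged
full-ensemble fallback for a sample never left out of bag). AUC uses the
tie-corrected rank formulation, which equals brute-force concordant-pair
counting and `pROC` on the same scores.

## Numerical choices and degenerate inputs

* Sequences shorter than 32 bp digest to an empty tag list (not an error);
  an all-zero abundance vector, an empty candidate list, an all-zero count
  vector, or all-zero paired differences raise immediate, named errors.
* Species with no specific tags are listed and flagged rather than
  silently dropped.
* A sample in which no species clears the G screen yields an empty profile
  with a warning, not a failure.
* Constant taxa produce `NA` Spearman correlations (emitted as missing)
  and are never reported by the LDA stage.
* All randomness flows from a single seed through named per-stage
  substreams, so cohort simulation, fold assignment, permutation tests and
  forests are individually and jointly reproducible; identical seeds give
  byte-identical FASTQ and report files.

## Problem sizes used by the test and acceptance suites

Recovery and calibration runs use sizes chosen to make the statistical
properties measurable while keeping the suites quick: 30-species
communities with 10⁵ (and 4×10⁵) error-free reads for abundance recovery;
20 absent species with 3 spurious reads over 3 tags each for the
false-positive screen; 200 null replicates (30 pairs; 199 permutations per
PERMANOVA, whose p-grid still resolves α = 0.05 exactly) for calibration;
50 seeds for the 8-fold planted-effect detection rate; and a 5-signal +
25-noise, 30-subject cohort (fold 3 against subject sd 0.8, so no single
marker separates the sides alone) for the marker workflow.

## Known limitations

Only BcgI geometry is implemented (no CspCI/BsaXI); matching is exact by
design; Chao1 on deeply undersampled samples underestimates richness, as
always; the LDA effect size is a faithful re-derivation, not a bug-for-bug
LEfSe port; and the generator's clean community model means real-data
failure modes (contamination, host carry-over, amplification bias) must be
judged separately.
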