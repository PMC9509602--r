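# urotag

Species-level microbiome profiling from iso-length type IIB restriction
tags, and the paired analysis stack used to compare the renal-pelvis
urobiome on the stone-bearing and non-stone-bearing sides of kidney-stone
patients.

## The problem

Urine from the renal pelvis is an extremely low-biomass sample: shotgun
metagenomics is dominated by host DNA, and 16S amplicons resolve genera at
best. Tag-based profiling sidesteps both problems. The type IIB restriction
enzyme BcgI recognises the bipartite site CGA-N6-TGC and cuts both strands
on both sides of it, releasing iso-length (~32 bp) fragments. Only these
fragments are sequenced, and each read is compared *exactly* against a
database of tags that are unique to a single species. Species identity is
therefore carried by marker identity, not alignment, and a small number of
reads suffices for species-level calls.

`urotag` implements that profiling model and the downstream paired
comparison stack, plus a synthetic-data generator (taxonomies, genomes with
planted BcgI sites, paired log-normal communities, error-bearing reads)
with full ground truth, so every stage can be validated end to end without
any external data.

## The model

For species *i* within a sample, with `S_i` = reads assigned to any of its
tags and `t_i` = distinct tags observed, the false-positive screen is the
**G score**

> G_i = sqrt(S_i × t_i),

with candidates retained at G ≥ 10: genuine detections accumulate reads
*across many* distinct tags, while contaminant or mis-assigned pile-ups on
one or two tags score low (3 reads on 3 tags gives G = 3). A secondary,
sample-specific tag database is then rebuilt over the candidates only —
which can only increase every candidate's specific-tag count `T_i` — all
reads are reassigned, and the **relative abundance** is the tag-count
normalised ratio

> RA_i = (S_i / T_i) / Σ_j (S_j / T_j).

Downstream, samples are compared with the field's standard tools: Chao1 /
Shannon / Simpson alpha diversity, Bray–Curtis / binary-Jaccard / Euclidean
distances with PCoA and PERMANOVA, paired Wilcoxon differential-abundance
tables, LDA effect sizes (threshold 2.0), Spearman co-abundance networks,
and random-forest marker selection: tenfold CV repeated 10 times over
nested top-*k* feature sets, the minimum-error + SD smallest-set rule, a
per-sample POD (probability of disease) index from out-of-bag stone votes,
and ROC/AUC.

## Worked example

```r
library(urotag)

tax     <- make_taxonomy(n_phyla = 3, n_genera = 6, n_species = 12, seed = 2)
genomes <- make_genomes(tax, length_mean = 20000, sites_range = c(20, 60), seed = 3)
db      <- build_tagdb(genomes, tax)
db
#> <tag_db scope=primary: 525 tags, 12 species (0 without specific tags)>

truth <- c(s0001 = 0.5, s0002 = 0.3, s0003 = 0.2)
reads <- simulate_reads(genomes, truth, n_reads = 20000,
                        error_rate = 0.001, n_rate = 0.0005, seed = 4)
qc <- qc_sample(reads)
qc$report
#>   n_raw n_enzyme n_clean fraction_enzyme fraction_clean
#> 1 20000    19781   19781         0.98905        0.98905

profile <- profile_sample(qc$reads, db, genomes)
round(profile$abundance, 3)
#> s0002 s0001 s0003
#> 0.299 0.501 0.199

head(profile$pass1, 4)
#>   species    S  t        G
#> 1   s0002 7686 41 561.3608
#> 2   s0001 7534 24 425.2246
#> 3   s0003 3865 31 346.1430
```

The 525 database tags are the BcgI fragments unique to one of the 12
genomes. Of 20,000 raw reads, 98.9% carry the recognition core at the
expected positions and survive the N/low-quality filters. The two-pass
profile recovers the simulated composition (0.5 / 0.3 / 0.2) to three
decimals; the pass-1 table shows why the detections are trustworthy — each
species' reads are spread over dozens of distinct tags, so G scores are in
the hundreds, far above the screening threshold of 10.

The full cohort analysis is laid out as numbered drivers under `analysis/`
(simulate → profile → diversity → differential abundance → markers), each a
thin script over the package functions that prints what it found and writes
its tables under `results/`. `run_pipeline()` performs the same sequence in
one call from a config list or YAML/JSON file.

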