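#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# 30 subjects, each contributing a stone-side and a non-stone-side renal
# pelvis sample; 300 detectable species across 10 phyla with log-normal
# community structure; planted side effects mirror the reported
# directionality: one genus enriched on the stone side, two depleted.
# Ground truth (design, abundances, effects) goes to results/cohort/;
# the heavyweight cohort object (genomes + reads) is cached under scratch/.

suppressPackageStartupMessages(library(urotag))

seed <- 20260919L
tax <- make_taxonomy(n_phyla = 10, n_genera = 60, n_species = 300, seed = seed)

# planted effects: all species of one genus up on the stone side, two genera
# down (fold changes on the stone side relative to the non-stone side)
up_genus <- "g001"
down_genera <- c("g002", "g003")
effects <- c(
  structure(rep(2.5, sum(tax$genus == up_genus)),
            names = tax$species_id[tax$genus == up_genus]),
  structure(rep(0.3, sum(tax$genus %in% down_genera)),
            names = tax$species_id[tax$genus %in% down_genera])
)

cohort <- simulate_cohort(
  n_phyla = 10, n_genera = 60, n_species = 300, n_subjects = 30,
  effects = effects, reads_per_sample = 20000,
  error_rate = 0.001, n_rate = 0.0005, seed = seed
)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
write_taxonomy(cohort$tax, "results/cohort/taxonomy.tsv")
write.table(cohort$design$samples, "results/cohort/design.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_truth_manifest(cohort, "results/cohort/truth.json")
dir.create("scratch", showWarnings = FALSE)
saveRDS(cohort, "scratch/cohort.rds")

message(sprintf("simulated %d samples from %d subjects; %d species, %d planted effects",
                ncol(cohort$design$abundance), 30, nrow(cohort$tax), length(effects)))
message("truth written to results/cohort/, cohort cached in scratch/cohort.rds")
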