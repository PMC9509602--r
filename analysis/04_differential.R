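#!/usr/bin/env Rscript
# Stage 4 — which taxa differ between the stone and non-stone sides?
#
# Paired Wilcoxon differential-abundance tables at phylum, genus and species
# rank (raw p-values, as is conventional for these tables), LDA effect sizes
# (threshold 2.0) and a Spearman co-abundance matrix of the top 30 genera.

suppressPackageStartupMessages(library(urotag))

species <- read_profile_tsv("results/profiles/species_abundance.tsv")
genus <- read_profile_tsv("results/profiles/genus_abundance.tsv")
phylum <- read_profile_tsv("results/profiles/phylum_abundance.tsv")
design <- read.table("results/cohort/design.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
side <- design$side[match(colnames(species), design$sample_id)]

dir.create("results/differential", recursive = TRUE, showWarnings = FALSE)

for (rank in c("phylum", "genus", "species")) {
  mat <- get(rank)
  tab <- differential_table(mat, design)
  write.table(tab, sprintf("results/differential/diff_%s.tsv", rank),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-7s rank: %d/%d taxa flagged at p < 0.05; top hit %s (p = %.2g, %s side)",
                  rank, sum(tab$flagged), nrow(tab), tab$taxon[1],
                  tab$p_value[1], tab$direction[1]))
}

lda <- lda_effect_size(species, side, lda_threshold = 2.0, seed = 13)
write.table(lda, "results/differential/lda_effect_sizes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("LDA: %d discriminative species at |score| >= 2.0 (%d stone-enriched)",
                nrow(lda), sum(lda$enriched_group == "stone")))

sp <- spearman_matrix(genus, top_n = 30)
write.table(data.frame(taxon = rownames(sp$rho), sp$rho, check.names = FALSE),
            "results/differential/spearman_rho_genus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(taxon = rownames(sp$p), sp$p, check.names = FALSE),
            "results/differential/spearman_p_genus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_sig <- sum(sp$p[upper.tri(sp$p)] < 0.05, na.rm = TRUE)
message(sprintf("Spearman: %d of %d genus pairs correlated at p < 0.05",
                n_sig, sum(upper.tri(sp$p))))
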