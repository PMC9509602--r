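#!/usr/bin/env Rscript
# Stage 3 — community diversity and structure between the two sides.
#
# Alpha diversity (Chao1 on read counts, Shannon/Simpson on proportions)
# compared by paired Wilcoxon; beta diversity (Bray-Curtis, binary Jaccard,
# Euclidean) ordinated by PCoA and tested by PERMANOVA; Venn partition of
# detected species.

suppressPackageStartupMessages(library(urotag))

species <- read_profile_tsv("results/profiles/species_abundance.tsv")
counts <- read_profile_tsv("results/profiles/species_read_counts.tsv")
design <- read.table("results/cohort/design.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
side <- design$side[match(colnames(species), design$sample_id)]

dir.create("results/ecology", recursive = TRUE, showWarnings = FALSE)

alpha <- alpha_table(counts, species)
alpha$side <- side
write.table(alpha, "results/ecology/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (idx in c("chao1", "shannon", "simpson")) {
  stone <- alpha[[idx]][side == "stone"]
  non <- alpha[[idx]][side == "non_stone"]
  p <- paired_wilcoxon(stone, non)$p_value
  message(sprintf("alpha %-8s stone %.3f vs non-stone %.3f, paired Wilcoxon p = %.3f",
                  idx, mean(stone), mean(non), p))
}

perma <- data.frame()
for (metric in c("bray_curtis", "jaccard_binary", "euclidean")) {
  d <- distance_matrix(species, metric)
  ord <- pcoa(d, n_axes = 3)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, side = side)
  write.table(coords, sprintf("results/ecology/pcoa_%s.tsv", metric),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res <- permanova(d, side, n_perm = 999, seed = 11)
  perma <- rbind(perma, data.frame(metric = metric, pseudo_F = res$pseudo_F,
                                   p_value = res$p_value))
  message(sprintf("PERMANOVA (%s): pseudo-F = %.3f, p = %.3f",
                  metric, res$pseudo_F, res$p_value))
}
write.table(perma, "results/ecology/permanova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

det_stone <- rownames(species)[rowSums(species[, side == "stone"]) > 0]
det_non <- rownames(species)[rowSums(species[, side == "non_stone"]) > 0]
venn <- venn_summary(det_stone, det_non)
write.table(venn, "results/ecology/venn_species.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("species detection: %d shared (%.2f%%), %d stone-only, %d non-stone-only of %d total",
                venn$n[1], venn$pct[1], venn$n[2], venn$n[3], attr(venn, "n_union")))
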