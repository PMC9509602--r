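#!/usr/bin/env Rscript
# Stage 5 — random-forest species markers and the POD index.
#
# Top-30 most abundant species feed a random forest; tenfold CV with 10
# repeats yields the error curve; the minimum-error + SD smallest-set rule
# picks the optimal marker set; per-sample POD (out-of-bag stone-vote
# fraction) is evaluated by ROC/AUC and a paired Wilcoxon test.

suppressPackageStartupMessages(library(urotag))

species <- read_profile_tsv("results/profiles/species_abundance.tsv")
design <- read.table("results/cohort/design.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)

res <- marker_workflow(species, design, top_n = 30, folds = 10, repeats = 10,
                       n_trees = 500, seed = 17)

dir.create("results/markers", recursive = TRUE, showWarnings = FALSE)
write.table(res$curve, "results/markers/cv_error_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(rank = seq_along(res$optimal_set),
                       species = res$optimal_set),
            "results/markers/optimal_marker_set.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = names(res$pod), pod = res$pod,
                       side = design$side[match(names(res$pod), design$sample_id)]),
            "results/markers/pod_index.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res$roc, "results/markers/roc_points.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("optimal marker set: %d species (CV cut-off rule)", res$k_star))
message(sprintf("AUC = %.3f; POD stone vs non-stone paired Wilcoxon p = %.3g",
                res$auc, res$pod_p))
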