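#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically read from YAML or JSON) with a
#' `simulate` block describing the synthetic cohort, an optional
#' `parameters` block overriding analysis defaults, and a `seed`.  Unknown
#' keys anywhere are rejected before any stage runs.
#'
#' @param config named list.
#' @return the config with defaults filled in.
#' @export
validate_config <- function(config) {
  known_top <- c("simulate", "parameters", "seed")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0L) {
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  defaults_sim <- list(n_phyla = 10L, n_genera = 60L, n_species = 300L,
                       n_subjects = 30L, effects = list(),
                       reads_per_sample = 20000L, error_rate = 0.001,
                       n_rate = 0.0005, sigma_lognormal = 1.5, subject_sd = 0.5)
  defaults_par <- list(g_score_threshold = 10, max_n_fraction = 0.08,
                       max_lowq_fraction = 0.20, lda_threshold = 2.0,
                       folds = 10L, repeats = 10L, n_perm = 999L, top_n = 30L,
                       n_trees = 500L)
  sim <- config$simulate %||% list()
  par <- config$parameters %||% list()
  bad_sim <- setdiff(names(sim), names(defaults_sim))
  if (length(bad_sim) > 0L) stop_invalid("unknown simulate key(s): %s", paste(bad_sim, collapse = ", "))
  bad_par <- setdiff(names(par), names(defaults_par))
  if (length(bad_par) > 0L) stop_invalid("unknown parameter key(s): %s", paste(bad_par, collapse = ", "))
  out <- list(
    simulate = utils::modifyList(defaults_sim, sim),
    parameters = utils::modifyList(defaults_par, par),
    seed = config$seed %||% 1L
  )
  with(out$parameters, {
    if (g_score_threshold <= 0 || lda_threshold <= 0 || folds < 2 ||
        repeats < 1 || n_perm < 1 || top_n < 1) {
      stop_invalid("thresholds and sizes must be positive")
    }
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order — simulate, build the tag database, QC,
#' two-pass profiling, diversity/ordination/PERMANOVA, paired differential
#' abundance with LDA effect sizes and Spearman correlations, and
#' random-forest marker selection with POD — and returns (and optionally
#' writes) a report bundle.  All randomness flows from the single config
#' seed through named per-stage substreams, so reruns with the same config
#' are identical.
#'
#' @param config configuration list (see [validate_config()]).
#' @param out_dir optional directory; when given, per-stage TSV/JSON outputs
#'   are written there.
#' @return list with elements `qc`, `profiles`, `species`, `genus`,
#'   `phylum` (abundance matrices), `alpha`, `permanova`, `venn`,
#'   `diff_species`, `diff_genus`, `diff_phylum`, `lda`, `spearman`,
#'   `markers`, and `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  par <- config$parameters
  sim <- config$simulate

  cohort <- do.call(simulate_cohort, c(
    sim[setdiff(names(sim), "effects")],
    list(effects = unlist(sim$effects) %||% numeric(0), seed = seed)
  ))
  message(sprintf("[simulate] %d species, %d samples, %d reads/sample",
                  nrow(cohort$tax), ncol(cohort$design$abundance),
                  sim$reads_per_sample))

  db <- build_tagdb(cohort$genomes, cohort$tax)
  message(sprintf("[tagdb] %d species-specific tags over %d species",
                  length(db$tags), length(db$T)))

  qc <- lapply(cohort$reads, qc_sample)
  clean <- lapply(qc, `[[`, "reads")
  qc_report <- do.call(rbind, lapply(qc, `[[`, "report"))
  qc_report <- cbind(sample_id = names(qc), qc_report)
  rownames(qc_report) <- NULL
  message(sprintf("[qc] %.1f%% of reads clean on average",
                  100 * mean(qc_report$fraction_clean)))

  profiles <- profile_cohort(clean, db, cohort$genomes, par$g_score_threshold)
  species <- profile_matrix(profiles)
  counts <- count_matrix(profiles)
  genus <- aggregate_ranks(species, cohort$tax, "genus")
  phylum <- aggregate_ranks(species, cohort$tax, "phylum")
  message(sprintf("[profiler] %d species detected across samples", nrow(species)))

  samples <- cohort$design$samples
  side <- samples$side[match(colnames(species), samples$sample_id)]
  alpha <- alpha_table(counts, species)
  perma <- lapply(c(bray_curtis = "bray_curtis", jaccard_binary = "jaccard_binary",
                    euclidean = "euclidean"), function(m) {
    permanova(distance_matrix(species, m), side, n_perm = par$n_perm,
              seed = substream_seed(seed, paste0("perm_", m)))
  })
  det_stone <- rownames(species)[rowSums(species[, side == "stone", drop = FALSE]) > 0]
  det_non <- rownames(species)[rowSums(species[, side == "non_stone", drop = FALSE]) > 0]
  venn <- venn_summary(det_stone, det_non)

  diff_species <- differential_table(species, samples)
  diff_genus <- differential_table(genus, samples)
  diff_phylum <- differential_table(phylum, samples)
  lda <- lda_effect_size(species, side, lda_threshold = par$lda_threshold,
                         seed = substream_seed(seed, "lda"))
  sp_cor <- spearman_matrix(genus, top_n = par$top_n)
  markers <- marker_workflow(species, samples, top_n = par$top_n,
                             folds = par$folds, repeats = par$repeats,
                             n_trees = par$n_trees,
                             seed = substream_seed(seed, "markers"))
  message(sprintf("[markers] k* = %d, AUC = %.3f", markers$k_star, markers$auc))

  result <- list(qc = qc_report, profiles = profiles, species = species,
                 counts = counts, genus = genus, phylum = phylum,
                 alpha = alpha, permanova = perma, venn = venn,
                 diff_species = diff_species, diff_genus = diff_genus,
                 diff_phylum = diff_phylum, lda = lda, spearman = sp_cor,
                 markers = markers, cohort = cohort, config = config)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(result$qc, "qc_report.tsv")
  write_profile_tsv(result$species, file.path(out_dir, "species_abundance.tsv"))
  write_profile_tsv(result$genus, file.path(out_dir, "genus_abundance.tsv"))
  write_profile_tsv(result$phylum, file.path(out_dir, "phylum_abundance.tsv"))
  tsv(result$alpha, "alpha_diversity.tsv")
  tsv(result$venn, "venn_species.tsv")
  tsv(result$diff_species, "diff_species.tsv")
  tsv(result$diff_genus, "diff_genus.tsv")
  tsv(result$diff_phylum, "diff_phylum.tsv")
  tsv(result$lda, "lda_effect_sizes.tsv")
  tsv(result$markers$curve, "cv_error_curve.tsv")
  tsv(data.frame(species = result$markers$optimal_set), "optimal_marker_set.tsv")
  tsv(data.frame(sample_id = names(result$markers$pod), pod = result$markers$pod),
      "pod_index.tsv")
  tsv(result$markers$roc, "roc_points.tsv")
  jsonlite::write_json(
    list(
      permanova = result$permanova,
      markers = list(k_star = result$markers$k_star, auc = result$markers$auc,
                     pod_p = result$markers$pod_p),
      parameters = result$config$parameters,
      seed = result$config$seed
    ),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}
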