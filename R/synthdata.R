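#' Generate a random taxonomy
#'
#' Builds a three-rank lineage tree (phylum > genus > species) in which every
#' genus belongs to exactly one phylum and every species to exactly one
#' genus, mirroring the rank structure used for aggregated community
#' profiles.
#'
#' @param n_phyla,n_genera,n_species rank sizes, `n_phyla <= n_genera <=
#'   n_species`.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data frame with columns `species_id`, `genus`, `phylum`.
#' @export
make_taxonomy <- function(n_phyla, n_genera, n_species, seed = 1L) {
  if (!is_count(n_phyla) || !is_count(n_genera) || !is_count(n_species) ||
      n_phyla < 1L || !(n_phyla <= n_genera && n_genera <= n_species)) {
    stop_invalid("need 1 <= n_phyla <= n_genera <= n_species")
  }
  set.seed(seed)
  phyla <- sprintf("p%02d", seq_len(n_phyla))
  genera <- sprintf("g%03d", seq_len(n_genera))
  species <- sprintf("s%04d", seq_len(n_species))
  # guarantee every phylum hosts a genus and every genus a species
  genus_phylum <- c(phyla, sample(phyla, n_genera - n_phyla, replace = TRUE))
  species_genus <- c(genera, sample(genera, n_species - n_genera, replace = TRUE))
  data.frame(
    species_id = species,
    genus = species_genus,
    phylum = genus_phylum[match(species_genus, genera)],
    stringsAsFactors = FALSE
  )
}

plant_core_sites <- function(sequence, k) {
  n <- nchar(sequence)
  # non-overlapping 32-bp windows, each at least 10 bp from the ends
  slots <- seq(from = 11L, to = n - BCGI_TAG_LEN - 10L, by = BCGI_TAG_LEN)
  if (length(slots) < k) {
    stop_invalid("genome of length %d too short for %d planted sites", n, k)
  }
  starts <- sort(sample(slots, k))
  for (s in starts) {
    core <- paste0("CGA", random_dna(6L), "TGC")
    substr(sequence, s + 10L, s + 21L) <- core
  }
  sequence
}

#' Generate genomes with planted BcgI sites
#'
#' One genome per species.  Base composition is clade-correlated: each phylum
#' draws a GC content inside `gc_range`, and genera/species jitter around it,
#' so related species share composition.  A per-species number of BcgI core
#' sites (CGA-N6-TGC) is planted at uniform random non-overlapping positions,
#' guaranteeing that every species carries digestible tags.
#'
#' @param tax taxonomy table from [make_taxonomy()].
#' @param length_mean mean genome length in bp (lengths jitter +/- 10%).
#' @param gc_range range of phylum-level GC content, inside (0, 1).
#' @param sites_range integer range; each species plants a uniform number of
#'   core sites in this range (default 20-200, the tag-count regime the
#'   profiling model assumes).
#' @param seed integer seed.
#' @return named character vector, species_id -> genome sequence.
#' @export
make_genomes <- function(tax, length_mean = 50000L, gc_range = c(0.35, 0.65),
                         sites_range = c(20L, 200L), seed = 1L) {
  if (nrow(tax) == 0L) stop_invalid("empty taxonomy")
  if (length(gc_range) != 2L || gc_range[1L] <= 0 || gc_range[2L] >= 1 ||
      gc_range[1L] > gc_range[2L]) {
    stop_invalid("gc_range must lie within (0, 1)")
  }
  set.seed(seed)
  phyla <- unique(tax$phylum)
  gc_phylum <- structure(runif(length(phyla), gc_range[1L], gc_range[2L]),
                         names = phyla)
  genera <- unique(tax$genus)
  gc_genus <- structure(
    gc_phylum[tax$phylum[match(genera, tax$genus)]] + rnorm(length(genera), 0, 0.02),
    names = genera
  )
  out <- character(nrow(tax))
  names(out) <- tax$species_id
  for (i in seq_len(nrow(tax))) {
    gc <- min(max(gc_genus[tax$genus[i]] + rnorm(1L, 0, 0.01), 0.05), 0.95)
    len <- max(BCGI_TAG_LEN + 22L,
               round(length_mean * runif(1L, 0.9, 1.1)))
    ks <- seq(sites_range[1L], sites_range[2L])
    k <- ks[sample.int(length(ks), 1L)]
    out[i] <- plant_core_sites(random_dna(len, gc), k)
  }
  out
}

#' Generate a paired two-group community design
#'
#' Emulates a paired cohort in which each subject contributes one sample per
#' body side (`stone` and `non_stone`).  Species base abundances follow a
#' log-normal rank-abundance curve (community effect, sd `sigma_lognormal`)
#' with a per-subject log-normal random effect (sd `subject_sd`) shared by
#' the two sides of a subject; the stone side multiplies planted species by
#' their fold change before renormalisation, so within-subject ratios carry
#' the planted signal exactly.
#'
#' @param species character vector of species ids.
#' @param n_subjects number of subjects (>= 2); the design has `2 *
#'   n_subjects` samples.
#' @param sigma_lognormal sd of the species-level log-normal community
#'   abundances (default 1.5).
#' @param effects named numeric vector, species_id -> fold change (> 0) of
#'   the stone side relative to the non-stone side.
#' @param subject_sd sd of the per-subject log-scale random effect.
#' @param seed integer seed.
#' @return object of class `paired_design`: list with `samples` (data frame
#'   `sample_id`, `subject_id`, `side`), `abundance` (species x samples
#'   matrix of proportions, each column summing to 1), `effects`, and
#'   `base_mean` (the drawn community log-means, ground truth).
#' @export
make_paired_design <- function(species, n_subjects = 30L, sigma_lognormal = 1.5,
                               effects = numeric(0), subject_sd = 0.5,
                               seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2L) stop_invalid("need n_subjects >= 2")
  if (length(effects) > 0L) {
    unknown <- setdiff(names(effects), species)
    if (length(unknown) > 0L) {
      stop_invalid("effects name unknown species: %s", paste(unknown, collapse = ", "))
    }
    if (any(effects <= 0)) stop_invalid("fold changes must be > 0")
  }
  set.seed(seed)
  n_sp <- length(species)
  mu <- rnorm(n_sp, 0, sigma_lognormal)          # community structure
  fold <- structure(rep(1, n_sp), names = species)
  fold[names(effects)] <- effects
  samples <- data.frame(
    sample_id = sprintf("subj%02d_%s", rep(seq_len(n_subjects), each = 2L),
                        rep(c("stone", "non_stone"), n_subjects)),
    subject_id = sprintf("subj%02d", rep(seq_len(n_subjects), each = 2L)),
    side = rep(c("stone", "non_stone"), n_subjects),
    stringsAsFactors = FALSE
  )
  abundance <- matrix(0, n_sp, nrow(samples),
                      dimnames = list(species, samples$sample_id))
  for (j in seq_len(n_subjects)) {
    b <- rnorm(n_sp, 0, subject_sd)              # subject effect, shared by sides
    base <- exp(mu + b)
    stone <- base * fold
    abundance[, 2L * j - 1L] <- stone / sum(stone)
    abundance[, 2L * j] <- base / sum(base)
  }
  structure(
    list(samples = samples, abundance = abundance, effects = effects,
         base_mean = structure(mu, names = species), seed = seed),
    class = "paired_design"
  )
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design: %d subjects x 2 sides, %d species, %d planted effects>\n",
              nrow(x$samples) / 2L, nrow(x$abundance), length(x$effects)))
  invisible(x)
}

phred33 <- function(q) intToUtf8(pmin(pmax(q, 2L), 40L) + 33L, multiple = FALSE)

#' Simulate iso-length tag reads from a community
#'
#' Each read is a 32-bp BcgI tag drawn from species `i` with probability
#' proportional to `abundance[i] * n_tags[i]` (tag-count-weighted sampling:
#' more marker loci means proportionally more fragments), uniformly over the
#' species' distinct tags, in a uniformly chosen strand orientation.
#' Per-base substitution errors occur at `error_rate` and N substitutions at
#' `n_rate`; Phred+33 qualities reflect the substitution-error rate, with
#' N bases set to Q2.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundance named numeric vector of relative abundances (>= 0, not
#'   all zero); names must be a subset of the genome names.
#' @param n_reads number of reads to emit.
#' @param error_rate per-base substitution probability, in `[0, 1)`.
#' @param n_rate per-base probability of replacement by N, in `[0, 1)`.
#' @param seed integer seed; output is byte-identical for identical seeds.
#' @return a read set (see [read_set()]) with an attribute `truth` holding
#'   the per-species read counts actually drawn.
#' @export
simulate_reads <- function(genomes, abundance, n_reads = 10000L,
                           error_rate = 0, n_rate = 0, seed = 1L) {
  if (any(abundance < 0)) stop_invalid("abundances must be >= 0")
  if (all(abundance == 0)) stop_invalid("all abundances are zero")
  if (error_rate < 0 || error_rate >= 1 || n_rate < 0 || n_rate >= 1) {
    stop_invalid("error_rate and n_rate must lie in [0, 1)")
  }
  unknown <- setdiff(names(abundance), names(genomes))
  if (length(unknown) > 0L) {
    stop_invalid("abundance names without genomes: %s", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  tags <- digest_all(genomes[names(abundance)])
  w <- abundance * lengths(tags)
  if (sum(w) == 0) stop_invalid("no digestible tags in species with nonzero abundance")
  sp_draw <- sample(names(abundance), n_reads, replace = TRUE, prob = w)
  seqs <- character(n_reads)
  for (s in unique(sp_draw)) {
    idx <- which(sp_draw == s)
    tt <- tags[[s]]
    seqs[idx] <- tt[sample.int(length(tt), length(idx), replace = TRUE)]
  }
  flip <- runif(n_reads) < 0.5
  seqs[flip] <- revcomp(seqs[flip])

  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = BCGI_TAG_LEN)
  n_base <- length(m)
  q <- matrix(if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 40L,
              nrow = BCGI_TAG_LEN, ncol = n_reads)
  touched <- FALSE
  if (error_rate > 0) {
    idx <- which(runif(n_base) < error_rate)
    if (length(idx) > 0L) {
      # substitute with one of the three other bases, uniformly
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"), nrow = 3L,
                    dimnames = list(NULL, c("A","C","G","T")))
      pick <- sample.int(3L, length(idx), replace = TRUE)
      m[idx] <- alt[cbind(pick, match(m[idx], colnames(alt)))]
      touched <- TRUE
    }
  }
  if (n_rate > 0) {
    idx <- which(runif(n_base) < n_rate)
    if (length(idx) > 0L) {
      m[idx] <- "N"
      q[idx] <- 2L
      touched <- TRUE
    }
  }
  if (touched) {
    seqs <- do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
  }
  qconst <- if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 40L
  quals <- rep(phred33(rep(qconst, BCGI_TAG_LEN)), n_reads)
  varied <- which(colSums(q != qconst) > 0L)
  for (j in varied) quals[j] <- phred33(q[, j])
  truth <- table(factor(sp_draw, levels = names(abundance)))
  out <- read_set(sprintf("read%06d", seq_len(n_reads)), seqs, quals)
  attr(out, "truth") <- structure(as.integer(truth), names = names(truth))
  out
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper tying the generator together: taxonomy, genomes, a
#' paired design, and one read set per sample, with a ground-truth manifest.
#'
#' @param n_phyla,n_genera,n_species taxonomy sizes.
#' @param n_subjects subjects (2 samples each).
#' @param effects named fold-change vector passed to [make_paired_design()].
#' @param reads_per_sample reads simulated per sample.
#' @param error_rate,n_rate per-base error rates.
#' @param sigma_lognormal,subject_sd community and subject variation.
#' @param seed master seed; each stage uses a named substream.
#' @return list with `tax`, `genomes`, `design`, and `reads` (named list of
#'   read sets, one per sample).
#' @export
simulate_cohort <- function(n_phyla = 10L, n_genera = 60L, n_species = 300L,
                            n_subjects = 30L, effects = numeric(0),
                            reads_per_sample = 20000L, error_rate = 0.001,
                            n_rate = 0.0005, sigma_lognormal = 1.5,
                            subject_sd = 0.5, seed = 1L) {
  tax <- make_taxonomy(n_phyla, n_genera, n_species,
                       seed = substream_seed(seed, "taxonomy"))
  genomes <- make_genomes(tax, seed = substream_seed(seed, "genomes"))
  design <- make_paired_design(tax$species_id, n_subjects,
                               sigma_lognormal = sigma_lognormal,
                               effects = effects, subject_sd = subject_sd,
                               seed = substream_seed(seed, "design"))
  reads <- lapply(seq_len(ncol(design$abundance)), function(j) {
    ab <- design$abundance[, j]
    simulate_reads(genomes, ab[ab > 0], reads_per_sample, error_rate, n_rate,
                   seed = substream_seed(seed, paste0("reads", j)))
  })
  names(reads) <- colnames(design$abundance)
  list(tax = tax, genomes = genomes, design = design, reads = reads)
}

#' Write a cohort's ground truth as a JSON manifest
#'
#' @param cohort result of [simulate_cohort()].
#' @param path output JSON path.
#' @export
write_truth_manifest <- function(cohort, path) {
  manifest <- list(
    samples = cohort$design$samples,
    effects = as.list(cohort$design$effects),
    abundance = as.data.frame(cohort$design$abundance)
  )
  # 8 significant digits keep the manifest compact; recovery errors of
  # interest are orders of magnitude larger
  jsonlite::write_json(manifest, path, digits = 8, auto_unbox = TRUE)
  invisible(path)
}
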