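#' Assign clean reads to tag-database species
#'
#' A read matches a database tag iff its canonical 32-mer equals the tag
#' exactly (marker identity; error-bearing reads simply go unmatched).  For
#' each species the assignment accumulates `S` (reads hitting any of its
#' tags, repeated hits included) and `t` (distinct tags observed at least
#' once), plus the G score `sqrt(S * t)` used for false-positive screening.
#'
#' @param clean a read set of clean reads.
#' @param db a `tag_db`.
#' @return object of class `tag_counts`: data frame with columns `species`,
#'   `S`, `t`, `G` (species with `S > 0` only), and attributes `n_unmatched`
#'   and `scope`.
#' @export
assign_reads <- function(clean, db) {
  stopifnot(inherits(db, "tag_db"))
  if (length(db$tags) == 0L) stop_invalid("empty tag database")
  clean <- as_read_set(clean)
  key <- canonical_tag(clean$sequence)
  hit <- match(key, names(db$tags))
  matched <- !is.na(hit)
  sp <- db$tags[hit[matched]]
  tag_seq <- names(db$tags)[hit[matched]]
  if (length(sp) == 0L) {
    counts <- data.frame(species = character(0), S = integer(0),
                         t = integer(0), G = numeric(0))
  } else {
    S <- tapply(sp, sp, length)
    t <- tapply(tag_seq, sp[seq_along(tag_seq)], function(x) length(unique(x)))
    species <- names(S)
    counts <- data.frame(
      species = species,
      S = as.integer(S[species]),
      t = as.integer(t[species]),
      stringsAsFactors = FALSE
    )
    counts$G <- g_score(counts$S, counts$t)
    counts <- counts[order(-counts$G, counts$species), , drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(counts, n_unmatched = sum(!matched), scope = db$scope,
            class = c("tag_counts", "data.frame"))
}

#' G score
#'
#' False-positive control statistic for a species detection: `sqrt(S * t)`,
#' where `S` is the number of reads assigned to the species' tags and `t`
#' the number of distinct tags observed.  High values require both read
#' support and tag breadth; isolated read pile-ups on one or two tags score
#' low.
#'
#' @param S,t non-negative counts (vectorised).
#' @return numeric G scores.
#' @export
g_score <- function(S, t) {
  if (any(S < 0) || any(t < 0)) stop_invalid("counts must be non-negative")
  sqrt(S * t)
}

#' Screen candidate species by G score
#'
#' @param counts a `tag_counts` object.
#' @param threshold minimum admissible G score (default 10); the boundary is
#'   inclusive, `G >= threshold` is retained.
#' @return character vector of candidate species ids.
#' @export
screen_candidates <- function(counts, threshold = 10) {
  if (threshold <= 0) stop_invalid("threshold must be > 0")
  counts$species[counts$G >= threshold]
}

#' Relative abundance from tag counts
#'
#' Normalises read counts by marker breadth: species `i` gets
#' `(S_i / T_i) / sum_j (S_j / T_j)`, where `T_i` is the species' total
#' distinct-tag count in the database in force.  Dividing by `T_i` removes
#' the advantage of species that simply carry more marker loci.
#'
#' @param counts a `tag_counts` object.
#' @param db the `tag_db` the counts were computed against (supplies `T`).
#' @return named numeric vector of relative abundances summing to 1
#'   (species with `S = 0` omitted).
#' @export
relative_abundance <- function(counts, db) {
  stopifnot(inherits(db, "tag_db"))
  counts <- counts[counts$S > 0, , drop = FALSE]
  if (nrow(counts) == 0L) stop_invalid("no reads assigned: empty profile")
  T <- db$T[counts$species]
  if (any(is.na(T))) {
    stop_invalid("database lacks T for species: %s",
                 paste(counts$species[is.na(T)], collapse = ", "))
  }
  ratio <- counts$S / T
  structure(ratio / sum(ratio), names = counts$species)
}

#' Two-pass taxonomic profile of one sample
#'
#' Pass 1 assigns the clean reads against the primary database and screens
#' candidate species at the G-score threshold.  Pass 2 rebuilds a
#' sample-specific secondary database over the candidates only — which can
#' only add specific tags per candidate — reassigns all clean reads, and
#' computes relative abundances with the secondary tag totals.
#'
#' @param clean a read set of clean reads.
#' @param primary the primary `tag_db`.
#' @param genomes named genome vector (needed to rebuild the secondary
#'   database).
#' @param g_threshold G-score screening threshold (default 10).
#' @param digests optional precomputed digest list over `genomes` (see
#'   [build_secondary_db()]).
#' @return object of class `species_profile`: list with `sample_id` (NA
#'   unless set by the caller), `abundance` (named vector summing to 1),
#'   `counts` (pass-2 `tag_counts`), `pass1` (pass-1 `tag_counts`),
#'   `candidates`, and `provenance` (`"pass2"`, or `"empty"` when no species
#'   clears the screen).
#' @export
profile_sample <- function(clean, primary, genomes, g_threshold = 10,
                           digests = NULL) {
  pass1 <- assign_reads(clean, primary)
  candidates <- screen_candidates(pass1, g_threshold)
  if (length(candidates) == 0L) {
    warning("no candidate species passed the G-score screen; empty profile")
    return(structure(
      list(sample_id = NA_character_, abundance = numeric(0),
           counts = pass1[0, ], pass1 = pass1, candidates = character(0),
           provenance = "empty"),
      class = "species_profile"
    ))
  }
  secondary <- build_secondary_db(genomes, candidates, digests = digests)
  pass2 <- assign_reads(clean, secondary)
  structure(
    list(sample_id = NA_character_,
         abundance = relative_abundance(pass2, secondary),
         counts = pass2, pass1 = pass1, candidates = candidates,
         provenance = "pass2"),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile [%s]: %d species, top = %s (%.3f)>\n",
              x$provenance, length(x$abundance),
              if (length(x$abundance)) names(which.max(x$abundance)) else "-",
              if (length(x$abundance)) max(x$abundance) else NA_real_))
  invisible(x)
}

#' Profile every sample of a cohort
#'
#' @param reads named list of clean read sets (one per sample).
#' @param primary primary `tag_db`.
#' @param genomes named genome vector.
#' @param g_threshold G-score threshold.
#' @return named list of `species_profile` objects with `sample_id` set.
#' @export
profile_cohort <- function(reads, primary, genomes, g_threshold = 10) {
  digests <- digest_all(genomes)
  out <- lapply(names(reads), function(id) {
    p <- profile_sample(reads[[id]], primary, genomes, g_threshold,
                        digests = digests)
    p$sample_id <- id
    p
  })
  names(out) <- names(reads)
  out
}

#' Species-by-sample abundance matrix from a list of profiles
#'
#' @param profiles list of `species_profile` objects (named by sample).
#' @return numeric matrix, rows = species (union over samples), columns =
#'   samples; absent species are 0.
#' @export
profile_matrix <- function(profiles) {
  species <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundance)))))
  mat <- matrix(0, length(species), length(profiles),
                dimnames = list(species, names(profiles)))
  for (j in seq_along(profiles)) {
    ab <- profiles[[j]]$abundance
    mat[names(ab), j] <- ab
  }
  mat
}

#' Per-sample species read counts (pass-2 S) from profiles
#'
#' Integer read-support matrix used where counts, not proportions, are
#' required (e.g. Chao1 richness).
#'
#' @param profiles list of `species_profile` objects.
#' @return integer matrix, species x samples.
#' @export
count_matrix <- function(profiles) {
  species <- sort(unique(unlist(lapply(profiles, function(p) p$counts$species))))
  mat <- matrix(0L, length(species), length(profiles),
                dimnames = list(species, names(profiles)))
  for (j in seq_along(profiles)) {
    cc <- profiles[[j]]$counts
    mat[cc$species, j] <- cc$S
  }
  mat
}

#' Aggregate a species-level matrix to a higher rank
#'
#' Sums species abundances by lineage; mass is conserved, so per-sample
#' column sums equal the species-level sums.
#'
#' @param mat species x samples abundance matrix.
#' @param tax taxonomy table covering every row of `mat`.
#' @param rank `"species"`, `"genus"` or `"phylum"`.
#' @return taxa x samples matrix at the requested rank.
#' @export
aggregate_ranks <- function(mat, tax, rank = c("species", "genus", "phylum")) {
  rank <- match.arg(rank)
  if (rank == "species") return(mat)
  idx <- match(rownames(mat), tax$species_id)
  if (any(is.na(idx))) {
    stop_invalid("species without lineage: %s",
                 paste(rownames(mat)[is.na(idx)], collapse = ", "))
  }
  group <- tax[[rank]][idx]
  out <- rowsum(mat, group)
  out[order(rownames(out)), , drop = FALSE]
}
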