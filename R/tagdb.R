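#' In-silico BcgI digestion of a genome
#'
#' BcgI is a type IIB restriction enzyme recognising the bipartite site
#' CGA-N6-TGC and cleaving both strands on both sides of it, releasing an
#' iso-length fragment.  The digest model used throughout this package is a
#' 32-bp tag: 10 bp upstream, the 12-bp recognition core (CGA at tag
#' positions 11-13, TGC at 20-22, 1-based), and 10 bp downstream.  Both
#' strands are scanned; each occurrence yields one tag in canonical
#' orientation (the lexicographically smaller of the tag and its reverse
#' complement).  Sites closer than 10 bp to a sequence end are skipped, as
#' are tags containing N.
#'
#' @param sequence a single DNA string over `A/C/G/T/N`.
#' @return character vector of canonical 32-bp tags, one per site occurrence
#'   (duplicates retained).
#' @export
digest_genome <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop_invalid("digest_genome() expects a single DNA string")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop_invalid("sequence contains characters outside A/C/G/T/N")
  }
  n <- nchar(sequence)
  if (n < BCGI_TAG_LEN) return(character(0))
  # forward-strand core and its reverse complement; lookahead keeps
  # overlapping occurrences
  starts <- integer(0)
  for (pat in c("(?=CGA[ACGT]{6}TGC)", "(?=GCA[ACGT]{6}TCG)")) {
    m <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
    if (m[1L] != -1L) starts <- c(starts, as.integer(m))
  }
  if (length(starts) == 0L) return(character(0))
  starts <- sort(starts)
  # core starts at tag position 11, so the tag spans [core-10, core+21]
  tag_start <- starts - (BCGI_CORE_OFFSET - 1L)
  keep <- tag_start >= 1L & tag_start + BCGI_TAG_LEN - 1L <= n
  tag_start <- tag_start[keep]
  if (length(tag_start) == 0L) return(character(0))
  tags <- substring(sequence, tag_start, tag_start + BCGI_TAG_LEN - 1L)
  tags <- tags[!grepl("N", tags, fixed = TRUE)]
  if (length(tags) == 0L) return(character(0))
  canonical_tag(tags)
}

new_tagdb <- function(tags, species, T, scope, candidates = NULL, flagged = character(0)) {
  structure(
    list(
      tags = tags,          # named character: names = tag sequence, values = species_id
      species = species,    # all species considered
      T = T,                # named integer: distinct species-specific tags per species
      scope = scope,        # "primary" or "secondary"
      candidates = candidates,
      flagged = flagged     # species with zero specific tags
    ),
    class = "tag_db"
  )
}

#' @export
print.tag_db <- function(x, ...) {
  cat(sprintf("<tag_db scope=%s: %d tags, %d species (%d without specific tags)>\n",
              x$scope, length(x$tags), length(x$species), length(x$flagged)))
  invisible(x)
}

# Digest every genome and count, per species, each distinct canonical tag once.
digest_all <- function(genomes) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  lapply(genomes, function(g) unique(digest_genome(g)))
}

build_db_from_digests <- function(digests, scope, candidates = NULL) {
  tag <- unlist(digests, use.names = FALSE)
  sp <- rep(names(digests), lengths(digests))
  # species-specific = tag seen in exactly one species (distinct-counted)
  n_species_per_tag <- table(tag)
  specific <- names(n_species_per_tag)[n_species_per_tag == 1L]
  keep <- tag %in% specific
  tags <- structure(sp[keep], names = tag[keep])
  T <- table(factor(tags, levels = names(digests)))
  flagged <- names(T)[T == 0L]
  T <- T[T > 0L]
  new_tagdb(tags, names(digests), structure(as.integer(T), names = names(T)),
            scope, candidates, flagged)
}

#' Build the primary species-specific tag database
#'
#' Digests all genomes and keeps only tags that occur in exactly one species.
#' Per species, duplicate tags within one genome count once, so `T[i]` is the
#' number of distinct species-specific markers of species `i`.  Species for
#' which no tag is specific are flagged and carry no `T` entry.
#'
#' @param genomes named character vector of genome sequences
#'   (species_id -> DNA string).
#' @param tax taxonomy table with a `species_id` column covering every genome.
#' @return a `tag_db` object with fields `tags` (tag -> species_id), `T`
#'   (per-species distinct specific-tag counts), `scope = "primary"` and
#'   `flagged` (species with zero specific tags).
#' @export
build_tagdb <- function(genomes, tax) {
  if (length(genomes) == 0L) stop_invalid("no genomes supplied")
  missing <- setdiff(names(genomes), tax$species_id)
  if (length(missing) > 0L) {
    stop_invalid("species absent from taxonomy: %s", paste(missing, collapse = ", "))
  }
  build_db_from_digests(digest_all(genomes), scope = "primary")
}

#' Build a secondary (sample-specific) tag database over candidate species
#'
#' Tag specificity is recomputed among the candidate species only, so each
#' candidate gains every tag it shares solely with non-candidates; its
#' secondary tag count is therefore at least its primary one.
#'
#' @param genomes named character vector of genome sequences.
#' @param candidates character vector of candidate species ids (non-empty,
#'   subset of the genome names).
#' @param digests optional precomputed per-species digest list (from
#'   digesting `genomes`), reused across samples to avoid repeated scans.
#' @return a `tag_db` with `scope = "secondary"`.
#' @export
build_secondary_db <- function(genomes, candidates, digests = NULL) {
  if (length(candidates) == 0L) stop_invalid("empty candidate list")
  unknown <- setdiff(candidates, names(genomes))
  if (length(unknown) > 0L) {
    stop_invalid("candidates without genomes: %s", paste(unknown, collapse = ", "))
  }
  if (is.null(digests)) digests <- digest_all(genomes[candidates])
  build_db_from_digests(digests[candidates], scope = "secondary",
                        candidates = candidates)
}
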