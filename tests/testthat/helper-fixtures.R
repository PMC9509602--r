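# Hand-constructible BcgI fixtures.
#
# A planted tag is 10 bp of A/T-only left flank, the 12-bp core CGA-<6bp>-TGC,
# and 10 bp of A/T-only right flank.  A/T-only flanks cannot complete a CGA or
# TGC half-site, so each planted tag contains exactly one core, and joining
# tags with poly-A spacers cannot create cores across junctions.  Tag counts
# in genomes assembled this way are therefore known by construction.

make_tag <- function(core6, left = "ATATATATAT", right = "TATATATATA") {
  stopifnot(nchar(core6) == 6, nchar(left) == 10, nchar(right) == 10)
  paste0(left, "CGA", core6, "TGC", right)
}

# distinct 6-mers over {A,C,G,T} indexed deterministically
core6_at <- function(i) {
  b <- c("A", "C", "G", "T")
  idx <- i - 1
  paste(b[(idx %/% 4^(5:0)) %% 4 + 1], collapse = "")
}

assemble_genome <- function(tags, spacer = strrep("A", 15)) {
  paste0(spacer, paste(tags, collapse = spacer), spacer)
}

# genome carrying tags with the given core indices
genome_with_cores <- function(core_idx) {
  assemble_genome(vapply(core_idx, function(i) make_tag(core6_at(i)), ""))
}

# tiny cohort shared across test files; built once per test run
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- urotag::simulate_cohort(
        n_phyla = 3, n_genera = 8, n_species = 20, n_subjects = 6,
        reads_per_sample = 4000, error_rate = 0.001, n_rate = 0.0005,
        effects = c(s0001 = 5), seed = 42
      )
    }
    cache
  }
})

# paired design with planted marker species: `n_signal` species get a fold
# change on the stone side, the rest are exchangeable noise.  Moderate folds
# against sizeable between-subject noise: no single marker separates the
# sides on its own, but the planted set does jointly.
marker_fixture <- function(n_signal = 5, n_noise = 25, n_subjects = 30,
                           fold = 3, subject_sd = 0.8, seed = 1) {
  sp <- sprintf("s%04d", seq_len(n_signal + n_noise))
  effects <- structure(rep(c(fold, 1 / fold), length.out = n_signal),
                       names = sp[seq_len(n_signal)])
  urotag::make_paired_design(sp, n_subjects = n_subjects, effects = effects,
                             subject_sd = subject_sd, seed = seed)
}

labels_of <- function(d) {
  factor(d$samples$side[match(colnames(d$abundance), d$samples$sample_id)],
         levels = c("non_stone", "stone"))
}

# brute-force scan for BcgI cores in both orientations (independent of the
# package's regex-based digestion)
brute_digest <- function(seq) {
  n <- nchar(seq)
  out <- character(0)
  rc1 <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (start in seq_len(max(0, n - 31))) {
    tag <- substr(seq, start, start + 31)
    core <- substr(tag, 11, 22)
    hit <- (substr(core, 1, 3) == "CGA" && substr(core, 10, 12) == "TGC" &&
              !grepl("[^ACGT]", substr(core, 4, 9))) ||
           (substr(core, 1, 3) == "GCA" && substr(core, 10, 12) == "TCG" &&
              !grepl("[^ACGT]", substr(core, 4, 9)))
    if (hit && !grepl("N", tag, fixed = TRUE)) {
      rc <- rc1(tag)
      out <- c(out, if (tag <= rc) tag else rc)
    }
  }
  out
}
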