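# assemble a two-species database plus reads drawn from chosen tags
two_species_db <- function() {
  tax <- data.frame(species_id = c("a", "b"), genus = "g", phylum = "p",
                    stringsAsFactors = FALSE)
  g <- c(a = genome_with_cores(1:10), b = genome_with_cores(11:30))
  list(tax = tax, genomes = g, db = build_tagdb(g, tax))
}

reads_from_tags <- function(tags, times = 1L) {
  seqs <- rep(tags, times)
  read_set(sprintf("r%04d", seq_along(seqs)), seqs, strrep("I", 32))
}

test_that("assign_reads accumulates S, distinct t, and the G score", {
  fx <- two_species_db()
  tags_a <- names(fx$db$tags)[fx$db$tags == "a"]
  # 9 distinct tags, first one read 4x -> S = 12, t = 9
  rs <- reads_from_tags(c(tags_a[1:9], rep(tags_a[1], 3)))
  counts <- assign_reads(rs, fx$db)
  expect_equal(counts$S[counts$species == "a"], 12L)
  expect_equal(counts$t[counts$species == "a"], 9L)
  expect_equal(counts$G[counts$species == "a"], sqrt(12 * 9))
  expect_equal(attr(counts, "n_unmatched"), 0L)

  # reverse-complemented reads still match (canonical comparison)
  rc <- reads_from_tags(revcomp(tags_a[1:5]))
  expect_equal(assign_reads(rc, fx$db)$S, 5L)

  # unmatched reads are tallied, not an error
  noise <- reads_from_tags(make_tag("TTTTTT"))
  cn <- assign_reads(noise, fx$db)
  expect_equal(nrow(cn), 0L)
  expect_equal(attr(cn, "n_unmatched"), 1L)
})

test_that("g_score and candidate screening behave at the boundary", {
  expect_equal(g_score(4, 25), 10)
  expect_equal(g_score(0, 0), 0)
  expect_equal(g_score(50, 2), 10)
  expect_error(g_score(-1, 2), "non-negative")

  counts <- structure(
    data.frame(species = c("x", "y", "z"), S = c(4L, 99L, 2L),
               t = c(25L, 1L, 2L), G = c(10, sqrt(99), sqrt(4))),
    class = c("tag_counts", "data.frame")
  )
  expect_equal(screen_candidates(counts, 10), "x")     # G = 10 retained
  expect_equal(screen_candidates(counts, 9.9), c("x", "y"))
  expect_error(screen_candidates(counts, 0), "> 0")
})

test_that("relative abundance normalises S/T and matches hand ratios", {
  fx <- two_species_db()
  # (S=10, T=10) vs (S=40, T=20): ratios 1 : 2 -> 1/3, 2/3
  tags_a <- names(fx$db$tags)[fx$db$tags == "a"]
  tags_b <- names(fx$db$tags)[fx$db$tags == "b"]
  rs <- reads_from_tags(c(tags_a, rep(tags_b, 2)))
  counts <- assign_reads(rs, fx$db)
  ab <- relative_abundance(counts, fx$db)
  expect_equal(sum(ab), 1)
  expect_equal(unname(ab[c("a", "b")]), c(1, 2) / 3)

  # hand example with fabricated counts: ratios 3 : 1 : 1
  db <- structure(list(tags = character(0), species = c("x", "y", "z"),
                       T = c(x = 2L, y = 2L, z = 1L), scope = "primary"),
                  class = "tag_db")
  cc <- data.frame(species = c("x", "y", "z"), S = c(6L, 2L, 1L), t = c(2L, 2L, 1L))
  expect_equal(unname(relative_abundance(cc, db)[c("x", "y", "z")]),
               c(0.6, 0.2, 0.2))
  expect_error(relative_abundance(cc[cc$S < 0, ], db), "empty profile")
})

test_that("two-pass profiling recovers a single-species sample exactly", {
  fx <- two_species_db()
  tags_a <- names(fx$db$tags)[fx$db$tags == "a"]
  p <- profile_sample(reads_from_tags(tags_a, times = 3L), fx$db, fx$genomes)
  expect_equal(p$provenance, "pass2")
  expect_equal(unname(p$abundance["a"]), 1)
  expect_equal(p$candidates, "a")
})

test_that("with all species as candidates, pass 2 equals pass 1", {
  cohort <- tiny_cohort()
  db <- build_tagdb(cohort$genomes, cohort$tax)
  clean <- qc_sample(cohort$reads[[1]])$reads
  pass1 <- assign_reads(clean, db)
  ab1 <- relative_abundance(pass1, db)
  sec <- build_secondary_db(cohort$genomes, names(cohort$genomes))
  ab2 <- relative_abundance(assign_reads(clean, sec), sec)
  expect_equal(ab2[names(ab1)], ab1, tolerance = 1e-12)
})

test_that("a contaminant below the G-score threshold never enters the profile", {
  fx <- two_species_db()
  tags_a <- names(fx$db$tags)[fx$db$tags == "a"]
  tags_b <- names(fx$db$tags)[fx$db$tags == "b"]
  # 3 spurious reads over 2 tags of b: G = sqrt(6) << 10
  rs <- reads_from_tags(c(rep(tags_a, 2), tags_b[1:2], tags_b[1]))
  p <- profile_sample(rs, fx$db, fx$genomes)
  expect_false("b" %in% names(p$abundance))
  expect_equal(unname(p$abundance["a"]), 1)
})

test_that("profiles sum to one and empty screens warn", {
  cohort <- tiny_cohort()
  db <- build_tagdb(cohort$genomes, cohort$tax)
  clean <- qc_sample(cohort$reads[[2]])$reads
  p <- profile_sample(clean, db, cohort$genomes)
  expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  expect_true(all(p$abundance >= 0))
  expect_true(all(p$counts$t <= p$counts$S))

  noise <- reads_from_tags(make_tag("TTTTTT"))
  expect_warning(pe <- profile_sample(noise, db, cohort$genomes), "empty")
  expect_length(pe$abundance, 0)
})

test_that("rank aggregation conserves mass and is associative", {
  cohort <- tiny_cohort()
  db <- build_tagdb(cohort$genomes, cohort$tax)
  profiles <- profile_cohort(lapply(cohort$reads[1:4], function(r) qc_sample(r)$reads),
                             db, cohort$genomes)
  mat <- profile_matrix(profiles)
  gen <- aggregate_ranks(mat, cohort$tax, "genus")
  phy <- aggregate_ranks(mat, cohort$tax, "phylum")
  expect_equal(colSums(gen), colSums(mat))
  expect_equal(colSums(phy), colSums(mat))
  # simple two-species genus sum
  tax2 <- data.frame(species_id = c("a", "b"), genus = "g1", phylum = "p1")
  m2 <- matrix(c(0.3, 0.7), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(aggregate_ranks(m2, tax2, "genus")[1, 1]), 1)
  # genus -> phylum equals species -> phylum (aggregate the genus matrix by hand)
  g2p <- rowsum(gen, cohort$tax$phylum[match(rownames(gen), cohort$tax$genus)])
  expect_equal(g2p[order(rownames(g2p)), ], phy, ignore_attr = TRUE)
  expect_error(aggregate_ranks(m2, tax2[1, ], "genus"), "lineage")
})
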