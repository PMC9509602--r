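test_that("alpha diversity indices match closed forms", {
  expect_equal(chao1(c(5, 3, 2)), 3)              # no singletons
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 5.5)      # 5 + 2*1/(2*2)
  expect_equal(chao1(1), 1)
  expect_gte(chao1(c(4, 1, 1, 1)), 3)             # Chao1 >= S_obs
  expect_error(chao1(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "integer")

  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(shannon(c(-0.5, 1.5)), "non-negative")

  expect_equal(simpson(rep(0.25, 4)), 0.75)
  expect_equal(simpson(1), 0)
  expect_equal(simpson(c(0.5, 0.5)), 0.5)
})

test_that("diversity indices agree with vegan on random count vectors", {
  set.seed(2)
  for (rep in 1:5) {
    counts <- rpois(25, 2)
    counts[1] <- counts[1] + 1L          # keep at least one nonzero
    props <- counts / sum(counts)
    expect_equal(shannon(props), unname(vegan::diversity(counts, "shannon")))
    expect_equal(simpson(props), unname(vegan::diversity(counts, "simpson")))
    expect_equal(chao1(counts), unname(vegan::estimateR(counts)["S.chao1"]))
  }
})

test_that("distance metrics satisfy their definitions and bounds", {
  mat <- matrix(c(2, 1, 0, 1, 1, 1), nrow = 3,
                dimnames = list(c("t1", "t2", "t3"), c("x", "y")))
  bc <- distance_matrix(mat, "bray_curtis")
  expect_equal(as.numeric(bc), 1 / 3)             # sum|x-y| / sum(x+y) = 2/6

  same <- cbind(x = c(1, 2, 3), y = c(1, 2, 3))
  rownames(same) <- paste0("t", 1:3)
  for (m in c("bray_curtis", "jaccard_binary", "euclidean")) {
    expect_equal(as.numeric(distance_matrix(same, m)), 0)
  }
  disj <- cbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1))
  rownames(disj) <- paste0("t", 1:4)
  expect_equal(as.numeric(distance_matrix(disj, "bray_curtis")), 1)
  expect_equal(as.numeric(distance_matrix(disj, "jaccard_binary")), 1)

  set.seed(1)
  rnd <- matrix(runif(50), 10, 5, dimnames = list(paste0("t", 1:10), paste0("s", 1:5)))
  for (m in c("bray_curtis", "jaccard_binary")) {
    d <- as.matrix(distance_matrix(rnd, m))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  expect_error(distance_matrix(rnd, "manhattan"))
  expect_error(distance_matrix(rnd[, 1, drop = FALSE], "euclidean"), "two samples")
})

procrustes_error <- function(X, Y) {
  # symmetric Procrustes residual (rotation/reflection + scaling)
  vegan::procrustes(X, Y, symmetric = TRUE)$ss
}

test_that("PCoA on Euclidean distances recovers the configuration", {
  set.seed(7)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  d <- dist(pts)
  fit <- pcoa(d, n_axes = 3)
  expect_lt(procrustes_error(pts, fit$coordinates), 1e-8)
  # eigenvalues sorted decreasing; non-trivial negative part absent here
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))
  # coincident samples land on coincident points
  m <- matrix(c(0, 0, 5, 0, 0, 5), nrow = 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  m <- cbind(m, s4 = m[, "s3"])
  f2 <- pcoa(distance_matrix(m, "euclidean"), 2)
  expect_equal(f2$coordinates["s3", ], f2$coordinates["s4", ])
  # equilateral triangle: two equal positive eigenvalues
  deq <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  feq <- pcoa(deq, 3)
  pos <- feq$eigenvalues[feq$eigenvalues > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2])
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA statistic matches vegan and extremes behave", {
  set.seed(21)
  mat <- matrix(abs(rnorm(20 * 12)), 20, 12,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:12)))
  labels <- rep(c("a", "b"), each = 6)
  d <- distance_matrix(mat, "bray_curtis")
  res <- permanova(d, labels, n_perm = 99, seed = 5)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = labels), permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)

  # widely separated clouds: maximal significance on the permutation grid
  # (10 + 10 samples, so a sampled permutation reproducing the grouping is
  # vanishingly unlikely)
  sep <- cbind(matrix(abs(rnorm(10 * 10)), 10, 10),
               matrix(abs(rnorm(10 * 10)) + 50, 10, 10))
  dimnames(sep) <- list(paste0("t", 1:10), paste0("s", 1:20))
  dsep <- distance_matrix(sep, "euclidean")
  rsep <- permanova(dsep, rep(c("a", "b"), each = 10), n_perm = 199, seed = 1)
  expect_equal(rsep$p_value, 1 / 200)

  # permuting sample order leaves F unchanged
  perm <- sample(12)
  res2 <- permanova(as.dist(as.matrix(d)[perm, perm]), labels[perm],
                    n_perm = 9, seed = 2)
  expect_equal(res2$pseudo_F, res$pseudo_F)

  expect_error(permanova(d, rep(c("a", "b"), c(1, 11)), 99), ">= 2")
})

test_that("stratified permutations stay within subject", {
  set.seed(9)
  mat <- matrix(abs(rnorm(8 * 8)), 8, 8,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:8)))
  d <- distance_matrix(mat, "euclidean")
  labels <- rep(c("a", "b"), 4)
  strata <- rep(paste0("subj", 1:4), each = 2)
  res <- permanova(d, labels, n_perm = 49, strata = strata, seed = 3)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("venn summaries reproduce set arithmetic", {
  vAB <- venn_summary(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(vAB$pct[vAB$part == "shared"], 100)

  v <- venn_from_counts(181, 77, 193)
  expect_equal(attr(v, "n_union"), 451L)
  expect_equal(v$pct, c(40.13, 17.07, 42.79))

  vd <- venn_summary(c("x", "y"), c("p", "q", "r"))
  expect_equal(vd$pct, c(0, 40, 60))
  expect_equal(sum(vd$n), 5L)
})

test_that("alpha table covers every sample with both count and proportion inputs", {
  counts <- matrix(c(5, 1, 1, 0, 2, 2, 3, 1), 4, 2,
                   dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  mat <- apply(counts, 2, function(x) x / sum(x))
  at <- alpha_table(counts, mat)
  expect_equal(at$sample_id, c("s1", "s2"))
  expect_equal(at$chao1[1], chao1(counts[, 1]))
  expect_equal(at$shannon[2], shannon(mat[, 2] / sum(mat[, 2])))
})
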