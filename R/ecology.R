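#' Alpha diversity indices
#'
#' Bias-corrected Chao1 richness from integer read counts, and Shannon
#' (natural log) and Gini-Simpson diversity from proportions.
#'
#' `chao1(x) = S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1` singletons
#' and `F2` doubletons; it needs genuine counts, not rescaled proportions.
#'
#' @param counts non-negative integer vector of per-species read counts.
#' @return a single numeric index value.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_invalid("chao1 needs non-negative integer counts")
  }
  if (all(counts == 0)) stop_invalid("chao1 undefined on an all-zero vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname chao1
#' @param props proportions summing to 1.
#' @export
shannon <- function(props) {
  if (any(props < 0)) stop_invalid("proportions must be non-negative")
  if (abs(sum(props) - 1) > 1e-6) stop_invalid("proportions must sum to 1")
  p <- props[props > 0]
  -sum(p * log(p))
}

#' @rdname chao1
#' @export
simpson <- function(props) {
  if (any(props < 0)) stop_invalid("proportions must be non-negative")
  if (abs(sum(props) - 1) > 1e-6) stop_invalid("proportions must sum to 1")
  1 - sum(props^2)
}

#' Per-sample alpha-diversity table
#'
#' @param counts species x samples integer matrix (read support).
#' @param mat species x samples abundance matrix.
#' @return data frame with one row per sample: `sample_id`, `chao1`,
#'   `shannon`, `simpson`.
#' @export
alpha_table <- function(counts, mat) {
  data.frame(
    sample_id = colnames(mat),
    chao1 = apply(counts, 2L, chao1),
    shannon = apply(mat, 2L, function(p) shannon(p / sum(p))),
    simpson = apply(mat, 2L, function(p) simpson(p / sum(p))),
    row.names = NULL
  )
}

#' Pairwise sample distances
#'
#' Bray-Curtis and Euclidean distances on abundances, and binary Jaccard on
#' presence/absence, computed with `vegan::vegdist`.
#'
#' @param mat taxa x samples abundance matrix.
#' @param metric one of `"bray_curtis"`, `"jaccard_binary"`, `"euclidean"`.
#' @return a `dist` object over samples with attribute `metric`.
#' @export
distance_matrix <- function(mat, metric = c("bray_curtis", "jaccard_binary", "euclidean")) {
  metric <- match.arg(metric)
  if (ncol(mat) < 2L) stop_invalid("need at least two samples")
  x <- t(mat)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(x, method = "bray"),
    jaccard_binary = vegan::vegdist(x, method = "jaccard", binary = TRUE),
    euclidean = vegan::vegdist(x, method = "euclidean")
  )
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-D^2 / 2` and
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues.  Negative eigenvalues are reported
#' untouched and carry no coordinates.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param n_axes number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all of
#'   them, decreasing) and `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d, n_axes = 3L) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop_invalid("distance matrix must be symmetric")
  n <- nrow(m)
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are an expected, reported outcome here
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > 1e-8 * max(abs(eig), 1))
  k <- min(n_axes, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = if (pos > 0) eig[seq_len(k)] / sum(eig[eig > 0]) else numeric(0)
  )
}

#' Two-group PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix: the
#' pseudo-F statistic compares between- to within-group sums of squared
#' distances, and its null distribution is obtained by permuting group
#' labels.  The p-value convention is `(1 + #{F_perm >= F_obs}) / (1 +
#' n_perm)`.  Labels are freely permuted by default; with `strata` the
#' permutation swaps labels only within subject, respecting a paired layout.
#'
#' @param d a `dist` object over samples.
#' @param labels group factor (two or more groups, each with >= 2 samples).
#' @param n_perm number of permutations (default 999).
#' @param strata optional vector of subject ids to restrict permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `pseudo_F`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999L, strata = NULL, seed = 1L) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_invalid("need >= 2 groups with >= 2 samples each")
  }
  m <- as.matrix(d)
  n <- nrow(m)
  if (length(labels) != n) stop_invalid("labels length must match the distance matrix")
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  a <- length(tab)
  f_stat <- function(lab) {
    ss_within <- 0
    for (g in levels(lab)) {
      idx <- which(lab == g)
      ss_within <- ss_within + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_stat(labels)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- if (is.null(strata)) {
      sample.int(n)
    } else {
      p <- seq_len(n)
      for (s in unique(strata)) {
        idx <- which(strata == s)
        p[idx] <- idx[sample.int(length(idx))]
      }
      p
    }
    if (f_stat(labels[perm]) >= f_obs) count <- count + 1L
  }
  list(pseudo_F = f_obs, p_value = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Shared and unique species between two groups
#'
#' Venn partition of two detected-species sets, with percentages of the
#' union rounded to two decimals.
#'
#' @param detected_A,detected_B character vectors (or sets) of species
#'   detected in each group.
#' @return data frame with rows `shared`, `only_A`, `only_B`: columns
#'   `n` and `pct` (of the union), plus attribute `n_union`.
#' @export
venn_summary <- function(detected_A, detected_B) {
  A <- unique(detected_A)
  B <- unique(detected_B)
  n_shared <- length(intersect(A, B))
  n_only_A <- length(setdiff(A, B))
  n_only_B <- length(setdiff(B, A))
  venn_from_counts(n_shared, n_only_A, n_only_B)
}

#' @rdname venn_summary
#' @param n_shared,n_only_A,n_only_B partition counts, when the sets
#'   themselves are not available.
#' @export
venn_from_counts <- function(n_shared, n_only_A, n_only_B) {
  n_union <- n_shared + n_only_A + n_only_B
  n <- c(shared = n_shared, only_A = n_only_A, only_B = n_only_B)
  pct <- if (n_union > 0) round(100 * n / n_union, 2) else rep(0, 3)
  structure(
    data.frame(part = names(n), n = as.integer(n), pct = as.numeric(pct),
               row.names = NULL),
    n_union = as.integer(n_union)
  )
}
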