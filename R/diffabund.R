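#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on within-subject differences.  Zero
#' differences are dropped; the exact null distribution is used when the
#' number of nonzero differences is at most 25 and there are no tied
#' absolute differences, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y paired numeric vectors (same length, same subject order).
#' @return list with `statistic` (V, sum of positive ranks), `p_value` and
#'   `n_nonzero`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop_invalid("all paired differences are zero: test undefined")
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, paired = FALSE, exact = exact,
                       correct = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_nonzero = length(d))
}

#' Paired differential-abundance table
#'
#' For every taxon at the requested rank, compares its relative abundance on
#' the two sides across subjects with the paired Wilcoxon test and reports
#' the group mean relative abundances in percent, the raw two-sided p-value
#' (no multiple-testing correction), and the direction of the higher group
#' mean.  Taxa whose paired differences are all zero are reported with
#' `p_value = NA`.
#'
#' @param mat taxa x samples abundance matrix (proportions).
#' @param samples design data frame with `sample_id`, `subject_id`, `side`
#'   (`"stone"` / `"non_stone"`); every subject needs exactly one sample per
#'   side.
#' @param alpha significance level used for the `flagged` column (default
#'   0.05).
#' @return data frame, one row per taxon: `taxon`, `mean_stone_pct`,
#'   `mean_non_stone_pct`, `statistic`, `p_value`, `direction`, `flagged`,
#'   ordered by p-value.
#' @export
differential_table <- function(mat, samples, alpha = 0.05) {
  layout <- check_paired_layout(mat, samples)
  out <- lapply(rownames(mat), function(tx) {
    xs <- mat[tx, layout$stone]
    ys <- mat[tx, layout$non_stone]
    res <- tryCatch(paired_wilcoxon(xs, ys),
                    error = function(e) list(statistic = NA_real_, p_value = NA_real_))
    data.frame(
      taxon = tx,
      mean_stone_pct = 100 * mean(xs),
      mean_non_stone_pct = 100 * mean(ys),
      statistic = res$statistic,
      p_value = res$p_value,
      direction = if (mean(xs) >= mean(ys)) "stone" else "non_stone",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$flagged <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_paired_layout <- function(mat, samples) {
  stopifnot(all(c("sample_id", "subject_id", "side") %in% names(samples)))
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id))) {
    stop_invalid("abundance matrix has samples absent from the design")
  }
  per_subj <- table(samples$subject_id, samples$side)
  bad <- rownames(per_subj)[rowSums(per_subj == 1L) != 2L]
  if (length(bad) > 0L) {
    stop_invalid("incomplete pair for subject %s", bad[1L])
  }
  subjects <- sort(unique(samples$subject_id))
  pick <- function(side) {
    vapply(subjects, function(s)
      samples$sample_id[samples$subject_id == s & samples$side == side], "")
  }
  list(subjects = subjects, stone = pick("stone"), non_stone = pick("non_stone"))
}

#' Linear-discriminant effect sizes (LEfSe-style)
#'
#' Two-stage screen for discriminative taxa between two classes.  Stage 1
#' keeps features with a Kruskal-Wallis p-value below `alpha`.  Stage 2
#' rescales each sample to a total of 1e6, then repeatedly (`n_boot` times)
#' draws class-balanced subsamples of two-thirds of the data, fits a
#' single-discriminant linear discriminant analysis on the surviving
#' features, and measures each feature's effect as the average of its raw
#' between-class mean difference and its difference along the discriminant
#' axis.  The effect size is `sign * log10(1 + |mean effect|)`; features
#' with `|score| >= lda_threshold` are reported.
#'
#' @param mat taxa x samples abundance matrix (proportions).
#' @param labels two-class factor over the columns of `mat` (>= 3 samples
#'   per class).
#' @param alpha stage-1 significance level (default 0.05).
#' @param lda_threshold reporting threshold on the log10 score (default 2).
#' @param n_boot number of subsample rounds (default 30).
#' @param seed integer seed.
#' @return data frame with one row per reported taxon: `taxon`,
#'   `enriched_group`, `lda_score` (signed log10 scale), `kw_p`; ordered by
#'   decreasing `|lda_score|`.
#' @export
lda_effect_size <- function(mat, labels, alpha = 0.05, lda_threshold = 2.0,
                            n_boot = 30L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop_invalid("exactly two classes required")
  if (any(table(labels) < 3L)) stop_invalid("each class needs >= 3 samples")
  kw_p <- apply(mat, 1L, function(v) {
    if (length(unique(v)) == 1L) return(1)
    stats::kruskal.test(v, labels)$p.value
  })
  survivors <- rownames(mat)[kw_p < alpha]
  empty <- data.frame(taxon = character(0), enriched_group = character(0),
                      lda_score = numeric(0), kw_p = numeric(0))
  if (length(survivors) == 0L) return(empty)
  x <- t(mat[survivors, , drop = FALSE]) * 1e6   # per-sample total 1e6 scale
  colnames(x) <- survivors
  set.seed(seed)
  g1 <- levels(labels)[1L]
  g2 <- levels(labels)[2L]
  eff <- matrix(NA_real_, n_boot, length(survivors),
                dimnames = list(NULL, survivors))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(levels(labels), function(g) {
      ig <- which(labels == g)
      sample(ig, max(3L, floor(2 * length(ig) / 3)))
    }))
    xs <- x[idx, , drop = FALSE]
    ls <- labels[idx]
    raw_diff <- colMeans(xs[ls == g1, , drop = FALSE]) -
      colMeans(xs[ls == g2, , drop = FALSE])
    proj_diff <- tryCatch({
      keep <- apply(xs, 2L, function(v) stats::var(v) > 0)
      if (!any(keep)) stop("degenerate")
      fit <- suppressWarnings(MASS::lda(xs[, keep, drop = FALSE], grouping = ls))
      w <- fit$scaling[, 1L]
      w <- w / sqrt(sum(w^2))
      pd <- raw_diff
      # feature's contribution along the discriminant, mapped back to
      # feature units so the two summands share a scale
      pd[] <- 0
      pd[names(w)] <- abs(w) * sum(raw_diff[names(w)] * w)
      pd
    }, error = function(e) raw_diff)
    eff[b, ] <- (abs(raw_diff) + abs(proj_diff)) / 2 * sign(raw_diff)
  }
  mean_eff <- colMeans(eff)
  score <- sign(mean_eff) * log10(1 + abs(mean_eff))
  keep <- abs(score) >= lda_threshold
  if (!any(keep)) return(empty)
  out <- data.frame(
    taxon = survivors[keep],
    enriched_group = ifelse(mean_eff[keep] > 0, g1, g2),
    lda_score = score[keep],
    kw_p = kw_p[survivors][keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$lda_score)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix of the most abundant taxa
#'
#' Selects the `top_n` taxa by mean relative abundance and computes
#' tie-corrected Spearman correlations and two-sided p-values for every
#' pair.  Pairs involving a constant taxon are returned as `NA`.
#'
#' @param mat taxa x samples abundance matrix (>= 3 samples).
#' @param top_n number of taxa to keep (default 30; capped at `nrow(mat)`).
#' @return list with `rho` and `p` (symmetric matrices over the selected
#'   taxa; unit diagonal on `rho`).
#' @export
spearman_matrix <- function(mat, top_n = 30L) {
  if (ncol(mat) < 3L) stop_invalid("need >= 3 samples")
  sel <- names(sort(rowMeans(mat), decreasing = TRUE))[seq_len(min(top_n, nrow(mat)))]
  x <- mat[sel, , drop = FALSE]
  k <- length(sel)
  rho <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(sel, sel)
  diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (stats::var(x[i, ]) == 0 || stats::var(x[j, ]) == 0) {
        rho[i, j] <- rho[j, i] <- NA_real_
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[i, ], x[j, ], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}
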