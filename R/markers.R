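#' Rank candidate marker species by random-forest importance
#'
#' Restricts attention to the `top_n` most abundant species (overall mean
#' relative abundance), trains a random forest (bootstrap trees, `sqrt(p)`
#' features per split, Gini impurity) on the class labels, and returns the
#' candidates ordered by decreasing mean decrease in Gini importance.
#'
#' @param mat species x samples abundance matrix.
#' @param labels two-class factor over samples (>= 2 per class).
#' @param top_n candidate pool size (default 30).
#' @param n_trees trees in the forest (default 500).
#' @param seed integer seed.
#' @return character vector of candidate species, most important first.
#' @export
rank_features <- function(mat, labels, top_n = 30L, n_trees = 500L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    stop_invalid("two classes with >= 2 samples each required")
  }
  pool <- names(sort(rowMeans(mat), decreasing = TRUE))[seq_len(min(top_n, nrow(mat)))]
  x <- t(mat[pool, , drop = FALSE])
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = n_trees, importance = FALSE)
  imp <- randomForest::importance(rf, type = 2L)[, 1L]
  names(sort(imp, decreasing = TRUE))
}

make_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (g in levels(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(sample(folds), length(idx))
  }
  fold
}

#' Cross-validation error curve over nested marker sets
#'
#' For each `k`, trains a random forest on the top-`k` species of a fixed
#' global importance ranking under repeated stratified k-fold
#' cross-validation, and records the mean misclassification error together
#' with its standard deviation across repeats.
#'
#' @param mat species x samples abundance matrix.
#' @param labels two-class factor.
#' @param ranking character vector of species, most important first.
#' @param folds number of CV folds (default 10).
#' @param repeats number of CV repeats (default 10).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return data frame with columns `k`, `error` (mean across repeats), `sd`
#'   (across repeats).
#' @export
cv_error_curve <- function(mat, labels, ranking, folds = 10L, repeats = 10L,
                           n_trees = 500L, seed = 1L) {
  if (length(ranking) == 0L) stop_invalid("empty ranking")
  labels <- as.factor(labels)
  if (min(table(labels)) < folds) {
    folds <- max(2L, min(table(labels)))
  }
  x_all <- t(mat[ranking, , drop = FALSE])
  n <- nrow(x_all)
  err <- matrix(NA_real_, repeats, length(ranking))
  for (r in seq_len(repeats)) {
    fold <- make_folds(labels, folds, seed = substream_seed(seed, paste0("fold", r)))
    for (k in seq_along(ranking)) {
      xk <- x_all[, seq_len(k), drop = FALSE]
      pred <- factor(rep(NA_character_, n), levels = levels(labels))
      for (f in seq_len(folds)) {
        test <- fold == f
        if (!any(test)) next
        if (length(unique(labels[!test])) < 2L) {
          stop_invalid("a training fold contains one class only")
        }
        set.seed(substream_seed(seed, sprintf("rf%d_%d_%d", r, k, f)))
        rf <- randomForest::randomForest(xk[!test, , drop = FALSE], labels[!test],
                                         ntree = n_trees)
        pred[test] <- predict(rf, xk[test, , drop = FALSE])
      }
      err[r, k] <- mean(pred != labels)
    }
  }
  data.frame(k = seq_along(ranking),
             error = colMeans(err),
             sd = apply(err, 2L, sd))
}

#' Optimal marker set from a CV error curve
#'
#' The cut-off value is the minimum mean CV error plus the standard
#' deviation at that minimum; among all set sizes whose error beats the
#' cut-off, the smallest is chosen.  (When the SD at the minimum is zero,
#' only the minimum itself qualifies.)
#'
#' @param curve data frame with columns `k`, `error`, `sd`.
#' @param ranking the global importance ranking the curve was computed on.
#' @return list with `k_star`, `cutoff`, and `optimal_set` (top `k_star`
#'   species of `ranking`).
#' @export
select_optimal_set <- function(curve, ranking) {
  if (nrow(curve) == 0L) stop_invalid("empty curve")
  i_min <- which.min(curve$error)
  cutoff <- curve$error[i_min] + curve$sd[i_min]
  ok <- curve$error < cutoff | curve$error == curve$error[i_min]
  k_star <- curve$k[which(ok)[1L]]
  list(k_star = k_star, cutoff = cutoff,
       optimal_set = head(ranking, k_star))
}

#' Train the marker model and compute per-sample POD indices
#'
#' Trains a random forest on the optimal marker set and scores each sample
#' with the probability-of-disease (POD) index: the fraction of trees voting
#' for the stone-side class.  Training samples are scored with their
#' out-of-bag votes, avoiding resubstitution optimism.
#'
#' @param mat species x samples abundance matrix.
#' @param labels two-class factor; `positive` names the disease class.
#' @param optimal_set species to train on.
#' @param positive label of the disease (stone-side) class.
#' @param n_trees trees (default 500).
#' @param seed integer seed.
#' @return list with `model` (the forest), `pod` (named numeric vector in
#'   `[0, 1]` over samples) and `positive`.
#' @export
pod_model <- function(mat, labels, optimal_set, positive = "stone",
                      n_trees = 500L, seed = 1L) {
  labels <- as.factor(labels)
  if (!positive %in% levels(labels)) stop_invalid("positive class '%s' not in labels", positive)
  x <- t(mat[optimal_set, , drop = FALSE])
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = n_trees)
  votes <- rf$votes  # out-of-bag vote fractions
  pod <- votes[, positive]
  no_oob <- !is.finite(pod)
  if (any(no_oob)) {
    # sample never out of bag: fall back to full-ensemble vote
    warning(sprintf("%d sample(s) had no out-of-bag trees; using full-ensemble votes", sum(no_oob)))
    full <- predict(rf, x[no_oob, , drop = FALSE], type = "vote")
    pod[no_oob] <- full[, positive]
  }
  names(pod) <- rownames(x)
  list(model = rf, pod = pod, positive = positive)
}

#' POD index of new samples under a trained marker model
#'
#' @param model result of [pod_model()].
#' @param mat species x samples abundance matrix containing the model's
#'   marker species.
#' @return named numeric vector of POD values in `[0, 1]`.
#' @export
pod_index <- function(model, mat) {
  x <- t(mat[rownames(model$model$importance), , drop = FALSE])
  votes <- predict(model$model, x, type = "vote")
  votes[, model$positive]
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction — the
#' probability that a random positive scores above a random negative, ties
#' counting one half — and the ROC as a step curve over score thresholds.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels two-class vector; `positive` names the positive class.
#' @param positive positive class label.
#' @return list with `auc` and `roc` (data frame of `fpr`, `tpr` points).
#' @export
roc_auc <- function(scores, labels, positive = "stone") {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop_invalid("exactly two classes required")
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) stop_invalid("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- t(vapply(thr, function(s) {
    c(fpr = sum(scores[!is_pos] >= s) / n0, tpr = sum(scores[is_pos] >= s) / n1)
  }, c(fpr = 0, tpr = 0)))
  list(auc = auc, roc = as.data.frame(roc))
}

#' Full marker-selection workflow
#'
#' Ranks features, builds the CV error curve, applies the minimum-error +
#' SD smallest-set rule, trains the POD model on the optimal set, and
#' evaluates it by ROC/AUC and a paired Wilcoxon test on POD between sides.
#'
#' @param mat species x samples abundance matrix.
#' @param samples paired design data frame (`sample_id`, `subject_id`,
#'   `side`).
#' @param top_n candidate pool (default 30).
#' @param folds,repeats CV layout (defaults 10 and 10).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return list with `ranking`, `curve`, `k_star`, `optimal_set`, `pod`,
#'   `auc`, `roc`, `pod_p` (paired Wilcoxon p-value on POD).
#' @export
marker_workflow <- function(mat, samples, top_n = 30L, folds = 10L,
                            repeats = 10L, n_trees = 500L, seed = 1L) {
  labels <- factor(samples$side[match(colnames(mat), samples$sample_id)],
                   levels = c("non_stone", "stone"))
  ranking <- rank_features(mat, labels, top_n = top_n, n_trees = n_trees,
                           seed = substream_seed(seed, "rank"))
  curve <- cv_error_curve(mat, labels, ranking, folds = folds,
                          repeats = repeats, n_trees = n_trees,
                          seed = substream_seed(seed, "cv"))
  sel <- select_optimal_set(curve, ranking)
  model <- pod_model(mat, labels, sel$optimal_set, positive = "stone",
                     n_trees = n_trees, seed = substream_seed(seed, "pod"))
  ra <- roc_auc(model$pod, labels, positive = "stone")
  layout <- check_paired_layout(mat, samples)
  pod_p <- paired_wilcoxon(model$pod[layout$stone], model$pod[layout$non_stone])$p_value
  list(ranking = ranking, curve = curve, k_star = sel$k_star,
       optimal_set = sel$optimal_set, pod = model$pod, auc = ra$auc,
       roc = ra$roc, pod_p = pod_p, model = model)
}
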