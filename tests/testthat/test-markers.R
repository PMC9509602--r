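test_that("a perfectly separating feature is ranked first", {
  set.seed(5)
  d <- make_paired_design(sprintf("s%04d", 1:20), n_subjects = 15, seed = 6)
  ab <- d$abundance
  lab <- labels_of(d)
  ab["s0003", ] <- ifelse(lab == "stone", 0.30, 0.05) + runif(30, 0, 0.001)
  ab <- apply(ab, 2, function(x) x / sum(x))
  ranking <- rank_features(ab, lab, top_n = 20, seed = 7)
  expect_equal(ranking[1], "s0003")
  expect_identical(ranking, rank_features(ab, lab, top_n = 20, seed = 7))
  expect_error(rank_features(ab, rep("x", 30)), "two classes")
})

test_that("optimal-set rule: minimum error + SD, smallest qualifying size", {
  ranking <- paste0("m", 1:10)
  curve <- data.frame(k = c(1, 5, 10), error = c(0.40, 0.10, 0.12),
                      sd = c(0.02, 0.05, 0.03))
  sel <- select_optimal_set(curve, ranking)
  expect_equal(sel$cutoff, 0.15)
  expect_equal(sel$k_star, 5)
  expect_equal(sel$optimal_set, paste0("m", 1:5))

  # SD zero at the minimum: only the minimum itself qualifies
  mono <- data.frame(k = 1:4, error = c(0.4, 0.3, 0.2, 0.1), sd = 0)
  expect_equal(select_optimal_set(mono, ranking)$k_star, 4)

  # all errors equal with positive SD: every size qualifies, smallest wins
  flat <- data.frame(k = 1:4, error = 0.2, sd = 0.05)
  expect_equal(select_optimal_set(flat, ranking)$k_star, 1)

  # scale-free: multiplying errors and SDs by c > 0 leaves k_star unchanged
  curve2 <- transform(curve, error = error * 7, sd = sd * 7)
  expect_equal(select_optimal_set(curve2, ranking)$k_star, sel$k_star)
  expect_error(select_optimal_set(curve[0, ], ranking), "empty")
})

test_that("CV error curve has the right shape and sane error levels", {
  d <- marker_fixture(n_signal = 2, n_noise = 8, n_subjects = 12, fold = 8,
                      subject_sd = 0.3, seed = 9)
  lab <- labels_of(d)
  ranking <- rank_features(d$abundance, lab, top_n = 10, n_trees = 100, seed = 2)
  curve <- cv_error_curve(d$abundance, lab, ranking, folds = 4, repeats = 3,
                          n_trees = 100, seed = 3)
  expect_equal(curve$k, 1:10)
  expect_true(all(curve$sd >= 0))
  expect_true(all(curve$error >= 0 & curve$error <= 1))
  # strong planted signal: errors well below the 0.5 coin-flip baseline
  expect_lt(min(curve$error), 0.25)
})

test_that("pure-noise features cross-validate near the coin-flip baseline", {
  d <- make_paired_design(sprintf("s%04d", 1:10), n_subjects = 12,
                          subject_sd = 0.3, seed = 10)
  # break the exact side symmetry with independent per-sample jitter
  ab <- d$abundance * matrix(exp(rnorm(length(d$abundance), 0, 0.3)),
                             nrow(d$abundance))
  ab <- apply(ab, 2, function(x) x / sum(x))
  dimnames(ab) <- dimnames(d$abundance)
  lab <- labels_of(d)
  ranking <- rank_features(ab, lab, top_n = 10, n_trees = 100, seed = 4)
  curve <- cv_error_curve(ab, lab, ranking, folds = 4, repeats = 3,
                          n_trees = 100, seed = 5)
  expect_gt(mean(curve$error), 0.3)
})

test_that("POD is a bounded vote fraction, antisymmetric under label swap", {
  d <- marker_fixture(seed = 11)
  lab <- labels_of(d)
  model <- pod_model(d$abundance, lab, rownames(d$abundance)[1:5],
                     positive = "stone", n_trees = 201, seed = 12)
  expect_true(all(model$pod >= 0 & model$pod <= 1))
  # POD of the opposite class is the complementary vote fraction
  model2 <- pod_model(d$abundance, lab, rownames(d$abundance)[1:5],
                      positive = "non_stone", n_trees = 201, seed = 12)
  expect_equal(model$pod + model2$pod, rep(1, length(model$pod)),
               ignore_attr = TRUE)
  # scoring new samples through the trained forest
  pod_new <- pod_index(model, d$abundance[, 1:4])
  expect_length(pod_new, 4)
  expect_true(all(pod_new >= 0 & pod_new <= 1))
  expect_error(pod_model(d$abundance, lab, "s0001", positive = "zz"), "positive")
})

test_that("AUC equals the concordant-pair fraction (brute-force oracle)", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c("stone", "stone", "non_stone", "non_stone"))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2), c("stone", "stone", "non_stone", "non_stone"))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("stone", "non_stone"), 3))$auc, 0.5)

  brute_auc <- function(scores, pos) {
    num <- 0; den <- 0
    for (i in which(pos)) for (j in which(!pos)) {
      den <- den + 1
      num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    num / den
  }
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(runif(n), 1)          # rounding forces occasional ties
    labels <- ifelse(pos, "stone", "non_stone")
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, pos))
  }
  expect_error(roc_auc(1:3, rep("stone", 3)), "two classes")
})

test_that("ROC points are a valid step curve", {
  ra <- roc_auc(c(0.9, 0.7, 0.7, 0.3, 0.1), c("stone", "stone", "non_stone", "non_stone", "non_stone"))
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[1], 0)
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  # cross-check AUC against pROC on the same scores
  pr <- pROC::roc(response = c(1, 1, 0, 0, 0), predictor = c(0.9, 0.7, 0.7, 0.3, 0.1),
                  quiet = TRUE, direction = "<")
  expect_equal(ra$auc, as.numeric(pROC::auc(pr)))
})

test_that("the full marker workflow recovers planted markers discriminatively", {
  d <- marker_fixture(n_signal = 5, n_noise = 25, n_subjects = 30, fold = 6, seed = 14)
  res <- marker_workflow(d$abundance, d$samples, top_n = 30, folds = 5,
                         repeats = 3, n_trees = 150, seed = 15)
  expect_gte(res$auc, 0.9)
  expect_gte(sum(sprintf("s%04d", 1:5) %in% res$optimal_set), 3)
  expect_lt(res$pod_p, 0.05)
  expect_equal(length(res$optimal_set), res$k_star)
})
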