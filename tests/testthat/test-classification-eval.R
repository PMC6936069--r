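# two Gaussian clusters in feature space, separation controlled by delta
toy_fm <- function(n_per_class, F, delta, seed) {
  X <- withr::with_seed(seed, {
    rbind(matrix(rnorm(n_per_class * F, 0), n_per_class, F),
          matrix(rnorm(n_per_class * F, delta), n_per_class, F))
  })
  colnames(X) <- paste0("f", seq_len(F))
  rownames(X) <- paste0("S", seq_len(2 * n_per_class))
  structure(list(features = X, feature_names = colnames(X),
                 subjects = rownames(X),
                 labels = rep(c(0L, 1L), each = n_per_class)),
            class = "feature_matrix")
}

test_that("ROC points match exhaustive confusion-matrix enumeration", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  roc <- roc_curve(scores, labels, "score_range")
  for (t in seq_along(roc$thresholds)) {
    pred <- scores >= roc$thresholds[t]
    expect_equal(roc$tpr[t], sum(pred & labels == 1) / 2)
    expect_equal(roc$fpr[t], sum(pred & labels == 0) / 2)
  }
  expect_true(any(roc$fpr == 0 & roc$tpr == 0))
  expect_true(any(roc$fpr == 1 & roc$tpr == 1))
})

test_that("ROC endpoint and monotonicity invariants hold on random data", {
  for (seed in 1:10) {
    n <- 12
    scores <- withr::with_seed(seed, runif(n))
    labels <- withr::with_seed(seed + 99,
                               sample(c(0, 1), n, replace = TRUE,
                                      prob = c(0.5, 0.5)))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    for (mode in c("score_range", "unit_interval")) {
      roc <- roc_curve(scores, labels, mode)
      expect_true(any(roc$fpr == 0 & roc$tpr == 0))
      expect_true(any(roc$fpr == 1 & roc$tpr == 1))
      # thresholds decrease, so both rates must be non-decreasing
      expect_true(all(diff(roc$tpr) >= 0))
      expect_true(all(diff(roc$fpr) >= 0))
      expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
    }
  }
})

test_that("AUC reaches its closed-form extremes", {
  labels <- c(0, 0, 1, 1)
  expect_equal(roc_curve(labels, labels, "unit_interval")$auc, 1)
  expect_equal(roc_curve(c(1, 0, 1, 0), labels, "unit_interval")$auc, 0.5,
               tolerance = 1e-12)   # useless classifier
  expect_equal(roc_curve(rep(0.4, 4), labels, "score_range")$auc, 0.5)
})

test_that("trapezoidal AUC equals the rank statistic on tie-free scores", {
  for (seed in 1:15) {
    n <- 14
    scores <- withr::with_seed(seed, rnorm(n))
    labels <- rep(c(0, 1), length.out = n)
    roc <- roc_curve(scores, labels, "score_range")
    expect_equal(roc$auc, mw_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  scores <- withr::with_seed(42, rnorm(16))
  labels <- rep(c(0, 1), 8)
  a <- roc_curve(scores, labels, "score_range")$auc
  expect_equal(roc_curve(exp(scores), labels, "score_range")$auc, a)
  expect_equal(roc_curve(-scores, 1 - labels, "score_range")$auc, a)
  expect_equal(roc_curve(scores, 1 - labels, "score_range")$auc, 1 - a,
               tolerance = 1e-12)
})

test_that("AUC agrees with an established implementation", {
  scores <- withr::with_seed(7, rnorm(20))
  labels <- rep(c(0, 1), 10)
  ours <- roc_curve(scores, labels, "score_range")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("LOOCV yields one score per subject on the correct side", {
  fm <- toy_fm(6, 4, delta = 6, seed = 1)   # far-separated clusters
  scores <- loocv_scores(fm, classifier_spec("linear_svm"))
  expect_length(scores, 12)
  expect_true(all(scores[fm$labels == 1] > 0))
  expect_true(all(scores[fm$labels == 0] < 0))

  fm4 <- toy_fm(2, 3, delta = 6, seed = 2)
  expect_length(loocv_scores(fm4, classifier_spec("linear_svm")), 4)
})

test_that("every classifier family runs LOOCV deterministically", {
  fm <- toy_fm(6, 5, delta = 2, seed = 3)
  for (kind in c("linear_svm", "random_forest", "lda",
                 "lasso_logistic", "knn")) {
    spec <- classifier_spec(kind, seed = 11)
    s1 <- loocv_scores(fm, spec)
    s2 <- loocv_scores(fm, spec)
    expect_identical(s1, s2)
    mode <- threshold_mode_for(spec)
    auc <- roc_curve(s1, fm$labels, mode)$auc
    expect_gte(auc, 0.5)   # clear signal: no family should invert it
  }
})

test_that("label shuffling drives AUC to chance", {
  fm <- toy_fm(25, 6, delta = 0, seed = 4)   # no signal at all
  aucs <- vapply(1:5, function(s) {
    fm_s <- fm
    fm_s$labels <- withr::with_seed(s, sample(fm$labels))
    sc <- loocv_scores(fm_s, classifier_spec("lda", seed = s))
    roc_curve(sc, fm_s$labels, "unit_interval")$auc
  }, numeric(1))
  expect_true(all(aucs > 0.25 & aucs < 0.75))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("single-class folds and missing labels are rejected", {
  fm <- toy_fm(6, 4, delta = 1, seed = 5)
  fm$labels <- NULL
  expect_error(loocv_scores(fm, classifier_spec("lda")), "labels")
  fm2 <- toy_fm(6, 4, delta = 1, seed = 6)
  fm2$labels <- c(1L, rep(0L, 11))
  expect_error(loocv_scores(fm2, classifier_spec("lda")), "2 subjects")
})

test_that("scope comparison table has the promised shape", {
  cohort <- generate_cohort(cohort_config(
    N = 18, K = 2, p_in_mean = 0.7, p_out_mean = 0.2, noise_sd = 0.05,
    seed = 9, n_per_group = 5, effect_module = 1, effect_delta = 0.25))
  specs <- list(classifier_spec("lda", seed = 1),
                classifier_spec("knn", seed = 1, k = 3))
  tab <- compare_feature_scopes(cohort$networks, cohort$labels,
                                cohort$partition, module_k = 1, specs)
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$scope), c("module", "whole_network"))
  expect_equal(tab$n_features[tab$scope == "whole_network"][1],
               18 * 17 / 2)

  # one module covering every node makes both scopes identical
  p_all <- partition(rep(1, 18))
  names(p_all) <- rownames(as.matrix(cohort$networks[[1]]))
  tab2 <- compare_feature_scopes(cohort$networks, cohort$labels, p_all,
                                 module_k = 1,
                                 list(classifier_spec("lda", seed = 2)))
  expect_equal(tab2$auc[1], tab2$auc[2])
})
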