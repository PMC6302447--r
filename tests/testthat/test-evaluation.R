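test_that("stratified folds are disjoint, exhaustive and class-balanced", {
  labels <- rep(c(1, 0), each = 10)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  for (f in folds) {
    expect_equal(sum(labels[f$test] == 1), 2)
    expect_equal(sum(labels[f$test] == 0), 2)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:20)

  # 182 positives vs 910 negatives (1:5): fold positives in {36, 37}, negatives 182
  labels2 <- rep(c(1, 0), c(182, 910))
  folds2 <- stratified_kfold(labels2, k = 5, seed = 3)
  pos_counts <- vapply(folds2, function(f) sum(labels2[f$test] == 1), numeric(1))
  neg_counts <- vapply(folds2, function(f) sum(labels2[f$test] == 0), numeric(1))
  expect_true(all(pos_counts %in% c(36, 37)))
  expect_equal(sum(pos_counts), 182)
  expect_true(all(neg_counts == 182))

  expect_error(stratified_kfold(c(1, 1, 1, 0, 0, 0, 0, 0), k = 5), "fewer than k")
  expect_identical(stratified_kfold(labels2, 5, seed = 3), folds2)  # deterministic
})

test_that("confusion rates reproduce the hand-computed example and flag undefined rates", {
  labels <- rep(c(1, 0), c(100, 100))
  probs <- c(rep(0.9, 90), rep(0.1, 10),   # 90 TP, 10 FN
             rep(0.9, 20), rep(0.1, 80))   # 20 FP, 80 TN
  cr <- confusion_and_rates(labels, probs)
  expect_equal(cr[c("TP", "FN", "FP", "TN")], list(TP = 90, FN = 10, FP = 20, TN = 80))
  expect_equal(cr$SN, 0.9)
  expect_equal(cr$SP, 0.8)
  expect_equal(cr$ACC, 0.85)

  perfect <- confusion_and_rates(c(1, 1, 0), c(0.9, 0.8, 0.1))
  expect_equal(unlist(perfect[c("SN", "SP", "ACC")]), c(SN = 1, SP = 1, ACC = 1))

  nopos <- confusion_and_rates(c(0, 0), c(0.4, 0.6))
  expect_true(is.na(nopos$SN))   # explicit NA, never silent 0
  expect_error(confusion_and_rates(integer(0), numeric(0)), "empty")
})

test_that("roc_auc equals the all-pairs Mann-Whitney statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(labels, qlogis(pmin(pmax(scores, 0.01), 0.99))),
                 roc_auc(labels, scores))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(12)
  labels <- sample(rep(c(1, 0), each = 500))
  expect_equal(roc_auc(labels, runif(1000)), 0.5, tolerance = 0.06)
})

test_that("paired t-test matches the closed form and flags degenerate inputs", {
  a <- c(0.91, 0.93, 0.90, 0.95, 0.92)
  b <- c(0.88, 0.90, 0.89, 0.91, 0.90)
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), length(d) - 1)
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value, p_hand, tolerance = 1e-9)
  expect_false(res$degenerate)

  expect_true(paired_t_test(a, a)$degenerate)          # identical samples
  expect_true(paired_t_test(a, a + 0.02)$degenerate)   # constant nonzero diff
})

test_that("cross-validation produces one record per run and fold, deterministically", {
  d <- make_separable_dataset(n_per_class = 15, L = 50, seed = 2)
  cfg <- method_config("base:F1", engine = classifier_engine(seed = 1, ntree = 50))
  rep1 <- run_cross_validation(cfg, d, folds = 5, runs = 1, seed = 7)
  expect_equal(nrow(rep1$per_fold), 5)
  expect_equal(nrow(rep1$per_run), 1)
  expect_true(all(rep1$per_fold$AUC >= 0 & rep1$per_fold$AUC <= 1))
  expect_equal(sum(rep1$per_fold$n_test), 30)
  rep2 <- run_cross_validation(cfg, d, folds = 5, runs = 1, seed = 7)
  expect_identical(rep1$per_fold, rep2$per_fold)

  rep3 <- run_cross_validation(cfg, d, folds = 3, runs = 2, seed = 7)
  expect_equal(nrow(rep3$per_fold), 6)
  expect_equal(names(rep3$overall), c("SN", "SP", "ACC", "AUC"))
})

test_that("baseline configurations reduce to the documented SVM models", {
  d <- make_separable_dataset(n_per_class = 10, L = 50, seed = 4)
  barman <- run_cross_validation("baseline:barman", d, folds = 3, runs = 1, seed = 2)
  manual <- run_cross_validation(
    method_config("base", spec = feature_spec("F3"),
                  engine = classifier_engine("svm_rbf", seed = 1)),
    d, folds = 3, runs = 1, seed = 2)
  expect_equal(barman$per_fold$AUC, manual$per_fold$AUC, tolerance = 1e-12)

  carter <- run_cross_validation("baseline:carter", d, folds = 3, runs = 1, seed = 2)
  expect_equal(nrow(carter$per_fold), 3)
})

test_that("lambda grid search respects length bounds and reports the argmax", {
  d <- make_separable_dataset(n_per_class = 10, L = 45, seed = 5)
  g <- grid_search_lambda(d, "PCPseDNC", 1, folds = 3, runs = 1, seed = 1,
                          engine = classifier_engine(seed = 1, ntree = 50))
  expect_equal(nrow(g), 1)
  expect_equal(attr(g, "best_lambda"), 1L)
  # shortest sequence 45 nt: di-variants allow lambda up to 43
  expect_error(grid_search_lambda(d, "PCPseDNC", c(1, 44)), "exceeds bound 43")
  expect_error(grid_search_lambda(d, "PCPseTNC", 43), "exceeds bound 42")
})
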