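test_that("engines validate hyperparameters at construction", {
  expect_error(classifier_engine("random_forest", ntree = 0), "ntree")
  expect_error(classifier_engine("svm_rbf", cost = -1), "cost")
  expect_error(classifier_engine("mlp", hidden = 0), "hidden")
  expect_error(classifier_engine("boosting"), "arg")
})

test_that("a separable toy problem reaches training AUC 1 on composition alone", {
  d <- make_separable_dataset(n_per_class = 15, L = 60, seed = 1)
  for (kind in c("random_forest", "svm_rbf", "mlp")) {
    bp <- train_base_predictor(d, "F1", classifier_engine(kind, seed = 2))
    p <- predict_proba(bp, d$sequences)
    expect_length(p, length(d$sequences))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(roc_auc(d$labels, p), 1,
                 label = paste("in-sample AUC for", kind))
    # positives score strictly higher than negatives on the separable fixture
    expect_gt(min(p[d$labels == 1]), max(p[d$labels == 0]))
  }
})

test_that("feature vectors with no class signal give chance-level AUC", {
  # literally identical features for both classes (MLP engine: the fit sees
  # zero usable columns after scaling and must fall back to chance)
  seqs <- setNames(rep(c("ACGTACGTACGTACGTACGTACGT"), 30), paste0("s", 1:30))
  d <- labeled_dataset(seqs, rep(c(1, 0), 15))
  bp <- train_base_predictor(d, "F2", classifier_engine("mlp", seed = 3))
  p <- predict_proba(bp, d$sequences)
  expect_equal(roc_auc(d$labels, p), 0.5, tolerance = 0.05)

  # random sequences, labels independent of content: held-out chance level
  set.seed(4)
  rnd <- setNames(vapply(1:40, function(i) random_dna(60, seed = 400 + i),
                         character(1)), paste0("r", 1:40))
  d2 <- labeled_dataset(rnd, rep(c(1, 0), 20))
  bp2 <- train_base_predictor(d2, "F2", classifier_engine(seed = 3, ntree = 100))
  expect_lt(abs(roc_auc(d2$labels, bp2$train_proba) - 0.5), 0.2)
})

test_that("refitting with the same seed reproduces probabilities exactly", {
  d <- make_separable_dataset(n_per_class = 10, L = 50, seed = 5)
  probe <- make_separable_dataset(n_per_class = 5, L = 50, seed = 6)$sequences
  for (kind in c("random_forest", "svm_rbf", "mlp")) {
    e <- classifier_engine(kind, seed = 11)
    p1 <- predict_proba(train_base_predictor(d, "F2", e), probe)
    p2 <- predict_proba(train_base_predictor(d, "F2", e), probe)
    expect_identical(p1, p2, label = kind)
  }
})

test_that("prediction preserves batch order", {
  d <- make_separable_dataset(n_per_class = 10, L = 50, seed = 7)
  bp <- train_base_predictor(d, "F1", classifier_engine(seed = 1))
  p <- predict_proba(bp, d$sequences)
  perm <- sample(length(p))
  expect_equal(predict_proba(bp, d$sequences[perm]), p[perm])
})

test_that("training requires both classes and a non-empty spec list", {
  seqs <- make_separable_dataset(n_per_class = 6, seed = 8)$sequences
  onecls <- labeled_dataset(seqs, rep(1L, length(seqs)))
  expect_error(train_base_predictor(onecls, "F1"), "both classes")
  d <- make_separable_dataset(n_per_class = 6, seed = 8)
  expect_error(train_all(d, specs = list()), "at least one")
})

test_that("train_all fits one predictor per spec", {
  d <- make_separable_dataset(n_per_class = 8, L = 50, seed = 9)
  preds <- train_all(d, specs = lapply(c("F1", "F3", "F10"), feature_spec),
                     engine = classifier_engine(seed = 1, ntree = 50))
  expect_named(preds, c("F1", "F3", "F10"))
  expect_true(all(vapply(preds, inherits, logical(1), "base_predictor")))
})
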