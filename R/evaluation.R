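#' Stratified k-fold split
#'
#' Partitions instances into k disjoint test folds, stratified by class:
#' per-fold class counts differ from exact proportionality by at most one
#' instance. Deterministic under `seed`.
#'
#' @param labels binary label vector (or a [labeled_dataset()]).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k elements, each `list(fold, train, test)` of instance
#'   indices.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (inherits(labels, "labeled_dataset")) labels <- labels$labels
  k <- as.integer(k)
  n <- length(labels)
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class %s has %d members, fewer than k = %d",
                   cl, length(idx), k))
    }
    idx <- sample(idx)
    sizes <- rep(length(idx) %/% k, k) + (seq_len(k) <= length(idx) %% k)
    fold_of[idx] <- rep(seq_len(k), times = sizes)
  }
  lapply(seq_len(k), function(f) {
    list(fold = f, train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Confusion counts and threshold metrics
#'
#' Applies the threshold (probability >= threshold predicts positive) and
#' reports TP/FP/TN/FN together with sensitivity `SN = TP/(TP+FN)`,
#' specificity `SP = TN/(TN+FP)` and accuracy
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`. A zero denominator yields `NA`, never a
#' silent 0.
#'
#' @param labels binary 0/1 labels.
#' @param probabilities predicted probabilities, same length.
#' @param threshold decision threshold (default 0.5).
#' @return list with elements `TP`, `FP`, `TN`, `FN`, `SN`, `SP`, `ACC`.
#' @export
confusion_and_rates <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(probabilities), all(labels %in% 0:1))
  pred <- as.integer(probabilities >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  TN <- sum(pred == 0L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  safe_div <- function(a, b) if (b == 0L) NA_real_ else a / b
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       SN = safe_div(TP, TP + FN),
       SP = safe_div(TN, TN + FP),
       ACC = (TP + TN) / (TP + FP + TN + FN))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive outscores a random negative, with ties counting one
#' half. Threshold-free and invariant under strictly monotone transforms
#' of the scores.
#'
#' @param labels binary 0/1 labels (both classes must be present).
#' @param scores numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUC requires both classes")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Two-sided paired t-test on matched AUC samples
#'
#' @param aucs_a,aucs_b equal-length paired samples (e.g. per-run AUCs of
#'   two methods), `n >= 2`.
#' @return list with `statistic`, `p_value`, `mean_diff`, `degenerate`
#'   (TRUE when the differences have zero variance, in which case the
#'   p-value is `NA`).
#' @export
paired_t_test <- function(aucs_a, aucs_b) {
  stopifnot(length(aucs_a) == length(aucs_b), length(aucs_a) >= 2L)
  d <- aucs_a - aucs_b
  if (sd(d) < 1e-15) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(aucs_a, aucs_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Method configuration for cross-validation
#'
#' Accepts either a config string — `"base:F12"`, `"waem"`, `"nnem"`,
#' `"baseline:carter"` (SVM on concatenated 1- and 2-spectrum, i.e.
#' mono + di-nucleotide composition), `"baseline:barman"` (SVM on the
#' 3-spectrum, i.e. tri-nucleotide composition) — or the parts explicitly.
#'
#' @param method `"base"`, `"waem"`, `"nnem"` or `"baseline"`; or a config
#'   string as above.
#' @param spec feature spec (for `"base"`) or baseline name (for
#'   `"baseline"`).
#' @param engine a [classifier_engine()] (base predictors; default random
#'   forest).
#' @param ga a [ga_config()] (WAEM).
#' @param nnem an [nnem_config()] (NNEM).
#' @return object of class `method_config`.
#' @export
method_config <- function(method, spec = NULL, engine = classifier_engine(),
                          ga = ga_config(), nnem = nnem_config()) {
  if (grepl(":", method, fixed = TRUE)) {
    parts <- strsplit(method, ":", fixed = TRUE)[[1L]]
    method <- parts[1L]
    spec <- parts[2L]
  }
  if (!method %in% c("base", "waem", "nnem", "baseline")) {
    stop(sprintf("unknown method '%s'", method))
  }
  if (method == "base") {
    if (is.null(spec)) stop("base method needs a feature spec, e.g. 'base:F12'")
    if (is.character(spec)) spec <- feature_spec(spec)
  }
  if (method == "baseline") {
    if (!spec %in% c("carter", "barman")) {
      stop("baseline must be 'carter' or 'barman'")
    }
    engine <- classifier_engine("svm_rbf", seed = engine$seed)
  }
  structure(list(method = method, spec = spec, engine = engine,
                 ga = ga, nnem = nnem),
            class = "method_config")
}

# precompute the feature matrices a method needs (encoding is stateless, so
# computing on the full dataset leaks nothing; all fitting is per-fold)
precompute_features <- function(config, seqs, props) {
  switch(config$method,
    base = list(x = encode_matrix(seqs, config$spec,
                                  props = pick_props(config$spec, props))),
    baseline = {
      x <- if (identical(config$spec, "carter")) {
        cbind(encode_matrix(seqs, feature_spec("F1")),
              encode_matrix(seqs, feature_spec("F2")))
      } else {
        encode_matrix(seqs, feature_spec("F3"))
      }
      list(x = x)
    },
    waem = {
      specs <- all_feature_specs()
      list(specs = specs,
           xs = lapply(specs, function(sp) {
             encode_matrix(seqs, sp, props = pick_props(sp, props))
           }))
    },
    nnem = {
      groups <- names(feature_groups())
      list(xs = setNames(lapply(groups, group_matrix, seqs = seqs,
                                props = props), groups))
    })
}

fit_predict_fold <- function(config, feats, labels, train, test, fold_seed) {
  switch(config$method,
    base = , baseline = {
      f <- fit_engine(feats$x[train, , drop = FALSE], labels[train],
                      set_engine_seed(config$engine, fold_seed))
      predict_engine(f, feats$x[test, , drop = FALSE])
    },
    waem = {
      fits <- lapply(feats$xs, function(x) {
        fit_engine(x[train, , drop = FALSE], labels[train],
                   set_engine_seed(config$engine, fold_seed))
      })
      fitness_scores <- do.call(cbind, lapply(fits, `[[`, "train_proba"))
      ga_cfg <- config$ga
      ga_cfg$seed <- as.integer(fold_seed %% .Machine$integer.max)
      w <- ga_optimize_weights(fitness_scores, labels[train], ga_cfg)
      test_scores <- matrix(
        mapply(function(f, x) predict_engine(f, x[test, , drop = FALSE]),
               fits, feats$xs),
        nrow = length(test))
      combine_weighted(test_scores, w)
    },
    nnem = {
      cfg <- config$nnem
      cfg$seed <- as.integer(fold_seed %% .Machine$integer.max)
      groups <- names(feats$xs)
      s_train <- matrix(0, length(train), length(groups),
                        dimnames = list(NULL, groups))
      s_test <- matrix(0, length(test), length(groups),
                       dimnames = list(NULL, groups))
      for (g in seq_along(groups)) {
        xg <- feats$xs[[g]]
        scaler <- fit_scaler(xg[train, , drop = FALSE])
        net <- mlp_fit(apply_scaler(scaler, xg[train, , drop = FALSE]),
                       labels[train], hidden = cfg$hidden1, l2 = cfg$l2,
                       epochs = cfg$epochs1, lr = cfg$lr, seed = cfg$seed + g)
        s_train[, g] <- mlp_predict(net, apply_scaler(scaler, xg[train, , drop = FALSE]))
        s_test[, g] <- mlp_predict(net, apply_scaler(scaler, xg[test, , drop = FALSE]))
      }
      stage2 <- mlp_fit(s_train, labels[train], hidden = cfg$hidden2, l2 = 0,
                        epochs = cfg$epochs2, lr = cfg$lr,
                        seed = cfg$seed + 100L)
      mlp_predict(stage2, s_test)
    })
}

#' Repeated stratified cross-validation
#'
#' Runs `runs` repetitions of stratified `folds`-fold cross-validation.
#' All model state — base predictor fits, GA weights, NNEM stage-1/2
#' networks and feature scalers — is fitted on the training folds only; a
#' leakage guard verifies train/test disjointness in every fold. Fold
#' metrics are averaged within each run, then run means are averaged for
#' the overall figures.
#'
#' @param config a [method_config()] or config string (`"base:F12"`,
#'   `"waem"`, `"nnem"`, `"baseline:barman"`, ...).
#' @param data a [labeled_dataset()].
#' @param folds folds per run (default 5).
#' @param runs repetitions with re-shuffled folds (default 20).
#' @param seed integer seed; run r uses fold seed `seed + r - 1`.
#' @param props optional list with `di`/`tri` [property_table()]s.
#' @param threshold decision threshold for SN/SP/ACC (default 0.5).
#' @return object of class `metrics_report`: `per_fold` and `per_run`
#'   data.frames plus `overall` named vector (SN, SP, ACC, AUC).
#' @export
run_cross_validation <- function(config, data, folds = 5L, runs = 20L,
                                 seed = 1L, props = NULL, threshold = 0.5) {
  if (is.character(config)) config <- method_config(config)
  stopifnot(inherits(config, "method_config"), inherits(data, "labeled_dataset"))
  labels <- data$labels
  n <- length(labels)
  feats <- precompute_features(config, data$sequences, props)
  per_fold <- list()
  for (r in seq_len(runs)) {
    split <- stratified_kfold(labels, k = folds, seed = seed + r - 1L)
    covered <- sort(unlist(lapply(split, `[[`, "test")))
    stopifnot(identical(covered, seq_len(n)))  # folds partition the data
    for (fs in split) {
      if (length(intersect(fs$train, fs$test)) > 0L) {
        stop("leakage guard: train and test folds overlap")
      }
      fold_seed <- (seed + 7919L * r + 104729L * fs$fold) %% .Machine$integer.max
      prob <- fit_predict_fold(config, feats, labels, fs$train, fs$test,
                               fold_seed)
      cr <- confusion_and_rates(labels[fs$test], prob, threshold)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(run = r, fold = fs$fold, n_test = length(fs$test),
                   TP = cr$TP, FP = cr$FP, TN = cr$TN, FN = cr$FN,
                   SN = cr$SN, SP = cr$SP, ACC = cr$ACC,
                   AUC = roc_auc(labels[fs$test], prob))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("SN", "SP", "ACC", "AUC")
  per_run <- aggregate(per_fold[metric_cols], by = list(run = per_fold$run),
                       FUN = mean)
  overall <- colMeans(per_run[metric_cols])
  structure(list(method = config$method,
                 label = if (!is.null(config$spec) && inherits(config$spec, "feature_spec"))
                   paste0(config$method, ":", config$spec$index)
                 else if (is.character(config$spec))
                   paste0(config$method, ":", config$spec)
                 else config$method,
                 per_fold = per_fold, per_run = per_run, overall = overall,
                 folds = folds, runs = runs, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s: %d run(s) of %d-fold CV\n",
              x$label, x$runs, x$folds))
  cat(sprintf("  AUC %.4f  ACC %.4f  SN %.4f  SP %.4f\n",
              x$overall["AUC"], x$overall["ACC"], x$overall["SN"],
              x$overall["SP"]))
  invisible(x)
}

#' Grid search over the pseudo-composition lag parameter
#'
#' Cross-validates a single pseudo-composition feature for each candidate
#' `lambda` and reports the AUC per value; the argmax is the selected lag.
#'
#' @param data a [labeled_dataset()].
#' @param variant pseudo-composition variant (see [pse_nc()]).
#' @param lambdas integer candidates; all must satisfy the length bound of
#'   the shortest sequence (`L - 2` for di, `L - 3` for tri variants).
#' @param engine a [classifier_engine()].
#' @param folds,runs,seed CV settings (see [run_cross_validation()]).
#' @param w pseudo-composition weight factor.
#' @param props optional [property_table()].
#' @return data.frame with columns `lambda`, `auc`; attribute
#'   `best_lambda`.
#' @export
grid_search_lambda <- function(data, variant, lambdas,
                               engine = classifier_engine(), folds = 5L,
                               runs = 1L, seed = 1L, w = 0.05, props = NULL) {
  ord <- if (endsWith(variant, "DNC")) 2L else 3L
  lmax <- min(nchar(data$sequences)) - ord
  if (any(lambdas > lmax)) {
    stop(sprintf("lambda %d exceeds bound %d (shortest sequence length %d, %s)",
                 max(lambdas), lmax, min(nchar(data$sequences)), variant))
  }
  idx <- switch(variant, PCPseDNC = "F14", PCPseTNC = "F15",
                SCPseDNC = "F16", SCPseTNC = "F17",
                stop("unknown variant"))
  auc <- vapply(lambdas, function(l) {
    spec <- feature_spec(idx, lambda = as.integer(l), w = w)
    cfg <- method_config("base", spec = spec, engine = engine)
    rep <- run_cross_validation(cfg, data, folds = folds, runs = runs,
                                seed = seed, props = props)
    unname(rep$overall["AUC"])
  }, numeric(1))
  out <- data.frame(lambda = as.integer(lambdas), auc = auc)
  attr(out, "best_lambda") <- out$lambda[which.max(out$auc)]
  out
}
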