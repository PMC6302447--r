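#' Weighted-average ensemble prediction
#'
#' The ensemble probability is the convex combination
#' `F(x) = sum_i w_i f_i(x)` of the base predictor probabilities, with
#' `sum w_i = 1`, `w_i >= 0`.
#'
#' @param scores numeric matrix (instances x predictors) of base predictor
#'   probabilities.
#' @param weights a [weight_vector()] (or numeric vector on the simplex) of
#'   length `ncol(scores)`.
#' @return numeric vector of ensemble probabilities in `[0, 1]`.
#' @export
combine_weighted <- function(scores, weights) {
  scores <- as.matrix(scores)
  weights <- weight_vector(weights)
  if (length(weights) != ncol(scores)) {
    stop(sprintf("weight vector length %d does not match %d predictors",
                 length(weights), ncol(scores)))
  }
  drop(scores %*% as.numeric(weights))
}

#' Train the weighted-average ensemble (WAEM)
#'
#' Fits one base predictor per feature spec, then optimizes the convex
#' combination weights by genetic algorithm, with AUC on the training data
#' as fitness (out-of-bag probabilities for random forests).
#'
#' @param data a [labeled_dataset()].
#' @param specs list of [feature_spec()]s (default all seventeen).
#' @param engine a [classifier_engine()] used for every base predictor.
#' @param ga a [ga_config()].
#' @param props optional list with `di`/`tri` [property_table()]s.
#' @return object of class `waem_model` with elements `predictors`,
#'   `weights` (with GA `trace` attribute), `fitness`.
#' @export
waem_train <- function(data, specs = all_feature_specs(),
                       engine = classifier_engine(), ga = ga_config(),
                       props = NULL) {
  predictors <- train_all(data, specs, engine, props)
  scores <- do.call(cbind, lapply(predictors, `[[`, "train_proba"))
  weights <- ga_optimize_weights(scores, data$labels, ga)
  structure(list(predictors = predictors, weights = weights,
                 fitness = attr(weights, "fitness"), props = props),
            class = "waem_model")
}

#' Predict with a WAEM model
#'
#' @param model a [waem_train()] result, or a list of `base_predictor`s if
#'   `weights` is supplied.
#' @param seqs named character vector of sequences.
#' @param weights optional [weight_vector()] overriding the model's.
#' @param props optional property tables.
#' @return numeric vector of probabilities, one per sequence.
#' @export
waem_predict <- function(model, seqs, weights = NULL, props = NULL) {
  if (inherits(model, "waem_model")) {
    predictors <- model$predictors
    if (is.null(weights)) weights <- model$weights
    if (is.null(props)) props <- model$props
  } else {
    predictors <- model
    if (is.null(weights)) stop("weights must be supplied with a raw predictor list")
  }
  scores <- do.call(cbind, lapply(predictors, predict_proba, seqs = seqs,
                                  props = props))
  combine_weighted(scores, weights)
}

#' @export
print.waem_model <- function(x, ...) {
  w <- as.numeric(x$weights)
  names(w) <- names(x$predictors)
  cat(sprintf("<waem_model> %d base predictors, fitness-set AUC %.4f\n",
              length(w), x$fitness))
  top <- sort(w, decreasing = TRUE)[seq_len(min(5L, length(w)))]
  cat("  top weights:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Neural network ensemble configuration
#'
#' Stage 1 fits one rectifier MLP per feature group (SP/MP/RCK/PNC), each
#' emitting a single sigmoid output, with cross-entropy + L2 loss (the
#' feature vectors are longer than typical datasets, hence the penalty).
#' Stage 2 fits a small MLP (cross entropy, no penalty) on the 4-vector of
#' stage-1 outputs.
#'
#' @param hidden1 stage-1 hidden-layer width (default 700).
#' @param l2 stage-1 L2 coefficient (default 0.3).
#' @param hidden2 stage-2 hidden-layer width (default 10).
#' @param epochs1,epochs2 Adam steps per stage.
#' @param lr learning rate for both stages.
#' @param seed integer seed (stage and group sub-seeds are derived from it).
#' @return object of class `nnem_config`.
#' @export
nnem_config <- function(hidden1 = 700L, l2 = 0.3, hidden2 = 10L,
                        epochs1 = 300L, epochs2 = 600L, lr = 0.01, seed = 1L) {
  if (hidden1 < 1L || hidden2 < 1L) stop("hidden sizes must be >= 1")
  if (l2 < 0) stop("l2 must be >= 0")
  structure(list(hidden1 = as.integer(hidden1), l2 = l2,
                 hidden2 = as.integer(hidden2),
                 epochs1 = as.integer(epochs1), epochs2 = as.integer(epochs2),
                 lr = lr, seed = as.integer(seed)),
            class = "nnem_config")
}

#' Train the two-stage neural ensemble (NNEM)
#'
#' Stage 1: four one-hidden-layer ReLU networks, one per merged feature
#' group (SP, MP, RCK, PNC), each trained on the group's z-scored feature
#' matrix and emitting one probability node. Stage 2: a one-hidden-layer
#' network on the 4-vector of stage-1 outputs. Stage-1 outputs feeding
#' stage 2 are computed on the training set itself (the literal stacking
#' recipe); deterministic under `config$seed`.
#'
#' @param data a [labeled_dataset()] containing both classes.
#' @param config an [nnem_config()].
#' @param props optional list with `di`/`tri` [property_table()]s.
#' @return object of class `nnem_model`.
#' @export
nnem_train <- function(data, config = nnem_config(), props = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(unique(data$labels)) < 2L) stop("training data must contain both classes")
  groups <- names(feature_groups())
  stage1 <- vector("list", length(groups))
  names(stage1) <- groups
  s_out <- matrix(0, length(data$sequences), length(groups),
                  dimnames = list(NULL, groups))
  for (g in seq_along(groups)) {
    xg <- group_matrix(data$sequences, groups[g], props)
    scaler <- fit_scaler(xg)
    xs <- apply_scaler(scaler, xg)
    net <- mlp_fit(xs, data$labels, hidden = config$hidden1, l2 = config$l2,
                   epochs = config$epochs1, lr = config$lr,
                   seed = config$seed + g)
    stage1[[g]] <- list(net = net, scaler = scaler)
    s_out[, g] <- mlp_predict(net, xs)
  }
  stage2 <- mlp_fit(s_out, data$labels, hidden = config$hidden2, l2 = 0,
                    epochs = config$epochs2, lr = config$lr,
                    seed = config$seed + 100L)
  structure(list(stage1 = stage1, stage2 = stage2, config = config,
                 props = props),
            class = "nnem_model")
}

#' Predict with an NNEM model
#'
#' @param model an [nnem_train()] result.
#' @param seqs named character vector of sequences (output order preserved).
#' @param props optional property tables (default: those used at training).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
nnem_predict <- function(model, seqs, props = NULL) {
  if (!inherits(model, "nnem_model")) stop("model is not a fitted nnem_model")
  groups <- names(feature_groups())
  if (!identical(sort(names(model$stage1)), sort(groups))) {
    stop(sprintf("nnem model must hold all four group networks (%s); found: %s",
                 paste(groups, collapse = "/"),
                 paste(names(model$stage1), collapse = "/")))
  }
  if (is.null(props)) props <- model$props
  s_out <- vapply(groups, function(g) {
    xg <- group_matrix(seqs, g, props)
    mlp_predict(model$stage1[[g]]$net,
                apply_scaler(model$stage1[[g]]$scaler, xg))
  }, numeric(length(seqs)))
  s_out <- matrix(s_out, ncol = length(groups),
                  dimnames = list(NULL, groups))
  stopifnot(ncol(s_out) == 4L)
  mlp_predict(model$stage2, s_out)
}

#' @export
print.nnem_model <- function(x, ...) {
  cat(sprintf("<nnem_model> stage-1 hidden %d (L2 %.2g) x 4 groups; stage-2 hidden %d\n",
              x$config$hidden1, x$config$l2, x$config$hidden2))
  invisible(x)
}
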