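#' Classifier engine specification
#'
#' One of three classifier families used to build the per-feature base
#' predictors: random forest (default, 200 trees; probability = fraction of
#' trees voting positive), RBF-kernel SVM (probabilities via Platt-style
#' calibration), or a one-hidden-layer ReLU network. Hyperparameters not
#' listed here stay at the underlying library defaults.
#'
#' @param kind `"random_forest"`, `"svm_rbf"` or `"mlp"`.
#' @param seed integer seed used at every fit for reproducibility.
#' @param ntree random forest: number of trees (default 200).
#' @param cost,gamma SVM: regularization and RBF width (`NULL` gamma =
#'   library default `1/d`).
#' @param hidden,l2,epochs,lr MLP hyperparameters (see [mlp_fit()]).
#' @return object of class `classifier_engine`.
#' @export
classifier_engine <- function(kind = c("random_forest", "svm_rbf", "mlp"),
                              seed = 1L, ntree = 200L, cost = 1, gamma = NULL,
                              hidden = 50L, l2 = 0.01, epochs = 300L, lr = 0.01) {
  kind <- match.arg(kind)
  ntree <- as.integer(ntree)
  if (kind == "random_forest" && ntree < 1L) stop("ntree must be >= 1")
  if (kind == "svm_rbf" && cost <= 0) stop("cost must be > 0")
  if (kind == "mlp" && hidden < 1L) stop("hidden size must be >= 1")
  structure(list(kind = kind, seed = as.integer(seed), ntree = ntree,
                 cost = cost, gamma = gamma, hidden = as.integer(hidden),
                 l2 = l2, epochs = as.integer(epochs), lr = lr),
            class = "classifier_engine")
}

set_engine_seed <- function(engine, seed) {
  engine$seed <- as.integer(seed %% .Machine$integer.max)
  engine
}

# Fit an engine on a plain feature matrix. Returns the fitted model plus
# training-set probabilities: out-of-bag for the random forest (in-sample RF
# probabilities are near-degenerate and useless as an ensemble fitness
# signal), in-sample for the other engines.
fit_engine <- function(x, y, engine) {
  stopifnot(inherits(engine, "classifier_engine"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  yf <- factor(y, levels = c(0L, 1L))
  set.seed(engine$seed)
  if (engine$kind == "random_forest") {
    fit <- randomForest(x, yf, ntree = engine$ntree)
    tp <- predict(fit, type = "prob")[, "1"]   # out-of-bag
    tp[is.na(tp)] <- 0.5
    list(kind = engine$kind, model = fit, train_proba = unname(tp))
  } else if (engine$kind == "svm_rbf") {
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
    args <- list(x = xs, y = yf, kernel = "radial", cost = engine$cost,
                 probability = TRUE, scale = FALSE)
    if (!is.null(engine$gamma)) args$gamma <- engine$gamma
    fit <- do.call(svm, args)
    pr <- attr(predict(fit, xs, probability = TRUE), "probabilities")[, "1"]
    list(kind = engine$kind, model = fit, scaler = scaler,
         train_proba = unname(pr))
  } else {
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
    fit <- mlp_fit(xs, y, hidden = engine$hidden, l2 = engine$l2,
                   epochs = engine$epochs, lr = engine$lr, seed = engine$seed)
    list(kind = engine$kind, model = fit, scaler = scaler,
         train_proba = mlp_predict(fit, xs))
  }
}

predict_engine <- function(fitted, x) {
  switch(fitted$kind,
    random_forest = unname(predict(fitted$model, x, type = "prob")[, "1"]),
    svm_rbf = {
      xs <- apply_scaler(fitted$scaler, x)
      unname(attr(predict(fitted$model, xs, probability = TRUE),
                  "probabilities")[, "1"])
    },
    mlp = mlp_predict(fitted$model, apply_scaler(fitted$scaler, x)))
}

#' Train one feature-based base predictor
#'
#' Encodes the dataset under `spec` and fits the engine, producing one of
#' the individual feature-based predictors `f_i` that the ensembles combine.
#'
#' @param data a [labeled_dataset()] containing both classes.
#' @param spec a [feature_spec()] or index string (`"F12"`).
#' @param engine a [classifier_engine()].
#' @param props optional [property_table()] for pseudo-composition specs.
#' @return object of class `base_predictor`.
#' @export
train_base_predictor <- function(data, spec, engine = classifier_engine(),
                                 props = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.character(spec)) spec <- feature_spec(spec)
  x <- encode_matrix(data$sequences, spec, props = pick_props(spec, props))
  fitted <- fit_engine(x, data$labels, engine)
  structure(list(spec = spec, engine = engine, fitted = fitted,
                 train_proba = fitted$train_proba,
                 n_train = nrow(x)),
            class = "base_predictor")
}

#' Predict positive-class probabilities
#'
#' @param predictor a fitted [train_base_predictor()] result.
#' @param seqs named character vector of sequences (order preserved in the
#'   output).
#' @param props optional [property_table()].
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(predictor, seqs, props = NULL) {
  if (!inherits(predictor, "base_predictor") || is.null(predictor$fitted)) {
    stop("predictor is not a fitted base_predictor")
  }
  x <- encode_matrix(seqs, predictor$spec,
                     props = pick_props(predictor$spec, props))
  predict_engine(predictor$fitted, x)
}

#' Train base predictors for a list of feature specs
#'
#' @param data a [labeled_dataset()].
#' @param specs list of [feature_spec()] objects (default: all seventeen).
#' @param engine a [classifier_engine()].
#' @param props optional list with `di`/`tri` [property_table()]s.
#' @return named list of `base_predictor` objects.
#' @export
train_all <- function(data, specs = all_feature_specs(),
                      engine = classifier_engine(), props = NULL) {
  if (length(specs) == 0L) stop("specs must contain at least one feature spec")
  specs <- lapply(specs, function(s) if (is.character(s)) feature_spec(s) else s)
  names(specs) <- vapply(specs, `[[`, character(1), "index")
  errs <- character(0)
  out <- lapply(specs, function(sp) {
    tryCatch(train_base_predictor(data, sp, engine, props),
             error = function(e) {
               errs[[length(errs) + 1L]] <<- sprintf("%s: %s", sp$index,
                                                     conditionMessage(e))
               NULL
             })
  })
  if (length(errs)) stop("base predictor training failed:\n  ",
                         paste(errs, collapse = "\n  "))
  out
}

#' @export
print.base_predictor <- function(x, ...) {
  cat(sprintf("<base_predictor> %s via %s (n_train = %d)\n",
              x$spec$index, x$engine$kind, x$n_train))
  invisible(x)
}
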