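#' Mutual information between a binary feature and binary labels
#'
#' Plug-in estimate `MI = sum p(z,y) log(p(z,y) / (p(z) p(y)))` over the four
#' cells of the empirical joint distribution, natural logarithm, with
#' `0 log 0 := 0`. Symmetric and nonnegative.
#'
#' @param feature,labels equal-length binary (0/1) vectors.
#' @return MI in nats.
#' @export
mutual_information <- function(feature, labels) {
  stopifnot(length(feature) == length(labels), length(feature) >= 1)
  n <- length(feature)
  mi <- 0
  for (zv in c(0, 1)) for (yv in c(0, 1)) {
    pj <- sum(feature == zv & labels == yv) / n
    if (pj == 0) next
    pz <- sum(feature == zv) / n
    py <- sum(labels == yv) / n
    mi <- mi + pj * log(pj / (pz * py))
  }
  max(mi, 0)
}

#' Hyperparameter search spaces
#'
#' The stated search ranges: SVM cost log-uniform on `[0.001, 1000]` with
#' kernel in {linear, rbf, sigmoid, polynomial} and gamma on `[0.0001, 8]`;
#' random forest with 50-100 trees, depth 5-30, 5-20 features per split;
#' GBDT with 50-100 trees, depth 5-20, learning rate 0.05-0.15 and subsample
#' 0.7-1.0.
#'
#' @return object of class `search_space`.
#' @export
search_space <- function() {
  structure(list(
    svm = list(C = c(0.001, 1000), kernel = c("linear", "rbf", "sigmoid",
                                              "polynomial"),
               gamma = c(0.0001, 8)),
    rf = list(n_trees = c(50L, 100L), max_depth = c(5L, 30L),
              max_features = c(5L, 20L)),
    gbdt = list(n_trees = c(50L, 100L), max_depth = c(5L, 20L),
                learning_rate = c(0.05, 0.15), subsample = c(0.7, 1.0))),
    class = "search_space")
}

#' Feature selection by mutual information or the Lasso
#'
#' `mi` ranks columns by mutual information with the labels and keeps the top
#' `k` (or those above `threshold`). `lasso` fits an L1-penalized linear
#' model with the penalty tuned by cross-validation over the grid 0.001 to
#' 0.1 in steps of 0.001 and keeps the columns with nonzero coefficients.
#'
#' @param x feature matrix (columns = features).
#' @param y labels (binary for `mi`; numeric or binary for `lasso`).
#' @param method `"mi"` or `"lasso"`.
#' @param k number of columns `mi` keeps (default 64).
#' @param threshold optional MI threshold overriding `k`.
#' @param seed RNG seed (CV fold assignment for the lasso).
#' @return integer vector of selected column indices (ascending).
#' @export
select_features <- function(x, y, method = c("mi", "lasso"), k = 64L,
                            threshold = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (all(x == 0)) stop("all-zero feature matrix")
  if (method == "mi") {
    mi <- apply(x, 2, mutual_information, labels = y)
    if (!is.null(threshold)) return(which(mi > threshold))
    keep <- order(mi, decreasing = TRUE)[seq_len(min(k, ncol(x)))]
    sort(keep[mi[keep] > 0])
  } else {
    set.seed(seed)
    lambdas <- seq(0.001, 0.1, by = 0.001)
    live <- which(apply(x, 2, stats::sd) > 0)
    cv <- glmnet::cv.glmnet(x[, live, drop = FALSE], y, alpha = 1,
                            lambda = rev(lambdas), nfolds = 5,
                            standardize = TRUE)
    fit <- glmnet::glmnet(x[, live, drop = FALSE], y, alpha = 1,
                          lambda = cv$lambda.min, standardize = TRUE)
    co <- as.matrix(fit$beta)
    sort(live[which(co[, 1] != 0)])
  }
}

make_cv_folds <- function(n, k = 5L, seed = 1L) {
  set.seed(seed)
  fold <- rep(seq_len(k), length.out = n)
  sample(fold)
}

#' Classification metrics: accuracy and F1 score
#'
#' `Acc = (TP + TN) / (TP + FP + TN + FN)`; `F1 = 2 TP / (2 TP + FN + FP)`
#' with class 1 as positive.
#'
#' @param y_pred,y_true equal-length binary vectors.
#' @return named vector `c(accuracy, f1)`.
#' @export
classification_metrics <- function(y_pred, y_true) {
  if (length(y_pred) == 0L) stop("empty input")
  stopifnot(length(y_pred) == length(y_true))
  tp <- sum(y_pred == 1 & y_true == 1)
  tn <- sum(y_pred == 0 & y_true == 0)
  fp <- sum(y_pred == 1 & y_true == 0)
  fn <- sum(y_pred == 0 & y_true == 1)
  c(accuracy = (tp + tn) / length(y_pred),
    f1 = if (2 * tp + fn + fp == 0) 0 else 2 * tp / (2 * tp + fn + fp))
}

#' Regression metrics: MRE, MAE, RMSE
#'
#' `MRE = mean(|pred - obs| / obs)`, `MAE = mean |pred - obs|`,
#' `RMSE = sqrt(mean (pred - obs)^2)`. MRE is undefined when an observed
#' value is zero, which raises an error.
#'
#' @param y_pred,y_true equal-length numeric vectors.
#' @return named vector `c(mre, mae, rmse)`.
#' @export
regression_metrics <- function(y_pred, y_true) {
  if (length(y_pred) == 0L) stop("empty input")
  stopifnot(length(y_pred) == length(y_true))
  if (any(y_true == 0)) stop("MRE undefined: zero value(s) in y_true")
  err <- y_pred - y_true
  c(mre = mean(abs(err) / abs(y_true)), mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)))
}

sample_hyperparams <- function(family, space) {
  sp <- space[[family]]
  if (family == "svm") {
    list(C = exp(stats::runif(1, log(sp$C[1]), log(sp$C[2]))),
         kernel = sample(sp$kernel, 1),
         gamma = exp(stats::runif(1, log(sp$gamma[1]), log(sp$gamma[2]))))
  } else if (family == "rf") {
    list(n_trees = sample(sp$n_trees[1]:sp$n_trees[2], 1),
         max_depth = sample(sp$max_depth[1]:sp$max_depth[2], 1),
         max_features = sample(sp$max_features[1]:sp$max_features[2], 1))
  } else {
    list(n_trees = sample(sp$n_trees[1]:sp$n_trees[2], 1),
         max_depth = sample(sp$max_depth[1]:sp$max_depth[2], 1),
         learning_rate = stats::runif(1, sp$learning_rate[1], sp$learning_rate[2]),
         subsample = stats::runif(1, sp$subsample[1], sp$subsample[2]))
  }
}

fit_one <- function(x, y, family, task, hp) {
  classify <- task == "classify"
  if (family == "svm") {
    e1071::svm(x, if (classify) factor(y, levels = c(0, 1)) else y,
               type = if (classify) "C-classification" else "eps-regression",
               kernel = if (hp$kernel == "polynomial") "polynomial" else hp$kernel,
               cost = hp$C, gamma = hp$gamma, scale = FALSE)
  } else if (family == "rf") {
    randomForest::randomForest(
      x, if (classify) factor(y, levels = c(0, 1)) else y,
      ntree = hp$n_trees,
      mtry = min(hp$max_features, ncol(x)),
      maxnodes = min(2^hp$max_depth, nrow(x)))
  } else {
    xgboost::xgboost(data = x, label = y, nrounds = hp$n_trees,
                     max_depth = hp$max_depth, eta = hp$learning_rate,
                     subsample = hp$subsample,
                     objective = if (classify) "binary:logistic"
                                 else "reg:squarederror",
                     nthread = 1, verbose = 0)
  }
}

predict_one <- function(fit, x, family, task) {
  p <- stats::predict(fit, x)
  if (task == "classify") {
    if (family == "gbdt") as.integer(p > 0.5)
    else as.integer(as.character(p))
  } else as.numeric(p)
}

#' Tune and fit an activity model with fivefold cross-validation
#'
#' Seeded random search over the stated hyperparameter space (a
#' tree-structured-estimator library is not part of this stack; the fallback
#' sampler is logged). For classification the objective is the mean of the
#' training-fold and held-out-fold accuracies averaged over the five folds;
#' for regression the mean held-out RMSE is minimized. The winning
#' configuration is refit on all data.
#'
#' @param x feature matrix.
#' @param y labels (0/1) or numeric response.
#' @param family `"svm"`, `"rf"` or `"gbdt"`.
#' @param task `"classify"` or `"regress"`.
#' @param space a [search_space()].
#' @param n_trials number of sampled configurations.
#' @param seed RNG seed; the same seed reproduces the same winner.
#' @return object of class `qsar_fit`: `fit`, `family`, `task`,
#'   `hyperparameters`, `cv_report` (per-fold and mean metrics).
#' @export
tune_and_fit <- function(x, y, family = c("svm", "rf", "gbdt"),
                         task = c("classify", "regress"),
                         space = search_space(), n_trials = 50L, seed = 1L) {
  family <- match.arg(family); task <- match.arg(task)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (task == "classify") {
    if (length(unique(y)) < 2L) stop("degenerate single-class labels")
    if (min(table(y)) < 5L) stop("need >= 5 samples per class for fivefold CV")
  }
  message("hyperparameter search: seeded random sampling over the stated space")
  set.seed(seed)
  folds <- make_cv_folds(nrow(x), 5L, seed = seed)
  trials <- lapply(seq_len(n_trials), function(i) sample_hyperparams(family, space))
  best <- NULL; best_obj <- -Inf
  for (hp in trials) {
    fold_train <- fold_test <- numeric(5)
    ok <- TRUE
    for (f in 1:5) {
      tr <- folds != f; te <- !tr
      fit <- tryCatch(fit_one(x[tr, , drop = FALSE], y[tr], family, task, hp),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      ptr <- predict_one(fit, x[tr, , drop = FALSE], family, task)
      pte <- predict_one(fit, x[te, , drop = FALSE], family, task)
      if (task == "classify") {
        fold_train[f] <- classification_metrics(ptr, y[tr])["accuracy"]
        fold_test[f] <- classification_metrics(pte, y[te])["accuracy"]
      } else {
        fold_train[f] <- -regression_metrics(ptr, y[tr])["rmse"]
        fold_test[f] <- -regression_metrics(pte, y[te])["rmse"]
      }
    }
    if (!ok) next
    obj <- if (task == "classify") mean((fold_train + fold_test) / 2)
           else mean(fold_test)
    if (obj > best_obj) {
      best_obj <- obj
      best <- list(hp = hp, fold_train = fold_train, fold_test = fold_test)
    }
  }
  if (is.null(best)) stop("no hyperparameter configuration could be fit")
  # final CV report with the winner, then refit on all data
  report <- cv_report(x, y, family, task, best$hp, folds)
  final <- fit_one(x, y, family, task, best$hp)
  structure(list(fit = final, family = family, task = task,
                 hyperparameters = best$hp, cv_report = report, seed = seed),
            class = "qsar_fit")
}

cv_report <- function(x, y, family, task, hp, folds) {
  rows <- lapply(1:5, function(f) {
    tr <- folds != f; te <- !tr
    fit <- fit_one(x[tr, , drop = FALSE], y[tr], family, task, hp)
    pte <- predict_one(fit, x[te, , drop = FALSE], family, task)
    if (task == "classify") classification_metrics(pte, y[te])
    else regression_metrics(pte, y[te])
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = as.data.frame(per_fold),
       mean = colMeans(per_fold))
}

#' @export
predict.qsar_fit <- function(object, newdata, ...) {
  predict_one(object$fit, newdata, object$family, object$task)
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat("qsar_fit:", x$family, x$task, "\n mean CV:",
      paste(names(x$cv_report$mean),
            signif(x$cv_report$mean, 4), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Train an activity model from molecule records
#'
#' End-to-end wrapper: fingerprints the molecules, optionally selects
#' features, and tunes/fits the requested model family. The returned bundle
#' predicts directly from SMILES via [predict_activity()].
#'
#' @param records a [molecule_records()] data.frame; classification uses
#'   `active_label`, regression uses `pic50`.
#' @param spec a [fingerprint_spec()].
#' @param family,task,space,n_trials,seed passed to [tune_and_fit()].
#' @param selection `"none"`, `"mi"` or `"lasso"`.
#' @param select_k top-k for MI selection.
#' @return object of class `activity_model`.
#' @export
train_activity_model <- function(records, spec = fingerprint_spec("ecfp4"),
                                 family = "rf", task = "classify",
                                 selection = "none", select_k = 128L,
                                 space = search_space(), n_trials = 20L,
                                 seed = 1L) {
  y <- if (task == "classify") records$active_label else records$pic50
  if (anyNA(y)) stop("records lack the response for task ", task)
  x <- compute_fingerprint(records$canonical_smiles, spec)
  sel <- seq_len(ncol(x))
  if (selection != "none") {
    ysel <- if (task == "classify") y else as.integer(y > stats::median(y))
    sel <- select_features(x, ysel, method = selection, k = select_k, seed = seed)
  }
  fit <- tune_and_fit(x[, sel, drop = FALSE], y, family = family, task = task,
                      space = space, n_trials = n_trials, seed = seed)
  structure(list(fit = fit, spec = spec, selected = sel), class = "activity_model")
}

#' Predict activity for SMILES with a trained activity model
#'
#' @param model an [train_activity_model()] bundle.
#' @param smiles character vector of valid SMILES.
#' @return binary labels (classification) or pIC50 predictions (regression).
#' @export
predict_activity <- function(model, smiles) {
  stopifnot(inherits(model, "activity_model"))
  x <- compute_fingerprint(smiles, model$spec)
  stats::predict(model$fit, x[, model$selected, drop = FALSE])
}
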