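# class levels used throughout: confusion matrices are ordered
# [non_faller, faller]; faller is the positive / high-risk class
.class_levels <- c("non_faller", "faller")

.as_xy <- function(table) {
  feats <- .feature_cols(table)
  list(X = as.matrix(table[, feats, drop = FALSE]),
       y = factor(table$label, levels = .class_levels),
       feats = feats)
}

.majority_vote <- function(pred_list) {
  votes <- vapply(pred_list, function(p) as.integer(p == "faller"), integer(length(pred_list[[1L]])))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  factor(ifelse(rowMeans(votes) > 0.5, "faller", "non_faller"),
         levels = .class_levels)
}

# --- hand-rolled ensembles (no AdaBoost/bagging implementation in the
# --- installed stack); both use rpart base learners ---------------------

.fit_adaboost <- function(X, y, n_rounds = 50L, maxdepth = 1L) {
  df <- data.frame(X, .y = y)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       minsplit = 2L, cp = 0,
                                                       xval = 0L))
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y])
    if (err <= 1e-12) { # perfect stump: dominate the vote and stop
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

.predict_adaboost <- function(obj, X) {
  df <- as.data.frame(X)
  if (length(obj$stumps) == 0L) {
    return(factor(rep("faller", nrow(df)), levels = .class_levels))
  }
  score <- rowSums(vapply(seq_along(obj$stumps), function(m) {
    p <- predict(obj$stumps[[m]], df, type = "class")
    obj$alphas[m] * ifelse(p == "faller", 1, -1)
  }, numeric(nrow(df))))
  factor(ifelse(score > 0, "faller", "non_faller"), levels = .class_levels)
}

.fit_bagging <- function(X, y, n_trees = 25L) {
  df <- data.frame(X, .y = y)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(nrow(df), replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(minsplit = 2L, cp = 0, xval = 0L))
  })
  list(trees = trees)
}

.predict_bagging <- function(obj, X) {
  df <- as.data.frame(X)
  .majority_vote(lapply(obj$trees, predict, newdata = df, type = "class"))
}

# --- gradient-boosted variants: all served by xgboost with different
# --- growth policies (leaf-wise histogram growth for the lightgbm entry) --

.fit_xgb <- function(X, y, nrounds, extra) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y == "faller"))
  params <- c(list(objective = "binary:logistic", nthread = 1L, seed = 0L),
              extra)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  list(booster = booster, feats = colnames(X))
}

.predict_xgb <- function(obj, X) {
  p <- predict(obj$booster, xgboost::xgb.DMatrix(X))
  factor(ifelse(p > 0.5, "faller", "non_faller"), levels = .class_levels)
}

.importance_xgb <- function(obj) {
  imp <- tryCatch(xgboost::xgb.importance(model = obj$booster),
                  error = function(e) NULL)
  if (is.null(imp) || nrow(imp) == 0L) return(NULL)
  out <- stats::setNames(rep(0, length(obj$feats)), obj$feats)
  out[imp$Feature] <- imp$Gain
  out
}

# --- registry ------------------------------------------------------------

.model_registry <- list(
  svm = list(
    fit = function(X, y, p) e1071::svm(X, y, kernel = "radial", cost = p$cost,
                                       scale = FALSE),
    predict = function(obj, X) factor(predict(obj, X), levels = .class_levels),
    grid = list(cost = c(0.1, 1, 10)),
    defaults = list(cost = 1)
  ),
  decision_tree = list(
    fit = function(X, y, p) {
      rpart::rpart(.y ~ ., data = data.frame(X, .y = y), method = "class",
                   control = rpart::rpart.control(maxdepth = p$maxdepth,
                                                  minsplit = 2L, cp = p$cp,
                                                  xval = 0L))
    },
    predict = function(obj, X) {
      factor(predict(obj, as.data.frame(X), type = "class"),
             levels = .class_levels)
    },
    importance = function(obj) obj$variable.importance,
    grid = list(maxdepth = c(3L, 6L), cp = c(0, 0.01)),
    defaults = list(maxdepth = 6L, cp = 0.01)
  ),
  random_forest = list(
    fit = function(X, y, p) randomForest::randomForest(X, y, mtry = p$mtry,
                                                       ntree = 300L),
    predict = function(obj, X) factor(predict(obj, X), levels = .class_levels),
    importance = function(obj) {
      imp <- randomForest::importance(obj)
      stats::setNames(imp[, 1L], rownames(imp))
    },
    grid = list(mtry = c(2L, 3L)),
    defaults = list(mtry = 2L)
  ),
  lightgbm = list( # leaf-wise histogram boosting
    fit = function(X, y, p) .fit_xgb(X, y, p$nrounds,
                                     list(tree_method = "hist",
                                          grow_policy = "lossguide",
                                          max_depth = 0L, max_leaves = 15L,
                                          eta = 0.1)),
    predict = .predict_xgb,
    importance = .importance_xgb,
    grid = list(nrounds = c(50L, 150L)),
    defaults = list(nrounds = 100L)
  ),
  xgboost = list( # depth-wise exact boosting
    fit = function(X, y, p) .fit_xgb(X, y, p$nrounds,
                                     list(max_depth = p$max_depth, eta = 0.1)),
    predict = .predict_xgb,
    importance = .importance_xgb,
    grid = list(nrounds = c(50L, 150L), max_depth = c(3L, 5L)),
    defaults = list(nrounds = 100L, max_depth = 4L)
  ),
  catboost = list( # depth-wise histogram boosting, shallow symmetric-style trees
    fit = function(X, y, p) .fit_xgb(X, y, p$nrounds,
                                     list(tree_method = "hist",
                                          grow_policy = "depthwise",
                                          max_depth = 4L, eta = 0.1,
                                          lambda = 3)),
    predict = .predict_xgb,
    importance = .importance_xgb,
    grid = list(nrounds = c(50L, 150L)),
    defaults = list(nrounds = 100L)
  ),
  adaboost = list(
    fit = function(X, y, p) .fit_adaboost(X, y, n_rounds = p$n_rounds),
    predict = .predict_adaboost,
    grid = list(n_rounds = c(25L, 50L)),
    defaults = list(n_rounds = 50L)
  ),
  knn = list(
    fit = function(X, y, p) list(X = X, y = y, k = p$k),
    predict = function(obj, X) {
      factor(as.character(class::knn(obj$X, X, obj$y, k = obj$k)),
             levels = .class_levels)
    },
    grid = list(k = c(3L, 5L, 7L)),
    defaults = list(k = 5L)
  ),
  voting = list( # hard majority over three diverse bases
    fit = function(X, y, p) {
      list(svm = e1071::svm(X, y, kernel = "radial", scale = FALSE),
           rf = randomForest::randomForest(X, y, ntree = 300L),
           nb = e1071::naiveBayes(as.data.frame(X), y))
    },
    predict = function(obj, X) {
      .majority_vote(list(
        factor(predict(obj$svm, X), levels = .class_levels),
        factor(predict(obj$rf, X), levels = .class_levels),
        factor(predict(obj$nb, as.data.frame(X)), levels = .class_levels)))
    },
    grid = list(),
    defaults = list()
  ),
  naive_bayes = list(
    fit = function(X, y, p) e1071::naiveBayes(as.data.frame(X), y,
                                              laplace = p$laplace),
    predict = function(obj, X) {
      factor(predict(obj, as.data.frame(X)), levels = .class_levels)
    },
    grid = list(),
    defaults = list(laplace = 0)
  ),
  mlp = list(
    fit = function(X, y, p) {
      fit <- nnet::nnet(X, as.integer(y == "faller"), size = p$size,
                        decay = p$decay, maxit = 300L, entropy = TRUE,
                        trace = FALSE)
      list(net = fit)
    },
    predict = function(obj, X) {
      p <- as.numeric(predict(obj$net, X))
      factor(ifelse(p > 0.5, "faller", "non_faller"), levels = .class_levels)
    },
    grid = list(size = c(4L, 8L), decay = c(0.01, 0.1)),
    defaults = list(size = 8L, decay = 0.01)
  ),
  bagging = list(
    fit = function(X, y, p) .fit_bagging(X, y, n_trees = p$n_trees),
    predict = .predict_bagging,
    grid = list(n_trees = c(25L, 50L)),
    defaults = list(n_trees = 25L)
  )
)

#' Names of the registered classifiers
#'
#' The twelve-model suite of the classification protocol. The three
#' gradient-boosted entries share one backend (xgboost) under different tree
#' growth policies: `lightgbm` grows leaf-wise on feature histograms,
#' `xgboost` depth-wise on exact splits, `catboost` depth-wise on histograms
#' with stronger regularisation.
#'
#' @return Character vector of model names.
#' @export
registered_models <- function() names(.model_registry)

# stratified fold assignment: shuffle within class, deal round-robin
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Fit a classifier with exhaustive grid search
#'
#' Evaluates every configuration in `grid` by stratified k-fold
#' cross-validated accuracy on the training table, then refits the best
#' configuration (ties: first in grid order) on the full training set.
#' A `NULL` grid uses the model's small built-in grid; an empty `list()`
#' skips the search and fits the registry defaults directly.
#'
#' @param train Feature data.frame with a `label` column (scaled upstream if
#'   desired).
#' @param model_name One of [registered_models()].
#' @param grid Named list of parameter value vectors, crossed exhaustively.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling folds and any stochastic fit.
#' @return A `gait_model` object.
#' @export
fit_model <- function(train, model_name, grid = NULL, n_folds = 5L, seed = 1L) {
  if (!model_name %in% names(.model_registry)) {
    stop("unknown model '", model_name, "'; registered: ",
         paste(names(.model_registry), collapse = ", "), call. = FALSE)
  }
  reg <- .model_registry[[model_name]]
  if (is.null(grid)) grid <- reg$grid
  xy <- .as_xy(train)

  configs <- if (length(grid) == 0L) list(reg$defaults) else {
    g <- do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE,
                                           stringsAsFactors = FALSE)))
    lapply(seq_len(nrow(g)), function(i) {
      utils::modifyList(reg$defaults, as.list(g[i, , drop = FALSE]))
    })
  }

  cv_acc <- rep(NA_real_, length(configs))
  if (length(configs) > 1L) {
    set.seed(seed)
    n_folds <- min(n_folds, min(table(xy$y)))
    fold <- .stratified_folds(xy$y, n_folds)
    for (ci in seq_along(configs)) {
      correct <- 0L
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        set.seed(seed + f)
        obj <- reg$fit(xy$X[tr, , drop = FALSE], xy$y[tr], configs[[ci]])
        pred <- reg$predict(obj, xy$X[!tr, , drop = FALSE])
        correct <- correct + sum(pred == xy$y[!tr])
      }
      cv_acc[ci] <- correct / length(xy$y)
    }
    best <- which.max(cv_acc)
  } else {
    best <- 1L
  }

  set.seed(seed)
  obj <- reg$fit(xy$X, xy$y, configs[[best]])
  structure(list(model_name = model_name, fit = obj,
                 params = configs[[best]], cv_accuracy = cv_acc[best],
                 grid_accuracies = cv_acc, feature_names = xy$feats),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<gait_model> %s (%s)%s\n", x$model_name,
              if (nzchar(ps)) ps else "defaults",
              if (is.na(x$cv_accuracy)) "" else
                sprintf(" cv accuracy %.3f", x$cv_accuracy)))
  invisible(x)
}

#' @export
predict.gait_model <- function(object, newdata, ...) {
  feats <- object$feature_names
  if (!all(feats %in% names(newdata))) {
    stop("newdata lacks feature column(s): ",
         paste(setdiff(feats, names(newdata)), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[, feats, drop = FALSE])
  .model_registry[[object$model_name]]$predict(object$fit, X)
}

#' Evaluate a fitted classifier on a test table
#'
#' @param model A `gait_model` from [fit_model()].
#' @param test Feature data.frame, preprocessed the same way as training.
#' @return A `model_result`: `model_name`, `accuracy`, `confusion_matrix`
#'   (2x2 counts, rows = truth, cols = predicted, class order
#'   `[non_faller, faller]`), `importances` (per-feature scores for tree
#'   models, else `NULL`) and the fitted `params`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "gait_model"))
  if (nrow(test) == 0L) stop("test table is empty", call. = FALSE)
  truth <- factor(test$label, levels = .class_levels)
  pred <- predict(model, test)
  cm <- table(truth = truth, predicted = pred)
  imp_fn <- .model_registry[[model$model_name]]$importance
  structure(list(model_name = model$model_name,
                 accuracy = sum(diag(cm)) / sum(cm),
                 confusion_matrix = unclass(cm),
                 importances = if (is.null(imp_fn)) NULL else imp_fn(model$fit),
                 params = model$params),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s: accuracy %.3f\n", x$model_name, x$accuracy))
  print(x$confusion_matrix)
  invisible(x)
}
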