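# linearly separable fixture: fallers all slower and more cadenced
separable_table <- function(n = 20L, seed = 1L) {
  tab <- simulate_feature_table(population_params(n_fallers = n, n_nonfallers = n,
                                                  seed = seed))
  feats <- setdiff(feature_schema_cols("per_foot"), "label")
  tab[tab$label == "faller", feats] <-
    tab[tab$label == "faller", feats] + 10 # far outside the other class
  tab
}

test_that("the registry exposes the twelve-model suite", {
  expect_setequal(registered_models(),
                  c("svm", "decision_tree", "random_forest", "lightgbm",
                    "xgboost", "catboost", "adaboost", "knn", "voting",
                    "naive_bayes", "mlp", "bagging"))
  expect_error(fit_model(separable_table(), "no_such_model"), "unknown model")
})

test_that("grid search maximises cross-validated accuracy and a 1-point grid is a direct fit", {
  tab <- separable_table(seed = 2)
  fit <- fit_model(tab, "knn", grid = list(k = c(1L, 3L, 5L)), seed = 2)
  expect_gte(fit$cv_accuracy, max(fit$grid_accuracies) - 1e-12)
  expect_length(fit$grid_accuracies, 3L)

  direct <- fit_model(tab, "knn", grid = list(), seed = 2)
  expect_true(is.na(direct$cv_accuracy)) # no search performed
  expect_equal(direct$params$k, 5L)      # registry default

  single <- fit_model(tab, "knn", grid = list(k = 5L), seed = 2)
  expect_identical(predict(single, tab), predict(direct, tab))
})

test_that("a tree separates the separable fixture perfectly in training", {
  tab <- separable_table(seed = 3)
  fit <- fit_model(tab, "decision_tree", grid = list(), seed = 3)
  expect_equal(mean(predict(fit, tab) == tab$label), 1)
})

test_that("every registered model fits, predicts and evaluates on the fixture", {
  tab <- separable_table(seed = 4)
  sp <- stratified_split(tab, 0.7, seed = 4)
  sc <- standard_scale(sp$train) # protocol preprocessing
  sp$train <- sc$table
  sp$test <- standard_scale(sp$test, sc$params)$table
  for (m in registered_models()) {
    fit <- fit_model(sp$train, m, grid = list(), seed = 4)
    res <- evaluate(fit, sp$test)
    expect_s3_class(res, "model_result")
    # recount oracle: accuracy is trace / total of the confusion matrix
    preds <- predict(fit, sp$test)
    recount <- sum(as.character(preds) == sp$test$label) / nrow(sp$test)
    expect_equal(res$accuracy, recount, info = m)
    expect_equal(sum(res$confusion_matrix), nrow(sp$test), info = m)
    expect_identical(rownames(res$confusion_matrix), c("non_faller", "faller"))
    # the fixture is trivially separable: perfect prediction, empty off-diagonal
    expect_equal(res$accuracy, 1, info = m)
    expect_equal(sum(res$confusion_matrix) - sum(diag(res$confusion_matrix)), 0,
                 info = m)
  }
})

test_that("tree models report per-feature importances", {
  tab <- separable_table(seed = 5)
  for (m in c("lightgbm", "random_forest")) {
    res <- evaluate(fit_model(tab, m, grid = list(), seed = 5), tab)
    expect_false(is.null(res$importances), info = m)
    expect_true(all(names(res$importances) %in%
                      setdiff(feature_schema_cols("per_foot"), "label")))
  }
  res_knn <- evaluate(fit_model(tab, "knn", grid = list(), seed = 5), tab)
  expect_null(res_knn$importances)
})

test_that("experiment ablations compose as documented", {
  tab <- simulate_feature_table(population_params(seed = 6))
  spec <- experiment_spec(models = c("decision_tree", "naive_bayes"),
                          ablations = c("full", "no_smote", "no_scaling", "none"),
                          seed = 6, grids = list(all = list()))
  res <- run_experiment(tab, spec)
  expect_equal(dim(res$accuracy), c(4L, 2L))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))

  # "none" = no SMOTE and no scaling: equals a manual split + raw fit
  sp <- stratified_split(tab, 0.7, seed = 6)
  manual <- evaluate(fit_model(sp$train, "decision_tree", grid = list(), seed = 6),
                     sp$test)
  expect_equal(res$accuracy["none", "decision_tree"], manual$accuracy)

  # SMOTE before the split lets synthetic rows reach the test set ...
  full_spec <- experiment_spec(models = "decision_tree", ablations = "full",
                               seed = 6, grids = list(all = list()))
  bal <- smote_oversample(tab, seed = 6)
  sp_bal <- stratified_split(bal, 0.7, seed = 6)
  expect_gt(sum(sp_bal$test$provenance == "smote"), 0L)
  # ... while the leakage-free variant keeps them out by construction
  sp_after <- stratified_split(tab, 0.7, seed = 6)
  train_after <- smote_oversample(sp_after$train, seed = 6)
  expect_false(any(sp_after$test$provenance == "smote"))
  expect_gt(sum(train_after$provenance == "smote"), 0L)
})
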