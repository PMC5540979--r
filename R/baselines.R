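#' Baseline classifier adapters
#'
#' Uniform fit/score interface so the cross-validation and sweep harness
#' can compare AdaBoost against the usual comparators: an RBF-kernel SVM,
#' Gaussian Naive Bayes (both via e1071) and a bare depth-limited decision
#' tree (the in-package weak learner at `max_depth = 9` by default, i.e.
#' DT9). Scores are continuous and oriented so that larger means "more
#' normal" (+1), making them directly usable by [roc_auc()].
#'
#' @param name `"adaboost"`, `"svm_rbf"`, `"naive_bayes_gaussian"` or
#'   `"dt"`.
#' @param ... hyperparameters passed to the underlying fit: `M`, `lr`,
#'   `max_depth` for adaboost/dt; `cost`, `gamma` for svm_rbf.
#' @return A list with elements `name`, `fit(X, y)` and `score(model, X)`.
#' @export
baseline_classifier <- function(name = c("adaboost", "svm_rbf",
                                         "naive_bayes_gaussian", "dt"),
                                ...) {
  name <- match.arg(name)
  hp <- list(...)
  switch(
    name,
    adaboost = list(
      name = name,
      fit = function(X, y) {
        adaboost_fit(X, y, M = hp$M %||% 500L, lr = hp$lr %||% 1.0,
                     max_depth = hp$max_depth %||% 9L)
      },
      score = function(model, X) adaboost_score(model, X)),
    dt = list(
      name = name,
      fit = function(X, y) {
        train_weak_learner(X, y, max_depth = hp$max_depth %||% 9L)
      },
      score = function(model, X) predict(model, as_feature_matrix(X))),
    svm_rbf = list(
      name = name,
      fit = function(X, y) {
        X <- as_feature_matrix(X)
        m <- e1071::svm(X, factor(y, levels = c(-1, 1)),
                        kernel = "radial",
                        cost = hp$cost %||% 1, gamma = hp$gamma %||%
                          (1 / ncol(X)), scale = FALSE)
        dv <- attr(predict(m, X, decision.values = TRUE),
                   "decision.values")[, 1]
        # orient decision values so +1 (normal) scores higher
        orient <- if (mean(dv[y > 0]) >= mean(dv[y < 0])) 1 else -1
        list(svm = m, orient = orient)
      },
      score = function(model, X) {
        dv <- attr(predict(model$svm, as_feature_matrix(X),
                           decision.values = TRUE),
                   "decision.values")[, 1]
        model$orient * dv
      }),
    naive_bayes_gaussian = list(
      name = name,
      fit = function(X, y) {
        X <- as.data.frame(as_feature_matrix(X))
        e1071::naiveBayes(X, factor(y, levels = c(-1, 1)))
      },
      score = function(model, X) {
        X <- as.data.frame(as_feature_matrix(X))
        pr <- predict(model, X, type = "raw")
        eps <- 1e-300
        log(pr[, "1"] + eps) - log(pr[, "-1"] + eps)
      }))
}

#' Grid search over baseline hyperparameters
#'
#' Small cross-validated grid search hook: evaluates each hyperparameter
#' combination by k-fold error and returns the grid with a `mean_err`
#' column, best row first.
#'
#' @param name classifier name as in [baseline_classifier()].
#' @param table scaled feature tibble.
#' @param grid data frame of hyperparameter combinations.
#' @param k folds.
#' @param seed fold seed.
#' @return The grid tibble ordered by increasing `mean_err`.
#' @export
baseline_grid_search <- function(name, table, grid, k = 5L, seed = 1L) {
  stopifnot(nrow(grid) >= 1)
  errs <- vapply(seq_len(nrow(grid)), function(i) {
    clf <- do.call(baseline_classifier, c(list(name = name),
                                          as.list(grid[i, , drop = FALSE])))
    res <- cross_validate(table, clf, k = k, n_runs = 1L, seed = seed)
    glance(res)$err
  }, numeric(1))
  out <- as_tibble(grid)
  out$mean_err <- errs
  dplyr::arrange(out, .data$mean_err)
}
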