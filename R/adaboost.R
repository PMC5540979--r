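as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  X
}

check_labels <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be in {-1, +1} (+1 = normal)", call. = FALSE)
  }
  y
}

#' Train a depth-limited decision-tree weak learner
#'
#' Greedy recursive partitioning on weighted samples, minimising the
#' weighted Gini impurity. Split candidates are midpoints between
#' consecutive distinct sorted feature values; ties are broken by the
#' smallest threshold, then the lowest feature index; leaves predict the
#' sign of the weighted class majority (tie -> +1). This is the base
#' learner `D_m(x)` inside the boosting loop and, at `max_depth = 9`, the
#' standalone DT9 comparator.
#'
#' @param X numeric feature matrix or data frame (rows = units).
#' @param y labels in `{-1, +1}`.
#' @param w non-negative sample weights; default uniform. Normalised to
#'   sum to 1 internally.
#' @param max_depth maximum tree depth (1 = decision stump).
#' @return An object of class `eb_tree`.
#' @export
train_weak_learner <- function(X, y, w = NULL, max_depth = 1L) {
  X <- as_feature_matrix(X)
  y <- check_labels(y)
  stopifnot(nrow(X) == length(y), max_depth >= 1)
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  w <- w / sum(w)
  if (length(unique(y)) < 2L) {
    warning("single class in y; returning depth-0 learner", call. = FALSE)
  }
  fit <- tree_fit_cpp(X, y, w, as.integer(max_depth))
  structure(list(tree = fit, max_depth = as.integer(max_depth),
                 p = ncol(X)),
            class = "eb_tree")
}

#' @export
predict.eb_tree <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$p) {
    stop("feature arity mismatch: model expects ", object$p, " feature(s)",
         call. = FALSE)
  }
  t <- object$tree
  tree_predict_cpp(t$feature, t$threshold, t$left, t$right, t$pred, X)
}

#' Fit an AdaBoost ensemble of depth-limited trees
#'
#' Classic discrete AdaBoost: weights start uniform (`W_1i = 1/N`); each
#' round trains a weighted weak learner `D_m`, computes the weighted
#' misclassification rate `e_m`, sets `alpha_m = 0.5 * ln((1 - e_m)/e_m)`,
#' reweights `W <- W * exp(-alpha_m * y * D_m(x))` and renormalises by
#' `Z_m`, and accumulates the margin `f_m = f_{m-1} + lr * alpha_m * D_m`.
#' A perfect round (`e_m = 0`) clamps `e_m` to 1e-10, keeps the learner and
#' stops; a round with `e_m >= 0.5` discards the learner and stops with a
#' warning. The recommended operating point for fatigue EEG features is
#' `max_depth = 9`, `lr = 1`, `M = 500`.
#'
#' @param X numeric feature matrix or data frame.
#' @param y labels in `{-1, +1}`.
#' @param M maximum number of boosting rounds.
#' @param lr learning rate (> 0) applied to the margin accumulation.
#' @param max_depth weak-learner depth limit.
#' @param seed optional integer recorded for provenance (training itself is
#'   deterministic given the data).
#' @return An object of class `adaboost` with elements `learners`,
#'   `alphas`, `errors`, `lr`, `M`, `seed`.
#' @export
adaboost_fit <- function(X, y, M = 500L, lr = 1.0, max_depth = 9L,
                         seed = NULL) {
  X <- as_feature_matrix(X)
  y <- check_labels(y)
  stopifnot(M >= 1, lr > 0, nrow(X) >= 1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- errors <- numeric(0)
  for (m in seq_len(M)) {
    learner <- train_weak_learner(X, y, w, max_depth = max_depth)
    pred <- predict(learner, X)
    e_m <- sum(w[pred != y])
    if (e_m >= 0.5) {
      warning("weak learner no better than chance (e_m = ",
              format(e_m, digits = 4), "); stopping at round ", m,
              call. = FALSE)
      break
    }
    e_clamped <- max(e_m, 1e-10)
    alpha <- 0.5 * log((1 - e_clamped) / e_clamped)
    learners[[length(learners) + 1L]] <- learner
    alphas <- c(alphas, alpha)
    errors <- c(errors, e_m)
    if (e_m == 0) break  # perfect learner: retain and stop boosting
    u <- w * exp(-alpha * y * pred)
    w <- u / sum(u)  # Z_m normalisation
  }
  structure(list(learners = learners, alphas = alphas, errors = errors,
                 lr = lr, M = length(learners),
                 max_depth = as.integer(max_depth), p = ncol(X),
                 feature_names = colnames(X), seed = seed),
            class = "adaboost")
}

#' Continuous AdaBoost margin
#'
#' `f_M(x) = sum_m lr * alpha_m * D_m(x)`; the sign is the class decision
#' and the magnitude feeds the ROC threshold sweep.
#'
#' @param model an [adaboost_fit()] model.
#' @param X feature matrix with the training arity.
#' @return Numeric margin per row of `X`.
#' @export
adaboost_score <- function(model, X) {
  stopifnot(inherits(model, "adaboost"))
  X <- as_feature_matrix(X)
  if (ncol(X) != model$p) {
    stop("feature arity mismatch: model expects ", model$p, " feature(s)",
         call. = FALSE)
  }
  score <- numeric(nrow(X))
  for (m in seq_along(model$learners)) {
    score <- score + model$lr * model$alphas[m] *
      predict(model$learners[[m]], X)
  }
  score
}

#' Hard AdaBoost decision
#'
#' Sign of [adaboost_score()]; an exactly zero margin predicts `+1`
#' (normal) by the documented tie-break.
#'
#' @inheritParams adaboost_score
#' @param tie_break label returned on an exactly zero margin.
#' @return Labels in `{-1, +1}`.
#' @export
adaboost_predict <- function(model, X, tie_break = 1) {
  s <- adaboost_score(model, X)
  out <- sign(s)
  out[out == 0] <- tie_break
  out
}

#' @export
predict.adaboost <- function(object, newdata,
                             type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") adaboost_score(object, newdata)
  else adaboost_predict(object, newdata)
}

#' @export
print.adaboost <- function(x, ...) {
  cat(sprintf("<adaboost> %d weak learner(s), max_depth %d, lr %g\n",
              x$M, x$max_depth, x$lr))
  invisible(x)
}

#' Tidy an AdaBoost model: one row per boosting round
#'
#' @param x an [adaboost_fit()] model.
#' @param ... unused.
#' @return Tibble with `round`, `alpha`, `error` (weighted e_m) and the
#'   achieved tree `depth`.
#' @export
tidy.adaboost <- function(x, ...) {
  tibble(round = seq_len(x$M), alpha = x$alphas, error = x$errors,
         depth = vapply(x$learners, function(l) l$tree$depth, 0L))
}

#' One-row model summary for an AdaBoost fit
#'
#' @inheritParams tidy.adaboost
#' @return Tibble with `M`, `lr`, `max_depth`, and the theoretical
#'   training-error bound `prod(2 * sqrt(e_m * (1 - e_m)))`.
#' @export
glance.adaboost <- function(x, ...) {
  tibble(M = x$M, lr = x$lr, max_depth = x$max_depth,
         error_bound = prod(2 * sqrt(x$errors * (1 - x$errors))))
}

# ---- persistence -----------------------------------------------------------

#' Save / load an AdaBoost model as versioned JSON
#'
#' @param model an [adaboost_fit()] model.
#' @param path JSON file path.
#' @return `path` (save) or the restored `adaboost` model (load).
#' @export
adaboost_save <- function(model, path) {
  stopifnot(inherits(model, "adaboost"))
  doc <- list(
    format = "eegboost-adaboost", version = 1L,
    lr = model$lr, max_depth = model$max_depth, p = model$p,
    feature_names = model$feature_names, seed = model$seed,
    alphas = model$alphas, errors = model$errors,
    learners = lapply(model$learners, function(l) l$tree))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname adaboost_save
#' @export
adaboost_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "eegboost-adaboost")) {
    stop("not an eegboost AdaBoost model file: ", path, call. = FALSE)
  }
  learners <- lapply(seq_len(length(doc$alphas)), function(m) {
    t <- if (is.data.frame(doc$learners)) {
      as.list(doc$learners[m, ])  # jsonlite may collapse uniform records
    } else doc$learners[[m]]
    tr <- list(feature = as.integer(unlist(t$feature)),
               threshold = as.numeric(unlist(t$threshold)),
               left = as.integer(unlist(t$left)),
               right = as.integer(unlist(t$right)),
               pred = as.numeric(unlist(t$pred)),
               depth = as.integer(t$depth[[1]]))
    structure(list(tree = tr, max_depth = as.integer(doc$max_depth),
                   p = as.integer(doc$p)),
              class = "eb_tree")
  })
  structure(list(learners = learners, alphas = as.numeric(doc$alphas),
                 errors = as.numeric(doc$errors), lr = doc$lr,
                 M = length(learners), max_depth = as.integer(doc$max_depth),
                 p = as.integer(doc$p),
                 feature_names = doc$feature_names, seed = doc$seed),
            class = "adaboost")
}
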