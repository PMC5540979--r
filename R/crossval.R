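meta_cols <- c("subject", "channel", "epoch_index", "state")

table_features <- function(table) {
  setdiff(names(table), meta_cols)
}

table_labels <- function(table) {
  state_to_label(table$state)
}

derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 48271 + salt * 7919) %% 2147483647
}

#' Assign units to cross-validation folds
#'
#' Shuffled assignment of `n` units to `k` folds (0-based fold indices)
#' with sizes differing by at most one. With `stratify`, units are dealt
#' to folds round-robin within each class (continuing one global deal
#' across classes), so per-class counts per fold also differ by at most
#' one.
#'
#' @param n number of units, or a vector of unit labels when stratifying.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer RNG seed.
#' @param stratify logical; `n` must then be the label vector.
#' @return Integer vector of fold indices in `0..k-1`.
#' @export
kfold_split <- function(n, k, seed = 1L, stratify = FALSE) {
  labels <- NULL
  if (stratify) {
    labels <- n
    n <- length(labels)
  }
  stopifnot(k >= 2)
  if (k > n) stop("k must not exceed the number of units", call. = FALSE)
  folds <- integer(n)
  withr::with_seed(seed, {
    if (is.null(labels)) {
      folds <- (sample(n) - 1L) %% k
    } else {
      pos <- 0L
      fold_order <- sample(k) - 1L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample(length(idx))]
        folds[idx] <- fold_order[((pos + seq_along(idx) - 1L) %% k) + 1L]
        pos <- pos + length(idx)
      }
    }
  })
  folds
}

#' Cross-validate a classifier on a scaled feature table
#'
#' Runs `n_runs` independent rounds of stratified k-fold cross-validation
#' (folds re-randomised per round with seeds derived from `seed`). Within
#' each round every unit is scored exactly once by a model that never saw
#' it; round-level metrics come from the pooled confusion counts and the
#' pooled score vector. The report carries per-round metrics, their means
#' and SDs, and a mean ROC obtained by vertical averaging of the
#' per-round ROC curves on a fixed FPR grid.
#'
#' @param table scaled feature tibble ([scale_features()]).
#' @param classifier a [baseline_classifier()] adapter (or any list with
#'   `name`, `fit(X, y)`, `score(model, X)`).
#' @param k folds per round.
#' @param n_runs independent rounds.
#' @param seed base seed; each round derives its own fold seed.
#' @return Object of class `eb_eval`: list with `runs` (tibble of per-run
#'   metrics and AUC), `mean_roc`, `classifier`, `k`, `n_runs`.
#' @export
cross_validate <- function(table, classifier, k = 10L, n_runs = 10L,
                           seed = 1L) {
  if (!identical(attr(table, "normalization_state"), "scaled")) {
    stop("feature table must be scaled before classification",
         call. = FALSE)
  }
  y <- table_labels(table)
  if (length(unique(y)) < 2L) {
    stop("need both classes present", call. = FALSE)
  }
  X <- as.matrix(table[table_features(table)])
  runs <- vector("list", n_runs)
  rocs <- vector("list", n_runs)
  fpr_grid <- seq(0, 1, by = 0.01)
  # folds follow canonical unit keys, so results are invariant to the
  # row order of the table
  ord <- order(table$subject, table$channel, table$epoch_index,
               table$state)
  for (r in seq_len(n_runs)) {
    folds <- integer(length(y))
    folds[ord] <- kfold_split(y[ord], k, seed = derive_seed(seed, r),
                              stratify = TRUE)
    scores <- numeric(length(y))
    for (f in 0:(k - 1L)) {
      test <- folds == f
      model <- classifier$fit(X[!test, , drop = FALSE], y[!test])
      scores[test] <- classifier$score(model, X[test, , drop = FALSE])
    }
    pred <- ifelse(scores >= 0, 1, -1)
    mets <- classification_metrics(confusion(y, pred))
    ra <- roc_auc(y, scores)
    runs[[r]] <- dplyr::mutate(mets, auc = ra$auc, run = r,
                               .before = 1)
    rocs[[r]] <- approx(ra$roc$fpr, ra$roc$tpr, xout = fpr_grid,
                        method = "constant", ties = max, rule = 2)$y
  }
  runs <- dplyr::bind_rows(runs)
  mean_roc <- tibble(fpr = fpr_grid,
                     tpr = rowMeans(do.call(cbind, rocs)))
  structure(list(runs = runs, mean_roc = mean_roc,
                 classifier = classifier$name, k = k, n_runs = n_runs,
                 seed = seed),
            class = "eb_eval")
}

#' @export
print.eb_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<eb_eval> %s, %d-fold CV x %d run(s): ERR %.4f +/- %.4f, AUC %.4f\n",
    x$classifier, x$k, x$n_runs, g$err, g$err_sd, g$auc))
  invisible(x)
}

#' Per-run metrics of a cross-validation report
#'
#' @param x an `eb_eval` from [cross_validate()].
#' @param ... unused.
#' @return Tibble with one row per run: `run`, `err`, `precision`,
#'   `recall`, `f1`, `mcc`, `auc`.
#' @export
tidy.eb_eval <- function(x, ...) x$runs

#' One-row summary (means and SDs over runs) of a cross-validation report
#'
#' @inheritParams tidy.eb_eval
#' @return One-row tibble with mean `err`, `precision`, `recall`, `f1`,
#'   `mcc`, `auc` plus `err_sd` and `auc_sd`.
#' @export
glance.eb_eval <- function(x, ...) {
  m <- dplyr::summarise(x$runs, dplyr::across(
    c("err", "precision", "recall", "f1", "mcc", "auc"), mean))
  m$err_sd <- sd(x$runs$err)
  m$auc_sd <- sd(x$runs$auc)
  m
}

#' Plot the mean ROC curve of a cross-validation report
#'
#' @param object an `eb_eval`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eb_eval <- function(object, ...) {
  ggplot2::ggplot(object$mean_roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean ROC (%s, %d-fold CV x %d runs, AUC %.3f)",
                      object$classifier, object$k, object$n_runs,
                      glance(object)$auc)) +
    ggplot2::theme_minimal()
}
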