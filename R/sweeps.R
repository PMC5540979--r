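#' Sweep the weak-learner depth limit
#'
#' Cross-validated AdaBoost error as a function of `max_depth` at a fixed
#' learning rate and iteration budget.
#'
#' @param table scaled feature tibble.
#' @param depths integer vector of `max_depth` values.
#' @param lr learning rate.
#' @param M boosting rounds.
#' @param k,n_runs,seed cross-validation settings (see
#'   [cross_validate()]).
#' @return Tibble with one row per depth: `max_depth`, `mean_err`,
#'   `sd_err`, `mean_auc`.
#' @export
sweep_max_depth <- function(table, depths, lr = 1.0, M = 500L, k = 10L,
                            n_runs = 10L, seed = 1L) {
  if (length(depths) == 0L) stop("empty depth list", call. = FALSE)
  purrr::map_dfr(depths, function(d) {
    res <- cross_validate(
      table, baseline_classifier("adaboost", M = M, lr = lr,
                                 max_depth = d),
      k = k, n_runs = n_runs, seed = seed)
    g <- glance(res)
    tibble(max_depth = d, mean_err = g$err, sd_err = g$err_sd,
           mean_auc = g$auc)
  })
}

#' Sweep the AdaBoost learning rate
#'
#' @inheritParams sweep_max_depth
#' @param lrs numeric vector of learning rates.
#' @param max_depth weak-learner depth limit.
#' @return Tibble with one row per learning rate: `lr`, `mean_err`,
#'   `sd_err`, `mean_auc`.
#' @export
sweep_lr <- function(table, lrs, max_depth = 9L, M = 500L, k = 10L,
                     n_runs = 10L, seed = 1L) {
  if (length(lrs) == 0L) stop("empty lr list", call. = FALSE)
  purrr::map_dfr(lrs, function(l) {
    res <- cross_validate(
      table, baseline_classifier("adaboost", M = M, lr = l,
                                 max_depth = max_depth),
      k = k, n_runs = n_runs, seed = seed)
    g <- glance(res)
    tibble(lr = l, mean_err = g$err, sd_err = g$err_sd, mean_auc = g$auc)
  })
}

stratified_holdout <- function(y, test_ratio, seed) {
  test <- logical(length(y))
  withr::with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_test <- round(test_ratio * length(idx))
      test[sample(idx, n_test)] <- TRUE
    }
  })
  test
}

#' Robustness against the test-sample ratio
#'
#' For each ratio, draws repeated stratified random train/test splits
#' (`train size = round((1 - ratio) * N)` overall) and reports the mean
#' test error per classifier. Ratios leaving an empty or single-class
#' train or test set are skipped with a warning.
#'
#' @param table scaled feature tibble.
#' @param ratios test fractions, each in the open interval (0, 1).
#' @param classifiers named list of [baseline_classifier()] adapters.
#' @param n_runs repeated splits per ratio.
#' @param seed base seed.
#' @return Tibble with `ratio`, `classifier`, `mean_err`, `sd_err`.
#' @export
sweep_test_ratio <- function(table, ratios, classifiers, n_runs = 10L,
                             seed = 1L) {
  stopifnot(all(ratios > 0 & ratios < 1))
  y <- table_labels(table)
  X <- as.matrix(table[table_features(table)])
  out <- list()
  for (ratio in ratios) {
    errs <- matrix(NA_real_, n_runs, length(classifiers))
    colnames(errs) <- names(classifiers)
    ok <- TRUE
    for (r in seq_len(n_runs)) {
      test <- stratified_holdout(y, ratio,
                                 derive_seed(seed, r + 1000 * ratio))
      if (!any(test) || all(test) ||
          length(unique(y[!test])) < 2L || length(unique(y[test])) < 2L) {
        warning("ratio ", ratio, " leaves a degenerate split; skipped",
                call. = FALSE)
        ok <- FALSE
        break
      }
      for (ci in seq_along(classifiers)) {
        clf <- classifiers[[ci]]
        model <- clf$fit(X[!test, , drop = FALSE], y[!test])
        s <- clf$score(model, X[test, , drop = FALSE])
        pred <- ifelse(s >= 0, 1, -1)
        errs[r, ci] <- classification_metrics(
          confusion(y[test], pred))$err
      }
    }
    if (!ok) next
    out[[length(out) + 1L]] <- tibble(
      ratio = ratio, classifier = names(classifiers),
      mean_err = colMeans(errs), sd_err = apply(errs, 2, sd))
  }
  dplyr::bind_rows(out)
}

#' Robustness against the number of subjects
#'
#' For each cohort size `n`, samples `repeats` random subject subsets
#' (without replacement within a subset), pools their units and
#' cross-validates each classifier, reporting the mean error over
#' repeats.
#'
#' @param table scaled feature tibble covering the full cohort.
#' @param n_values cohort sizes to evaluate.
#' @param classifiers named list of [baseline_classifier()] adapters.
#' @param repeats random subject combinations per cohort size.
#' @param k folds for the inner cross-validation.
#' @param seed base seed.
#' @return Tibble with `n_subjects`, `classifier`, `mean_err`, `sd_err`.
#' @export
sweep_n_subjects <- function(table, n_values, classifiers, repeats = 20L,
                             k = 10L, seed = 1L) {
  subjects <- unique(table$subject)
  if (any(n_values > length(subjects))) {
    stop("n exceeds the available cohort of ", length(subjects),
         " subjects", call. = FALSE)
  }
  out <- list()
  for (n in n_values) {
    errs <- matrix(NA_real_, repeats, length(classifiers))
    colnames(errs) <- names(classifiers)
    for (r in seq_len(repeats)) {
      sub <- withr::with_seed(derive_seed(seed, r + 997 * n),
                              sample(subjects, n))
      tab <- table[table$subject %in% sub, , drop = FALSE]
      attr(tab, "normalization_state") <- "scaled"
      for (ci in seq_along(classifiers)) {
        res <- cross_validate(tab, classifiers[[ci]], k = k, n_runs = 1L,
                              seed = derive_seed(seed, r + 31 * ci))
        errs[r, ci] <- glance(res)$err
      }
    }
    out[[length(out) + 1L]] <- tibble(
      n_subjects = n, classifier = names(classifiers),
      mean_err = colMeans(errs), sd_err = apply(errs, 2, sd))
  }
  dplyr::bind_rows(out)
}

#' Plot a sweep result
#'
#' Line plot of mean error against the swept parameter, one line per
#' classifier when present, with +/- 1 SD ribbons when available.
#'
#' @param sweep tibble returned by one of the `sweep_*` functions.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  xvar <- intersect(c("max_depth", "lr", "ratio", "n_subjects"),
                    names(sweep))[1]
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[xvar]],
                                           y = .data$mean_err))
  if ("classifier" %in% names(sweep)) {
    p <- p + ggplot2::aes(colour = .data$classifier)
  }
  if ("sd_err" %in% names(sweep)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_err - .data$sd_err,
                   ymax = .data$mean_err + .data$sd_err),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "Mean error rate") +
    ggplot2::theme_minimal()
}
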