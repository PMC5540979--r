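test_that("confusion counts follow the normal-positive convention", {
  y <- c(rep(1, 5), rep(-1, 5))
  cm <- confusion(y, y)
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))

  y2 <- c(rep(1, 3), rep(-1, 7))
  cm2 <- confusion(y2, rep(1, 10))
  expect_equal(cm2$TP, 3L); expect_equal(cm2$FP, 7L)
  expect_equal(cm2$TN, 0L); expect_equal(cm2$FN, 0L)

  withr::with_seed(5, {
    for (i in 1:10) {
      yt <- sample(c(-1, 1), 30, replace = TRUE)
      yp <- sample(c(-1, 1), 30, replace = TRUE)
      cm <- confusion(yt, yp)
      oc <- oracle_confusion(yt, yp)
      expect_equal(c(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN), oc)
    }
  })
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(1, -1), c(1)), "mismatch")
})

test_that("scalar metrics match direct arithmetic", {
  perfect <- classification_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(0, 1, 1, 1, 1), ignore_attr = TRUE)

  m <- classification_metrics(list(TP = 50, TN = 40, FP = 10, FN = 0))
  expect_equal(m$err, 0.1)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 2 * (50 / 60) / (50 / 60 + 1))
  expect_equal(m$mcc, 2000 / sqrt(60 * 50 * 50 * 40))

  deg <- classification_metrics(list(TP = 0, TN = 10, FP = 0, FN = 5))
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% attr(deg, "degenerate"))
})

test_that("metric identities hold on exhaustive small confusion tables", {
  for (TP in 0:3) for (TN in 0:3) for (FP in 0:3) for (FN in 0:3) {
    tot <- TP + TN + FP + FN
    if (tot == 0) next
    m <- classification_metrics(list(TP = TP, TN = TN, FP = FP, FN = FN))
    expect_equal(m$err, 1 - (TP + TN) / tot)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    }
    if (m$mcc == 1) expect_equal(FP + FN, 0)
    if (m$mcc == -1) expect_equal(TP + TN, 0)
  }
})

test_that("ROC/AUC handles separation, chance and ties", {
  y <- c(rep(1, 4), rep(-1, 4))
  perf <- roc_auc(y, c(4, 3, 2, 1, -1, -2, -3, -4))
  expect_equal(perf$auc, 1)
  expect_equal(perf$roc$fpr[1], 0)
  expect_equal(perf$roc$tpr[nrow(perf$roc)], 1)

  flat <- roc_auc(y, rep(0.3, 8))
  expect_equal(flat$auc, 0.5)

  expect_error(roc_auc(rep(1, 4), rnorm(4)), "both classes")
})

test_that("AUC equals Mann-Whitney pair counting, and agrees with pROC", {
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      y <- sample(c(-1, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
      s <- round(rnorm(n), 1)  # rounding forces ties
      ra <- roc_auc(y, s)
      expect_equal(ra$auc, oracle_auc(y, s), tolerance = 1e-12)
      expect_true(all(diff(ra$roc$fpr) >= 0))
    }
  })
  withr::with_seed(14, {
    y <- sample(c(-1, 1), 60, replace = TRUE)
    s <- rnorm(60) + 0.8 * y
  })
  ours <- roc_auc(y, s)$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(factor(y, levels = c(-1, 1)), s,
                                   direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("k-fold splits partition units into balanced folds", {
  f <- kfold_split(100, 10, seed = 3)
  expect_equal(sort(unique(f)), 0:9)
  expect_true(all(table(f) == 10))

  f2 <- kfold_split(47, 5, seed = 4)
  expect_equal(length(f2), 47L)
  expect_lte(diff(range(table(f2))), 1)

  y <- rep(c(1, -1), c(30, 21))
  fs <- kfold_split(y, 7, seed = 5, stratify = TRUE)
  expect_lte(diff(range(table(fs))), 1)
  for (cl in c(-1, 1)) {
    expect_lte(diff(range(table(fs[y == cl]))), 1)
  }
  expect_error(kfold_split(5, 10), "exceed")
})

test_that("cross-validation scores every unit once and is reproducible", {
  tab <- make_blob_table(n_per_class = 40, sep = 3, seed = 7)
  clf <- baseline_classifier("adaboost", M = 10, max_depth = 2)
  r1 <- cross_validate(tab, clf, k = 5, n_runs = 2, seed = 11)
  r2 <- cross_validate(tab, clf, k = 5, n_runs = 2, seed = 11)
  expect_identical(tidy(r1), tidy(r2))  # bit-exact under a fixed seed
  expect_equal(nrow(tidy(r1)), 2L)
  g <- glance(r1)
  expect_lt(g$err, 0.2)  # separable blobs
  expect_gt(g$auc, 0.9)

  r3 <- cross_validate(tab, clf, k = 5, n_runs = 2, seed = 12)
  expect_false(identical(tidy(r1)$err, tidy(r3)$err))
})

test_that("cross-validation is invariant to unit ordering", {
  tab <- make_blob_table(n_per_class = 30, sep = 2.5, seed = 9)
  clf <- baseline_classifier("dt", max_depth = 3)
  r <- cross_validate(tab, clf, k = 5, n_runs = 1, seed = 21)
  perm <- withr::with_seed(1, sample(nrow(tab)))
  tabp <- tab[perm, ]
  attr(tabp, "normalization_state") <- "scaled"
  rp <- cross_validate(tabp, clf, k = 5, n_runs = 1, seed = 21)
  # folds follow unit keys, so permuting rows changes nothing
  expect_equal(glance(rp)$err, glance(r)$err)
  expect_equal(glance(rp)$auc, glance(r)$auc)
})

test_that("a majority-class scorer sits at chance on balanced data", {
  tab <- make_blob_table(n_per_class = 50, sep = 0, seed = 15)
  maj <- list(name = "always-normal",
              fit = function(X, y) NULL,
              score = function(model, X) rep(1, nrow(X)))
  r <- cross_validate(tab, maj, k = 5, n_runs = 2, seed = 2)
  expect_equal(glance(r)$err, 0.5)
  expect_equal(glance(r)$auc, 0.5)

  expect_error(cross_validate(tab[tab$state == "normal", ], maj),
               "scaled|classes")
})

test_that("unscaled tables are refused by the harness", {
  tab <- make_blob_table(n_per_class = 10, seed = 3)
  attr(tab, "normalization_state") <- "raw"
  clf <- baseline_classifier("dt")
  expect_error(cross_validate(tab, clf), "scaled")
})

test_that("paired t-test matches the closed form and handles edges", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(const$p_value, 0)
  expect_true(!is.null(attr(const, "degenerate")))

  withr::with_seed(19, {
    a <- rnorm(10); b <- rnorm(10, 0.5)
  })
  res <- paired_t_test(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_manual), 9),
               tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_error(paired_t_test(1:3, 1:4), "mismatch")
})

test_that("mean ROC is a proper curve", {
  tab <- make_blob_table(n_per_class = 30, sep = 2, seed = 25)
  clf <- baseline_classifier("adaboost", M = 5, max_depth = 1)
  r <- cross_validate(tab, clf, k = 5, n_runs = 3, seed = 31)
  roc <- r$mean_roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(all(diff(roc$tpr) >= -1e-12))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
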