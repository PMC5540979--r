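test_that("a stump separates separable 1-D data", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  stump <- train_weak_learner(X, y, max_depth = 1)
  expect_equal(predict(stump, X), y)
  thr <- stump$tree$threshold[1]
  expect_gt(thr, -1); expect_lt(thr, 1)
})

test_that("weight concentration flips the stump to the weighted point", {
  # point 1 is mislabeled relative to the bulk; almost all weight on it
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(1, -1, 1, 1)
  w <- c(0.97, 0.01, 0.01, 0.01)
  stump <- train_weak_learner(X, y, w, max_depth = 1)
  expect_equal(predict(stump, X)[1], 1)
  # and it agrees with the exhaustive weighted stump search
  oracle <- oracle_best_stump(X, y, w / sum(w))
  expect_equal(predict(stump, X), oracle$pred)
})

test_that("stump matches the exhaustive search on random weighted data", {
  withr::with_seed(17, {
    for (i in 1:15) {
      n <- sample(5:10, 1)
      X <- matrix(rnorm(2 * n), ncol = 2)
      y <- sample(c(-1, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1] <- -y[1]
      w <- runif(n); w <- w / sum(w)
      stump <- train_weak_learner(X, y, w, max_depth = 1)
      oracle <- oracle_best_stump(X, y, w)
      if (is.finite(oracle$imp)) {
        expect_equal(stump$tree$feature[1] + 1L, oracle$feature)
        expect_equal(stump$tree$threshold[1], oracle$threshold,
                     tolerance = 1e-12)
        expect_equal(predict(stump, X), oracle$pred)
      }
    }
  })
})

test_that("no stump separates XOR data", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  stump <- train_weak_learner(X, y, max_depth = 1)
  err <- mean(predict(stump, X) != y)
  expect_gte(err, 0.25)
  # depth 2 solves it
  tree2 <- train_weak_learner(X, y, max_depth = 2)
  expect_equal(predict(tree2, X), y)
})

test_that("single-class input returns a depth-0 learner with warning", {
  X <- matrix(1:4, ncol = 1)
  expect_warning(t0 <- train_weak_learner(X, c(1, 1, 1, 1)), "single")
  expect_equal(predict(t0, X), rep(1, 4))
  expect_equal(t0$tree$depth, 0L)
})

test_that("boosting stops immediately on a perfect weak learner", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  model <- adaboost_fit(X, y, M = 500, max_depth = 1)
  expect_equal(model$M, 1L)
  expect_equal(adaboost_predict(model, X), y)
  expect_equal(model$errors, 0)
})

test_that("round-1 quantities match the exhaustive stump computation", {
  # 1-D values 1..8 with labels +,+,+,-,-,-,+,+
  X <- matrix(1:8, ncol = 1)
  y <- c(1, 1, 1, -1, -1, -1, 1, 1)
  w1 <- rep(1 / 8, 8)
  oracle <- oracle_best_stump(X, y, w1)
  e1 <- oracle$err                      # = 2/8
  alpha1 <- 0.5 * log((1 - e1) / e1)
  u <- w1 * exp(-alpha1 * y * oracle$pred)
  w2 <- u / sum(u)

  model <- adaboost_fit(X, y, M = 3, max_depth = 1)
  expect_equal(model$errors[1], e1, tolerance = 1e-12)
  expect_equal(model$alphas[1], alpha1, tolerance = 1e-12)
  expect_equal(predict(model$learners[[1]], X), oracle$pred)

  # replay the weight recursion against the stored round-2 error
  pred2 <- predict(model$learners[[2]], X)
  expect_equal(model$errors[2], sum(w2[pred2 != y]), tolerance = 1e-12)
})

test_that("replayed weights renormalise to one and errors stay consistent", {
  withr::with_seed(23, {
    X <- matrix(rnorm(200), ncol = 2)
    y <- ifelse(X[, 1] + 0.5 * rnorm(100) > 0, 1, -1)
  })
  model <- adaboost_fit(X, y, M = 15, max_depth = 1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  for (m in seq_len(model$M)) {
    pred <- predict(model$learners[[m]], X)
    expect_equal(sum(w[pred != y]), model$errors[m], tolerance = 1e-12)
    u <- w * exp(-model$alphas[m] * y * pred)
    w <- u / sum(u)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("ensemble training error respects the AdaBoost bound per round", {
  withr::with_seed(29, {
    X <- matrix(rnorm(300), ncol = 3)
    y <- ifelse(X[, 1] + X[, 2] + rnorm(100) > 0, 1, -1)
  })
  model <- adaboost_fit(X, y, M = 20, max_depth = 1)
  errs <- model$errors
  for (m in seq_len(model$M)) {
    partial <- model
    partial$learners <- model$learners[seq_len(m)]
    partial$alphas <- model$alphas[seq_len(m)]
    partial$M <- m
    train_err <- mean(adaboost_predict(partial, X) != y)
    bound <- prod(2 * sqrt(errs[seq_len(m)] * (1 - errs[seq_len(m)])))
    expect_lte(train_err, bound + 1e-12)
  }
})

test_that("scores compose learners linearly and respect symmetries", {
  withr::with_seed(31, {
    X <- matrix(rnorm(60), ncol = 2)
    y <- ifelse(X[, 1] > 0, 1, -1)
  })
  m1 <- adaboost_fit(X, y, M = 1, lr = 0.7, max_depth = 2)
  s <- adaboost_score(m1, X)
  expect_equal(s, 0.7 * m1$alphas[1] * predict(m1$learners[[1]], X))

  # antisymmetry under label flip
  m5 <- adaboost_fit(X, y, M = 5, max_depth = 2)
  m5f <- adaboost_fit(X, -y, M = 5, max_depth = 2)
  expect_equal(adaboost_score(m5, X), -adaboost_score(m5f, X),
               tolerance = 1e-10)

  # predictions invariant to positive rescaling of the alphas
  m5r <- m5
  m5r$alphas <- 3.7 * m5$alphas
  expect_equal(adaboost_predict(m5r, X), adaboost_predict(m5, X))

  # brute-force weighted majority over learners
  votes <- sapply(seq_len(m5$M),
                  function(k) predict(m5$learners[[k]], X))
  brute <- sign(votes %*% (m5$lr * m5$alphas))
  brute[brute == 0] <- 1
  expect_equal(adaboost_predict(m5, X), as.vector(brute))
})

test_that("training is deterministic and lr=1, M=1 equals the bare learner", {
  withr::with_seed(37, {
    X <- matrix(rnorm(80), ncol = 2)
    y <- sample(c(-1, 1), 40, replace = TRUE)
  })
  a <- adaboost_fit(X, y, M = 10, max_depth = 2)
  b <- adaboost_fit(X, y, M = 10, max_depth = 2)
  expect_identical(adaboost_score(a, X), adaboost_score(b, X))

  m1 <- adaboost_fit(X, y, M = 1, lr = 1, max_depth = 2)
  bare <- train_weak_learner(X, y, max_depth = 2)
  expect_equal(adaboost_predict(m1, X), predict(bare, X))
})

test_that("models survive JSON persistence", {
  withr::with_seed(41, {
    X <- matrix(rnorm(100), ncol = 2)
    y <- ifelse(X[, 1] - X[, 2] > 0, 1, -1)
  })
  model <- adaboost_fit(X, y, M = 8, max_depth = 3, seed = 41)
  path <- withr::local_tempfile(fileext = ".json")
  adaboost_save(model, path)
  back <- adaboost_load(path)
  expect_equal(adaboost_score(back, X), adaboost_score(model, X),
               tolerance = 1e-12)
  expect_equal(back$alphas, model$alphas)
  expect_equal(back$lr, model$lr)
})

test_that("tidy and glance summarise a boosted model", {
  withr::with_seed(43, {
    X <- matrix(rnorm(100), ncol = 2)
    y <- ifelse(X[, 1] + rnorm(50, sd = 2) > 0, 1, -1)
  })
  model <- adaboost_fit(X, y, M = 6, max_depth = 1)
  td <- tidy(model)
  expect_equal(nrow(td), model$M)
  expect_true(all(td$alpha > 0))
  expect_true(all(td$depth <= 1))
  g <- glance(model)
  expect_equal(g$M, model$M)
  expect_gt(g$error_bound, 0)
})

test_that("baseline adapters share the fit/score contract", {
  tab <- make_blob_table(n_per_class = 40, sep = 3, seed = 5)
  X <- as.matrix(tab[c("FE", "SE")])
  y <- ifelse(tab$state == "normal", 1, -1)

  for (nm in c("svm_rbf", "naive_bayes_gaussian", "dt", "adaboost")) {
    clf <- baseline_classifier(nm, M = 10, max_depth = 3)
    model <- clf$fit(X, y)
    s <- clf$score(model, X)
    expect_type(s, "double")
    expect_length(s, nrow(X))
    # well-separated blobs: every adapter should beat chance easily
    expect_lt(mean(ifelse(s >= 0, 1, -1) != y), 0.2)
  }
  expect_error(baseline_classifier("mystery"), "arg")

  # naive Bayes on well-separated unit-variance Gaussians: near-Bayes rule
  withr::with_seed(11, {
    Xg <- matrix(c(rnorm(100, 2), rnorm(100, -2)), ncol = 1)
    yg <- rep(c(1, -1), each = 100)
  })
  nb <- baseline_classifier("naive_bayes_gaussian")
  mg <- nb$fit(Xg, yg)
  expect_lt(mean(ifelse(nb$score(mg, Xg) >= 0, 1, -1) != yg), 0.05)

  # dt adapter is the in-package weak learner with uniform weights
  dt <- baseline_classifier("dt", max_depth = 9)
  md <- dt$fit(X, y)
  expect_s3_class(md, "eb_tree")
})

test_that("arity mismatches and bad labels are rejected", {
  X <- matrix(rnorm(40), ncol = 2)
  y <- rep(c(-1, 1), 10)
  model <- adaboost_fit(X, y, M = 2, max_depth = 1)
  expect_error(adaboost_score(model, matrix(1:3, ncol = 3)), "arity")
  expect_error(adaboost_fit(X, rep(c(0, 1), 10), M = 2), "labels")
})
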