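# Independent naive implementations used as oracles. These deliberately
# share no code with the package internals: templates are materialised as
# matrix rows and the counting is done with explicit loops / vectorised
# row arithmetic.

oracle_templates <- function(x, m, center = FALSE) {
  L <- length(x)
  n <- L - m + 1L
  tpl <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) tpl[i, ] <- x[i:(i + m - 1L)]
  if (center) tpl <- tpl - rowMeans(tpl)
  tpl
}

oracle_cheb_row <- function(tpl, i) {
  # Chebyshev distance from row i to every row
  apply(abs(sweep(tpl, 2, tpl[i, ], "-")), 1, max)
}

oracle_apen <- function(x, m, r) {
  L <- length(x)
  phi <- function(mm) {
    tpl <- oracle_templates(x, mm)
    n <- nrow(tpl)
    acc <- 0
    for (i in seq_len(n)) {
      cnt <- sum(oracle_cheb_row(tpl, i) <= r)  # self-match included
      acc <- acc + log(cnt / n)
    }
    acc / n
  }
  phi(m) - phi(m + 1L)
}

oracle_sampen <- function(x, m, r) {
  n <- length(x) - m
  tpl_m <- oracle_templates(x, m)[seq_len(n), , drop = FALSE]
  tpl_m1 <- oracle_templates(x, m + 1L)
  B <- A <- 0
  for (i in seq_len(n)) {
    dm <- oracle_cheb_row(tpl_m, i)
    dm1 <- oracle_cheb_row(tpl_m1, i)
    B <- B + sum(dm[-i] <= r)
    A <- A + sum(dm1[-i] <= r)
  }
  if (A == 0) return(NA_real_)
  log(B / A)
}

oracle_fuzzyen <- function(x, m, nexp, r) {
  n <- length(x) - m
  gam <- function(mm) {
    tpl <- oracle_templates(x, mm, center = TRUE)[seq_len(n), ,
                                                  drop = FALSE]
    acc <- 0
    for (i in seq_len(n)) {
      d <- oracle_cheb_row(tpl, i)[-i]
      acc <- acc + mean(exp(-d^nexp / r))
    }
    acc / n
  }
  log(gam(m)) - log(gam(m + 1L))
}

oracle_spectral_entropy <- function(x) {
  L <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  p <- p[2:(L %/% 2 + 1)]
  y <- p / sum(p)
  y <- y[y > 0]
  sum(y * log(1 / y))
}

# Mann-Whitney pair-counting AUC (ties count 1/2)
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == -1]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive weighted decision stump: enumerates every (feature, midpoint
# threshold) candidate, scores it by the weighted Gini impurity
# sum(W_child * gini_child), and keeps the minimiser (ties: smallest
# threshold, then lowest feature index). Leaves are weighted majorities
# with ties -> +1; the stump's weighted error is returned alongside.
oracle_best_stump <- function(X, y, w) {
  X <- as.matrix(X)
  gini <- function(wp, wn) {
    wt <- wp + wn
    if (wt <= 0) return(0)
    1 - (wp / wt)^2 - (wn / wt)^2
  }
  best <- list(imp = Inf, err = Inf, feature = NA, threshold = Inf)
  for (f in seq_len(ncol(X))) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    thrs <- (v[-1] + v[-length(v)]) / 2
    for (thr in thrs) {
      left <- X[, f] <= thr
      wpl <- sum(w[left & y == 1]); wnl <- sum(w[left & y == -1])
      wpr <- sum(w[!left & y == 1]); wnr <- sum(w[!left & y == -1])
      imp <- (wpl + wnl) * gini(wpl, wnl) + (wpr + wnr) * gini(wpr, wnr)
      maj <- function(wp, wn) if (wp >= wn) 1 else -1
      pred <- ifelse(left, maj(wpl, wnl), maj(wpr, wnr))
      err <- sum(w[pred != y])
      if (imp < best$imp - 1e-12 ||
          (abs(imp - best$imp) <= 1e-12 && thr < best$threshold - 1e-12)) {
        best <- list(imp = imp, err = err, feature = f, threshold = thr,
                     pred = pred)
      }
    }
  }
  best
}

# tiny tabular confusion oracle
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == -1 && y_pred[i] == -1) tn <- tn + 1
    if (y_true[i] == -1 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 1 && y_pred[i] == -1) fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# small default entropy parameters used across tests
tp_default <- entropy_params()

# quick synthetic feature table for classifier tests: two Gaussian blobs
make_blob_table <- function(n_per_class = 50, sep = 2, seed = 1,
                            n_subjects = 2) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    tab <- tibble::tibble(
      subject = rep(sprintf("s%d", seq_len(n_subjects)),
                    length.out = n),
      channel = "ch1",
      epoch_index = seq_len(n) - 1L,
      state = rep(c("normal", "fatigue"), each = n_per_class),
      FE = c(stats::rnorm(n_per_class, sep / 2),
             stats::rnorm(n_per_class, -sep / 2)),
      SE = stats::rnorm(n))
    tab$FE <- pmin(pmax(tab$FE / (sep / 2 + 3), -1), 1)
    tab$SE <- pmin(pmax(tab$SE / 3, -1), 1)
    attr(tab, "normalization_state") <- "scaled"
    tab
  })
}
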