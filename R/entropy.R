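#' Entropy estimator parameters
#'
#' Shared parameters of the four estimators: embedding dimension `m`,
#' tolerance coefficient `s_coef` (the match radius is
#' `s = s_coef * SD(epoch)`, recomputed per epoch), and the fuzzy-membership
#' gradient exponent `n`. Defaults follow common EEG practice for 1-s
#' windows: `m = 2`, `s_coef = 0.2`, `n = 4`. All four entropies use the
#' natural logarithm.
#'
#' @param m embedding dimension (integer >= 1).
#' @param s_coef tolerance as a fraction of the epoch SD (> 0).
#' @param n fuzzy gradient exponent (> 0).
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, s_coef = 0.2, n = 4) {
  stopifnot(m >= 1, s_coef > 0, n > 0)
  structure(list(m = as.integer(m), s_coef = s_coef, n = n),
            class = "entropy_params")
}

#' Phase-space embedding
#'
#' Forms the `L - m + 1` overlapping m-dimensional template vectors
#' `T_i = [x(i), ..., x(i + m - 1)]`. With `center = TRUE` each template is
#' baseline-subtracted by its own mean (the fuzzy-entropy variant).
#'
#' @param x numeric vector of length `L > m`.
#' @param m embedding dimension.
#' @param center subtract each template's own mean.
#' @return A `(L - m + 1) x m` numeric matrix, one template per row.
#' @export
embed_vectors <- function(x, m, center = FALSE) {
  L <- length(x)
  if (L <= m) stop("insufficient length: need length(x) > m", call. = FALSE)
  out <- vapply(seq_len(m), function(k) x[k:(L - m + k)],
                numeric(L - m + 1L))
  out <- matrix(out, ncol = m)
  if (center) out <- out - rowMeans(out)
  out
}

#' Chebyshev (maximum-coordinate) distance
#'
#' @param a,b numeric vectors of equal length.
#' @return `max(abs(a - b))`.
#' @export
chebyshev_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch between template vectors", call. = FALSE)
  }
  max(abs(a - b))
}

epoch_tolerance <- function(x, params) params$s_coef * sd(x)

#' Spectral entropy of an epoch
#'
#' Shannon entropy of the normalised one-sided periodogram of the
#' mean-removed window: with bin powers `Y_i` and `y_i = Y_i / sum(Y)`,
#' `PE = sum(y_i * ln(1 / y_i))`. Zero-power bins contribute 0; a constant
#' (zero AC power) epoch returns 0 with attribute `degenerate = TRUE`.
#' `normalize = TRUE` divides by `ln(n_bins)` to map onto `[0, 1]`.
#'
#' @param x numeric epoch vector, length >= 2.
#' @param params an [entropy_params()] (unused by PE; kept for a uniform
#'   interface).
#' @param normalize divide by the maximum attainable entropy.
#' @return Spectral entropy in nats (or normalised to `[0, 1]`).
#' @export
spectral_entropy <- function(x, params = entropy_params(),
                             normalize = FALSE) {
  L <- length(x)
  if (L < 2L) stop("insufficient length: need at least 2 samples",
                   call. = FALSE)
  z <- x - mean(x)
  pw <- Mod(fft(z))^2
  idx <- 2L:(L %/% 2L + 1L)  # one-sided, DC excluded, Nyquist kept if even L
  pw <- pw[idx]
  tot <- sum(pw)
  if (tot <= .Machine$double.eps * L) {
    return(structure(0, degenerate = TRUE))
  }
  y <- pw / tot
  y <- y[y > 0]
  pe <- -sum(y * log(y))
  if (normalize) pe <- pe / log(length(idx))
  pe
}

#' Approximate entropy of an epoch
#'
#' Regularity statistic comparing log-frequencies of template matches
#' (Chebyshev distance within tolerance `s = s_coef * SD`) at embedding
#' dimensions `m` and `m + 1`. Self-matches are included in the counts, so
#' every count is >= 1 and the logarithm is always defined; `strict = TRUE`
#' excludes them for study. Scale-invariant because the tolerance tracks
#' the epoch SD; a constant epoch returns 0.
#'
#' @param x numeric epoch vector, length >= m + 2.
#' @param params an [entropy_params()].
#' @param strict exclude self-matches (may return `NA`).
#' @return Approximate entropy in nats.
#' @export
approximate_entropy <- function(x, params = entropy_params(),
                                strict = FALSE) {
  check_entropy_input(x, params)
  s <- epoch_tolerance(x, params)
  if (s == 0) return(0)
  apen_cpp(as.numeric(x), params$m, s, strict)
}

#' Sample entropy of an epoch
#'
#' Negative log of the ratio of match frequencies at dimensions `m + 1` and
#' `m`, self-matches excluded. Always >= 0 when defined. When no template
#' pair matches at `m + 1` the statistic is undefined and `NA` is returned
#' (the undefined-entropy sentinel; [extract_features()] excludes and
#' counts such units). A constant epoch returns 0.
#'
#' @inheritParams approximate_entropy
#' @return Sample entropy in nats, or `NA` when undefined.
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  check_entropy_input(x, params)
  s <- epoch_tolerance(x, params)
  if (s == 0) return(0)
  sampen_cpp(as.numeric(x), params$m, s)
}

#' Fuzzy entropy of an epoch
#'
#' Sample-entropy variant on baseline-centered templates with the hard
#' match indicator replaced by the fuzzy membership
#' `D_ij = exp(-d_ij^n / s)`, so the statistic is continuous in the data
#' and always finite. The membership is evaluated on the epoch
#' standardised to unit SD with width `s = s_coef`: because the exponent
#' `n` acts on the distance, applying the membership to the raw amplitudes
#' would make the statistic depend on the measurement scale, whereas on
#' the standardised epoch it is invariant to additive offsets (removed by
#' the per-template baseline) and to positive rescaling. A constant epoch
#' returns 0.
#'
#' @inheritParams approximate_entropy
#' @return Fuzzy entropy in nats.
#' @export
fuzzy_entropy <- function(x, params = entropy_params()) {
  check_entropy_input(x, params)
  s <- sd(x)
  if (s == 0) return(0)
  fuzzyen_cpp(as.numeric(x) / s, params$m, params$n, params$s_coef)
}

check_entropy_input <- function(x, params) {
  if (length(x) < params$m + 2L) {
    stop("insufficient length: need length(x) >= m + 2", call. = FALSE)
  }
  if (anyNA(x)) stop("epoch contains missing values", call. = FALSE)
  invisible(TRUE)
}
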