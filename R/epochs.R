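#' Section a recording into non-overlapping epochs
#'
#' Splits every channel into consecutive windows of `window_s` seconds
#' (`L = round(fs * window_s)` samples). The trailing partial window is
#' discarded, so a 5-minute channel yields 300 one-second epochs. Each epoch
#' is one "unit": the atomic classification instance.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds.
#' @return A tibble with one row per epoch: `subject`, `channel`, `state`,
#'   `epoch_index` (0-based) and a list-column `values` of length-`L`
#'   numeric vectors. A recording shorter than one window yields zero rows
#'   with a warning.
#' @export
window_epochs <- function(rec, window_s = 1.0) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  L <- round(rec$fs * window_s)
  nt <- ncol(rec$samples)
  n_ep <- nt %/% L
  if (n_ep == 0L) {
    warning("recording shorter than one window; no epochs produced",
            call. = FALSE)
    return(tibble(subject = character(), channel = character(),
                  state = character(), epoch_index = integer(),
                  values = list()))
  }
  rows <- vector("list", nrow(rec$samples))
  for (ci in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ci, ]
    vals <- lapply(seq_len(n_ep) - 1L,
                   function(k) x[(k * L + 1L):((k + 1L) * L)])
    rows[[ci]] <- tibble(
      subject = rec$subject_id,
      channel = rec$channel_names[ci],
      state = rec$state,
      epoch_index = seq_len(n_ep) - 1L,
      values = vals)
  }
  dplyr::bind_rows(rows)
}

#' Assemble a labelled epoch dataset from several recordings
#'
#' Concatenates [window_epochs()] over all recordings in deterministic
#' order (input order, then channel, then epoch index). The full study
#' design -- 28 subjects x 2 states x 30 channels x 5 minutes in 1-s
#' windows -- yields 504,000 units, 252,000 per state.
#'
#' @param recordings list of [eeg_recording()] objects.
#' @param window_s window length in seconds.
#' @return A tibble of epochs as in [window_epochs()], with per-class unit
#'   counts in `attr(, "class_counts")`.
#' @export
assemble_dataset <- function(recordings, window_s = 1.0) {
  stopifnot(length(recordings) > 0)
  out <- purrr::map(recordings, window_epochs, window_s = window_s)
  out <- dplyr::bind_rows(out)
  key <- paste(out$subject, out$state, out$channel, out$epoch_index,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("integrity error: duplicated (subject, state, channel, ",
         "epoch_index) keys across recordings", call. = FALSE)
  }
  attr(out, "class_counts") <- table(out$state)
  out
}
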