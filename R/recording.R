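#' Multichannel EEG recording
#'
#' Container for one continuous multichannel recording: a channels x
#' timepoints amplitude matrix (microvolts), the sampling rate, a subject
#' identifier and the behavioural state label. States are encoded internally
#' as `normal = +1`, `fatigue = -1` throughout the package.
#'
#' @param samples numeric matrix, channels x timepoints.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id opaque subject identifier (coerced to character).
#' @param state `"normal"` or `"fatigue"`.
#' @param channel_names optional character vector, one per channel.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, subject_id, state,
                          channel_names = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  state <- match.arg(state, c("normal", "fatigue"))
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         subject_id = as.character(subject_id), state = state,
         channel_names = as.character(channel_names)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, state %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$state, nrow(x$samples), ncol(x$samples),
              x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

state_to_label <- function(state) ifelse(state == "normal", 1L, -1L)
label_to_state <- function(label) ifelse(label > 0, "normal", "fatigue")

# ---- delimited format (one channel per row) + sidecar metadata -------------

sidecar_path <- function(path) paste0(path, ".meta")

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[`, "", 1L))
  vals
}

#' Read an EEG recording from disk
#'
#' The delimited format stores one channel per row (whitespace or comma
#' separated, auto-detected) with metadata (`fs`, `subject_id`, `state`,
#' optional `channel_names`) in a `<path>.meta` key=value sidecar. The EDF
#' reader understands continuous 16-bit EDF as written by
#' [write_recording()]. Entries in `meta` override sidecar/header values.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"edf"`.
#' @param meta named list of metadata overrides (`fs`, `subject_id`,
#'   `state`, `channel_names`).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("delimited", "edf"),
                           meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path, meta))

  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- tryCatch(
    read.table(path, sep = sep, header = FALSE,
               colClasses = "numeric", fill = FALSE),
    error = function(e) {
      stop("delimited parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  samples <- as.matrix(df)
  dimnames(samples) <- NULL

  side <- read_sidecar(sidecar_path(path))
  side[names(meta)] <- meta
  if (is.null(side$fs)) {
    stop("metadata error: sampling rate `fs` missing for ", path,
         call. = FALSE)
  }
  ch <- side$channel_names
  if (is.character(ch) && length(ch) == 1L && grepl(",", ch)) {
    ch <- trimws(strsplit(ch, ",", fixed = TRUE)[[1]])
  }
  eeg_recording(samples, fs = as.numeric(side$fs),
                subject_id = side$subject_id %||% "unknown",
                state = side$state %||% "normal",
                channel_names = ch)
}

#' Write an EEG recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output file; the delimited format adds a `<path>.meta`
#'   sidecar.
#' @param format `"delimited"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "edf") return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rec$samples))) {
    writeLines(paste(format(rec$samples[i, ], digits = 17, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), con)
  }
  writeLines(c(paste0("fs=", format(rec$fs, digits = 17)),
               paste0("subject_id=", rec$subject_id),
               paste0("state=", rec$state),
               paste0("channel_names=", paste(rec$channel_names,
                                              collapse = ","))),
             sidecar_path(path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF (16-bit, single data record) ------------------------------

edf_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  nt <- ncol(rec$samples)
  dur <- nt / rec$fs
  pmin <- apply(rec$samples, 1, min)
  pmax <- apply(rec$samples, 1, max)
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1  # avoid zero span for constant channels
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8L),
    edf_field(rec$subject_id, 80L),
    edf_field(rec$state, 80L),
    edf_field("01.01.20", 8L), edf_field("00.00.00", 8L),
    edf_field(256L * (ns + 1L), 8L),
    edf_field("", 44L),
    edf_field(1L, 8L),
    edf_field(format(dur, digits = 7), 8L),
    edf_field(ns, 4L))
  sig <- paste0(
    paste(vapply(rec$channel_names, edf_field, "", width = 16L),
          collapse = ""),
    strrep(edf_field("", 80L), ns),
    strrep(edf_field("uV", 8L), ns),
    paste(vapply(pmin, function(v) edf_field(format(v, digits = 7), 8L), ""),
          collapse = ""),
    paste(vapply(pmax, function(v) edf_field(format(v, digits = 7), 8L), ""),
          collapse = ""),
    strrep(edf_field(-32768L, 8L), ns),
    strrep(edf_field(32767L, 8L), ns),
    strrep(edf_field("", 80L), ns),
    paste(rep(edf_field(nt, 8L), ns), collapse = ""),
    strrep(edf_field("", 32L), ns))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((rec$samples[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  if (!identical(trimws(rd(8L)), "0")) {
    stop("format error: not a continuous EDF file: ", path, call. = FALSE)
  }
  subject <- trimws(rd(80L))
  state <- trimws(rd(80L))
  rd(8L); rd(8L); rd(8L); rd(44L)
  n_rec <- as.integer(trimws(rd(8L)))
  dur <- as.numeric(trimws(rd(8L)))
  ns <- as.integer(trimws(rd(4L)))
  chn <- vapply(seq_len(ns), function(i) trimws(rd(16L)), "")
  rd(80L * ns); rd(8L * ns)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8L))), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8L))), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8L))), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(trimws(rd(8L))), 0)
  rd(80L * ns)
  spr <- vapply(seq_len(ns), function(i) as.integer(trimws(rd(8L))), 0L)
  rd(32L * ns)
  out <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little")
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        pmin[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
    }
  }
  st <- meta$state %||% (if (state %in% c("normal", "fatigue")) state
                         else "normal")
  eeg_recording(out, fs = meta$fs %||% (spr[1] / dur),
                subject_id = meta$subject_id %||% subject,
                state = st, channel_names = meta$channel_names %||% chn)
}

# ---- filtering -------------------------------------------------------------

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the pass band is phase-neutral. The default
#' band of interest for fatigue EEG is 0.15-45 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges; `0 < low_hz < high_hz < fs / 2`.
#' @param order filter order (per direction).
#' @return The filtered [eeg_recording()], same shape.
#' @export
bandpass_filter <- function(rec, low_hz = 0.15, high_hz = 45, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("parameter error: need 0 < low_hz < high_hz < fs/2 (Nyquist = ",
         nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    out$samples[i, ] <- signal::filtfilt(bf, rec$samples[i, ])
  }
  out
}
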