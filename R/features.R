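feature_order <- c("FE", "SE", "AE", "PE")

#' Extract entropy features for a table of epochs
#'
#' Computes the requested entropy feature(s) for every unit. The combined
#' set carries all four columns in the order FE, SE, AE, PE. Units whose
#' sample entropy is undefined (no template match at dimension m + 1) are
#' excluded; the number excluded is reported in `attr(, "n_excluded")`.
#'
#' @param epochs epoch tibble from [window_epochs()] / [assemble_dataset()];
#'   all epochs must share the same length.
#' @param feature_set one of `"FE"`, `"SE"`, `"AE"`, `"PE"`, `"combined"`.
#' @param params an [entropy_params()].
#' @return A raw feature tibble: metadata columns `subject`, `channel`,
#'   `epoch_index`, `state`, then one column per feature. Attribute
#'   `normalization_state` is `"raw"`.
#' @export
extract_features <- function(epochs,
                             feature_set = c("combined", "FE", "SE",
                                             "AE", "PE"),
                             params = entropy_params()) {
  feature_set <- match.arg(feature_set)
  if (nrow(epochs) == 0L) stop("empty epoch list", call. = FALSE)
  lens <- lengths(epochs$values)
  if (length(unique(lens)) != 1L) {
    stop("all epochs must have the same length", call. = FALSE)
  }
  feats <- if (feature_set == "combined") feature_order else feature_set
  fns <- list(
    FE = function(x) fuzzy_entropy(x, params),
    SE = function(x) sample_entropy(x, params),
    AE = function(x) approximate_entropy(x, params),
    PE = function(x) as.numeric(spectral_entropy(x, params)))
  out <- dplyr::select(epochs, "subject", "channel", "epoch_index", "state")
  for (f in feats) {
    out[[f]] <- vapply(epochs$values, fns[[f]], numeric(1))
  }
  keep <- stats::complete.cases(out[feats])
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("all units excluded as undefined", call. = FALSE)
  attr(out, "normalization_state") <- "raw"
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Scale features to the interval -1..1 within subject x channel groups
#'
#' Min-max affine map of every feature column to `[-1, 1]` separately
#' within each (subject, channel) group. The default mode fits the map on
#' all units before any train/test split; `mode = "train_only"` fits the
#' group ranges on training units only (flagged via `train`) and applies
#' them everywhere, clipping test values that fall outside `[-1, 1]`
#' unless `clip = FALSE`. A constant group maps to 0 with a warning.
#'
#' @param table raw feature tibble from [extract_features()].
#' @param mode `"per_subject_channel_global"` or `"train_only"`.
#' @param train logical vector flagging training rows (train_only mode).
#' @param clip clip out-of-range values in train_only mode.
#' @return The scaled feature tibble (`normalization_state = "scaled"`).
#' @export
scale_features <- function(table,
                           mode = c("per_subject_channel_global",
                                    "train_only"),
                           train = NULL, clip = TRUE) {
  mode <- match.arg(mode)
  if (identical(attr(table, "normalization_state"), "scaled")) {
    stop("feature table is already scaled", call. = FALSE)
  }
  feats <- intersect(feature_order, names(table))
  if (mode == "train_only") {
    if (is.null(train) || length(train) != nrow(table)) {
      stop("train_only mode needs a logical `train` flag per row",
           call. = FALSE)
    }
  } else {
    train <- rep(TRUE, nrow(table))
  }
  grp <- paste(table$subject, table$channel, sep = "\r")
  n_const <- 0L
  for (f in feats) {
    v <- table[[f]]
    for (g in unique(grp)) {
      in_g <- grp == g
      fit <- in_g & train
      if (!any(fit)) {
        stop("group without training units in train_only mode",
             call. = FALSE)
      }
      lo <- min(v[fit]); hi <- max(v[fit])
      if (hi <= lo) {
        v[in_g] <- 0
        n_const <- n_const + 1L
      } else {
        v[in_g] <- 2 * (v[in_g] - lo) / (hi - lo) - 1
      }
    }
    if (clip) v <- pmin(pmax(v, -1), 1)
    table[[f]] <- v
  }
  if (n_const > 0L) {
    warning(n_const, " constant (subject, channel, feature) group(s) ",
            "mapped to 0", call. = FALSE)
  }
  attr(table, "normalization_state") <- "scaled"
  table
}

#' Write / read a feature table as CSV
#'
#' Metadata columns first, then feature columns; the normalisation state
#' travels in a `# normalization_state:` comment line.
#'
#' @param table feature tibble.
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# normalization_state: ",
                    attr(table, "normalization_state") %||% "raw"), con)
  utils::write.table(as.data.frame(table), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  state <- sub("^# normalization_state:\\s*", "", first)
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  out$subject <- as.character(out$subject)
  out$channel <- as.character(out$channel)
  attr(out, "normalization_state") <- state
  out
}
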