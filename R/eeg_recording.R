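#' The standard 22-channel scalp montage
#'
#' International 10-20 electrode labels used by default for 22-channel
#' recordings; `m1`/`m2` are surface channels standing in for sphenoidal
#' electrodes.
#'
#' @return Character vector of 22 channel labels.
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz", "Oz", "m1", "m2")
}

STAGES <- c("AS", "SS", "IS")

#' Multichannel EEG recording
#'
#' Container for a channels-by-samples voltage matrix with its sampling rate,
#' channel labels and optional vigilance-stage annotations.
#'
#' @param data Numeric matrix, channels in rows, samples in columns
#'   (microvolts).
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel labels, one per row.
#'   Defaults to `chan01`, `chan02`, ... or [montage_10_20()] for 22 rows.
#' @param stages Optional data frame with columns `start_s`, `end_s`,
#'   `stage`; stages must be one of `"AS"` (awake), `"SS"` (sleep), `"IS"`
#'   (ictal) and intervals must lie within the recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, stages = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(labels)) {
    labels <- if (nrow(data) == 22L) montage_10_20()
              else sprintf("chan%02d", seq_len(nrow(data)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("number of labels (", length(labels),
         ") does not match number of channels (", nrow(data), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  rownames(data) <- labels
  dur <- ncol(data) / fs
  if (!is.null(stages)) {
    stages <- as.data.frame(stages)
    stopifnot(all(c("start_s", "end_s", "stage") %in% names(stages)))
    stages$stage <- as.character(stages$stage)
    if (!all(stages$stage %in% STAGES))
      stop("stages must be one of: ", paste(STAGES, collapse = ", "))
    if (any(stages$start_s < 0) || any(stages$end_s > dur + 1e-9) ||
        any(stages$end_s <= stages$start_s))
      stop("stage intervals must be increasing and lie within [0, ", dur, "] s")
  }
  structure(list(data = data, fs = fs, labels = labels, stages = stages),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n")
  if (!is.null(x$stages)) {
    s <- vapply(seq_len(nrow(x$stages)), function(i)
      sprintf("%s[%g-%gs]", x$stages$stage[i], x$stages$start_s[i],
              x$stages$end_s[i]), "")
    cat("  stages:", paste(s, collapse = " "), "\n")
  }
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Reads either a European Data Format (EDF) file or a delimited numeric
#' matrix (channels in rows). For CSV input, a non-numeric first column is
#' taken as the channel labels; otherwise labels come from the `labels`
#' argument.
#'
#' @param path Path to the file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by file extension).
#' @param fs Sampling rate in Hz; required for CSV, ignored for EDF (taken
#'   from the header).
#' @param labels Optional channel labels overriding file content.
#' @param stages Optional stage annotation data frame (see
#'   [eeg_recording()]).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = NULL,
                           labels = NULL, stages = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") {
    edf <- read_edf(path)
    if (is.null(labels)) labels <- edf$labels
    return(eeg_recording(edf$data, fs = edf$fs, labels = labels,
                         stages = stages))
  }
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  first <- suppressWarnings(as.numeric(raw[[1]]))
  if (anyNA(first)) {                      # labelled first column
    if (is.null(labels)) labels <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  }
  m <- as.matrix(raw)
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric cells in ", path)
  if (is.null(fs)) stop("`fs` is required for CSV input")
  eeg_recording(m, fs = fs, labels = labels, stages = stages)
}

#' Write an EEG recording to a CSV file
#'
#' Channels in rows, labels in the first column, full double precision, so
#' that a write/read round trip reproduces the data exactly.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  lines <- vapply(seq_len(nrow(rec$data)), function(i)
    paste(rec$labels[i],
          paste(sprintf("%.17g", rec$data[i, ]), collapse = ","), sep = ","),
    "")
  writeLines(lines, path)
  invisible(path)
}
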