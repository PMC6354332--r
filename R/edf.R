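# Minimal European Data Format (EDF) support: continuous signals, identical
# sampling rate across channels, 16-bit samples. Covers the subset of the
# format produced by clinical scalp-EEG systems and by write_edf() below.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF file
#'
#' @param path Path to an EDF file whose signals share one sampling rate.
#' @return List with `data` (channels x samples matrix of physical values),
#'   `fs`, and `labels` in header order.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                               # version
  read_ascii(con, 80); read_ascii(con, 80)          # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)            # start date / time
  as.integer(read_ascii(con, 8))                    # header bytes
  read_ascii(con, 44)                               # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  dur_rec <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- fld(16)
  fld(80); fld(8)                                   # transducer, unit
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                                           # prefiltering
  nr <- as.integer(fld(8))                          # samples per record
  fld(32)                                           # reserved
  if (length(unique(nr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- nr[1] / dur_rec
  data <- matrix(0, ns, n_rec * nr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nr[1], size = 2, endian = "little")
      data[s, ((r - 1) * nr[1] + 1):(r * nr[1])] <-
        (dig - dmin[s]) * scale[s] + pmin[s]
    }
  }
  list(data = data, fs = fs, labels = labels)
}

pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

#' Write a recording as an EDF file
#'
#' Samples are quantized to 16 bits over each channel's own physical range,
#' one-second data records; `fs` must therefore be a whole number. Trailing
#' samples not filling a record are dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF output requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s, width) writeChar(pad(s, width), con, nchars = width,
                                    eos = NULL)
  w("0", 8); w("synthetic", 80); w("focimap", 80)
  w("01.01.00", 8); w("00.00.00", 8)
  w(256 + ns * 256, 8); w("", 44); w(n_rec, 8); w("1", 8); w(ns, 4)
  for (s in rec$labels) w(s, 16)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w("uV", 8)
  for (v in pmin) w(formatC(v, format = "g", digits = 6), 8)
  for (v in pmax) w(formatC(v, format = "g", digits = 6), 8)
  for (i in seq_len(ns)) w(dmin, 8)
  for (i in seq_len(ns)) w(dmax, 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(fs, 8)
  for (i in seq_len(ns)) w("", 32)
  pminw <- as.numeric(pad(formatC(pmin, format = "g", digits = 6), 8))
  pmaxw <- as.numeric(pad(formatC(pmax, format = "g", digits = 6), 8))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pminw[s]) / (pmaxw[s] - pminw[s]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
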