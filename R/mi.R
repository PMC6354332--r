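# Short-term synchronization: binned (histogram) entropies and mutual
# information in log10 units ("hartleys"), matching the decimal logarithm of
# the defining equations. Marginal entropies are always derived from the
# margins of the joint histogram, which makes I(X;Y) = Hx + Hy - Hxy hold as
# an identity and keeps I >= 0 structurally.

# Equal-width bin indices. With range = "robust" the partition spans
# [max(min, mean - 3 sd), min(max, mean + 3 sd)] and outliers are clamped
# into the edge bins; heavy-tailed samples would otherwise stretch the
# partition and waste resolution where there is no mass.
bin_index <- function(x, bins, range = c("robust", "minmax")) {
  range <- match.arg(range)
  lo <- min(x); hi <- max(x)
  if (range == "robust") {
    m <- mean(x); s <- sd(x)
    if (is.finite(s) && s > 0) {
      lo <- max(lo, m - 3 * s)
      hi <- min(hi, m + 3 * s)
    }
  }
  if (hi <= lo) return(rep(1L, length(x)))   # constant sequence: one bin
  idx <- 1L + floor((x - lo) / ((hi - lo) / bins))
  pmin.int(bins, pmax.int(1L, idx))
}

entropy_from_p <- function(p) {
  p <- p[p > 0]
  -sum(p * log10(p))
}

#' Histogram entropy of a sample sequence
#'
#' Shannon entropy (decimal log, so a uniform 10-bin histogram has entropy
#' 1) of the equal-width-bin histogram of `x`. Empty bins contribute zero; a
#' constant sequence has entropy 0.
#'
#' @param x Numeric sample sequence.
#' @param bins Number of bins (N of the N x N partition), `>= 2`.
#' @param range `"robust"` (default; bins span the mean +/- 3 SD, clamped to
#'   the observed range, with outliers absorbed by the edge bins) or
#'   `"minmax"` (bins span exactly `[min(x), max(x)]`).
#' @return Entropy in log10 units.
#' @export
histogram_entropy <- function(x, bins = 16, range = "robust") {
  if (bins < 2) stop("`bins` must be >= 2")
  if (length(x) < bins) stop("need at least `bins` samples")
  p <- tabulate(bin_index(x, bins, range), nbins = bins) / length(x)
  entropy_from_p(p)
}

#' Mutual information between two sample sequences
#'
#' Binned mutual information `I = Hx + Hy - Hxy` from the N x N joint
#' histogram, in log10 units. Marginal entropies come from the joint
#' histogram's margins, so the identity is exact and the result cannot be
#' negative beyond float rounding (tiny negatives are clamped to 0).
#'
#' @inheritParams histogram_entropy
#' @param y Second sequence, same length as `x`.
#' @return Mutual information in log10 units (0 for independent sequences in
#'   the large-sample limit).
#' @export
mutual_information <- function(x, y, bins = 16, range = "robust") {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (bins < 2) stop("`bins` must be >= 2")
  if (length(x) < bins) stop("sequences shorter than `bins`")
  bx <- bin_index(x, bins, range)
  by <- bin_index(y, bins, range)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / length(x)
  jm <- matrix(joint, bins, bins)
  i <- entropy_from_p(rowSums(jm)) + entropy_from_p(colSums(jm)) -
    entropy_from_p(joint)
  max(0, i)
}

#' Pairwise mutual-information matrix for one window
#'
#' Symmetric channels x channels matrix of pairwise mutual information; the
#' diagonal holds each channel's own histogram entropy.
#'
#' @param window Numeric matrix, channels x samples.
#' @param bins Bin count per axis (default 16).
#' @param labels Channel labels (default: rownames or `chanXX`).
#' @param window_index Optional index tag for bookkeeping.
#' @param range Binning range rule, see [histogram_entropy()].
#' @return Object of class `mi_matrix`: list with `values`, `labels`,
#'   `bins`, `window`.
#' @export
mi_matrix <- function(window, bins = 16, labels = NULL, window_index = NA,
                      range = "robust") {
  window <- as.matrix(window)
  nch <- nrow(window)
  if (nch < 2) stop("need at least 2 channels")
  if (ncol(window) < bins) stop("window shorter than `bins`")
  if (is.null(labels))
    labels <- rownames(window) %||% sprintf("chan%02d", seq_len(nch))
  v <- matrix(0, nch, nch, dimnames = list(labels, labels))
  bidx <- lapply(seq_len(nch), function(i) bin_index(window[i, ], bins, range))
  n <- ncol(window)
  for (i in seq_len(nch)) {
    p <- tabulate(bidx[[i]], nbins = bins) / n
    v[i, i] <- entropy_from_p(p)
  }
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      joint <- tabulate(bidx[[i]] + bins * (bidx[[j]] - 1L),
                        nbins = bins * bins) / n
      jm <- matrix(joint, bins, bins)
      mi <- entropy_from_p(rowSums(jm)) + entropy_from_p(colSums(jm)) -
        entropy_from_p(joint)
      v[i, j] <- v[j, i] <- max(0, mi)
    }
  }
  structure(list(values = v, labels = labels, bins = bins,
                 window = window_index),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("<mi_matrix> %d channels, %d bins, window %s\n",
              length(x$labels), x$bins, format(x$window)))
  cat(sprintf("  off-diagonal MI: mean %.4f, max %.4f\n",
              mean(offdiag(x$values)), max(offdiag(x$values))))
  invisible(x)
}

offdiag <- function(m) m[row(m) != col(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage summary of mutual-information matrices
#'
#' Mean and coefficient of variation (in percent, population SD) of the
#' off-diagonal mutual information pooled over all channel pairs and all
#' windows of one stage.
#'
#' @param mats List of [mi_matrix()] objects belonging to one stage.
#' @param stage Optional stage label recorded in the output.
#' @return List with `stage`, `mean`, `cv` (percent; `NA` when the mean is
#'   zero) and `n_windows`.
#' @export
mi_stage_stats <- function(mats, stage = NA_character_) {
  if (length(mats) < 1) stop("need at least one MI matrix")
  vals <- unlist(lapply(mats, function(m) {
    stopifnot(inherits(m, "mi_matrix"))
    offdiag(m$values)
  }))
  mu <- mean(vals)
  sd_pop <- sqrt(mean((vals - mu)^2))
  list(stage = stage, mean = mu,
       cv = if (mu > 0) 100 * sd_pop / mu else NA_real_,
       n_windows = length(mats))
}
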