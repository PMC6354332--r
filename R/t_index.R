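# Long-term synchronization statistic: the pooled-variance two-sample
# T-index between two channels' per-window feature profiles within one
# stage. Similar profiles give |T| near zero, so LOW T-index means HIGH
# nonlinear synchronization.

#' Pooled-variance two-sample T statistic
#'
#' `T = (mean1 - mean2) / sqrt(Sc2 * (1/n1 + 1/n2))` with the pooled
#' variance `Sc2 = ((n1-1) S1^2 + (n2-1) S2^2) / (n1 + n2 - 2)` (sample
#' variances, `n - 1` denominators). Antisymmetric in its arguments.
#'
#' @param sample1,sample2 Numeric vectors with at least 2 values each
#'   (missing values dropped).
#' @return Signed T; 0 when both variances vanish with equal means, `Inf`
#'   (sign of the mean difference) when they vanish with unequal means.
#' @export
pooled_t <- function(sample1, sample2) {
  x <- sample1[!is.na(sample1)]
  y <- sample2[!is.na(sample2)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 values")
  d <- mean(x) - mean(y)
  sc2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sc2 == 0) {
    if (d == 0) return(0)
    return(sign(d) * Inf)
  }
  d / sqrt(sc2 * (1 / n1 + 1 / n2))
}

#' T-index matrix of one feature in one stage
#'
#' Cell `(i, j)` holds `|pooled_t()|` between channel i's and channel j's
#' per-window values of one nonlinear feature, restricted to windows of one
#' stage; missing windows are dropped per channel (pairwise deletion). A
#' channel with fewer than 2 valid values yields an `NA` row and column.
#'
#' @param profiles Long-format data frame from [feature_profiles()].
#' @param feature Which feature (`"CD"`, `"ApEn"`, `"HE"`, `"PCAI"`).
#' @param stage Which stage (`"AS"`, `"SS"`, `"IS"`), or `NULL` to pool all
#'   windows.
#' @param labels Channel ordering (default: order of first appearance).
#' @return Object of class `t_index_matrix`: list with `values` (`|T|`,
#'   zero diagonal), `signed`, `feature`, `stage`, `labels`, `n` (valid
#'   windows per channel).
#' @export
t_index_matrix <- function(profiles, feature, stage = NULL, labels = NULL) {
  p <- profiles[profiles$feature == feature, , drop = FALSE]
  if (!is.null(stage)) p <- p[!is.na(p$stage) & p$stage == stage, ,
                              drop = FALSE]
  if (nrow(p) == 0) stop("no profile values for feature ", feature,
                         if (!is.null(stage)) paste0(" in stage ", stage))
  if (is.null(labels)) labels <- unique(p$channel)
  samples <- lapply(labels, function(ch) {
    v <- p$value[p$channel == ch]
    v[!is.na(v)]
  })
  nval <- vapply(samples, length, 0L)
  nch <- length(labels)
  if (nch < 2) stop("need at least 2 channels")
  tv <- matrix(NA_real_, nch, nch, dimnames = list(labels, labels))
  diag(tv) <- 0
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      if (nval[i] >= 2 && nval[j] >= 2) {
        tv[i, j] <- pooled_t(samples[[i]], samples[[j]])
        tv[j, i] <- -tv[i, j]
      }
    }
  }
  structure(list(values = abs(tv), signed = tv, feature = feature,
                 stage = stage %||% NA_character_, labels = labels,
                 n = nval),
            class = "t_index_matrix")
}

#' @export
print.t_index_matrix <- function(x, ...) {
  cat(sprintf("<t_index_matrix> %s / %s, %d channels\n", x$feature, x$stage,
              length(x$labels)))
  v <- offdiag(x$values)
  cat(sprintf("  |T| off-diagonal: mean %.3f (NA: %d cells)\n",
              mean(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Mean off-diagonal T-index of a matrix
#'
#' The stage-level synchronization summary: mean of the off-diagonal,
#' non-missing `|T|` cells.
#'
#' @param mat A [t_index_matrix()].
#' @return Scalar mean.
#' @export
t_matrix_average <- function(mat) {
  stopifnot(inherits(mat, "t_index_matrix"))
  v <- offdiag(mat$values)
  v <- v[!is.na(v)]
  if (!length(v)) stop("all off-diagonal cells are missing")
  mean(v)
}
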