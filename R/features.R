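# Per-channel nonlinear features on phase-space reconstructions: delay and
# embedding-dimension selection, correlation dimension (Grassberger-
# Procaccia), approximate entropy, rescaled-range Hurst exponent, and the
# PCA eigenvalue-spread index. These per-window feature profiles are the
# samples entering the long-term T-index synchronization statistic.

#' Delay-embedding matrix
#'
#' Row `i` is the delay vector `(x(i), x(i+tau), ..., x(i+(m-1)tau))`.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (`>= 1`).
#' @param tau Delay in samples (`>= 1`).
#' @return Matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @export
embed_delay <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  if (m < 1 || tau < 1 || n < 1)
    stop("series too short for m = ", m, ", tau = ", tau)
  idx <- outer(seq_len(n), (0:(m - 1)) * tau, `+`)
  matrix(x[idx], nrow = n)
}

#' Embedding delay from the auto-mutual-information profile
#'
#' Mutual information between `x(t)` and `x(t + lag)` for `lag = 1 ..
#' max_lag`; returns the first local minimum. If none exists, the first lag
#' whose auto-MI drops below `1/e` of the lag-1 value is used; failing that,
#' `max_lag` is returned with attribute `flagged = TRUE`.
#'
#' @param x Numeric series (non-constant).
#' @param max_lag Largest lag considered (must be `< length(x) / 4`).
#' @param bins Histogram bins for the MI estimates.
#' @return Integer delay (samples), possibly with attribute `flagged`.
#' @export
delay_from_automi <- function(x, max_lag = 50, bins = 16) {
  if (sd(x) == 0) stop("constant sequence has no auto-MI structure")
  if (max_lag >= length(x) / 4) stop("`max_lag` must be < length(x)/4")
  n <- length(x)
  ami <- vapply(seq_len(max_lag), function(l)
    mutual_information(x[1:(n - l)], x[(1 + l):n], bins = bins), 0)
  for (l in seq_len(max_lag - 1L)) {
    if (ami[l] <= ami[l + 1L] && (l == 1L || ami[l] <= ami[l - 1L]))
      return(l)
  }
  drop <- which(ami < ami[1] / exp(1))
  if (length(drop)) return(drop[1])
  structure(max_lag, flagged = TRUE)
}

#' Minimal embedding dimension by Cao's method
#'
#' Computes Cao's `E1(m) = E(m+1)/E(m)` from nearest-neighbour distance
#' ratios and selects the smallest dimension at which `E1` saturates
#' (`|E1(m+1) - E1(m)| < tol` with `E1(m+1) > 0.9`). `E2(m)` (from the
#' future-component statistic `E*`) distinguishes deterministic series,
#' where `E2` deviates from 1 at some `m`, from stochastic ones, where `E2`
#' stays near 1 at every `m` and `E1` saturates only slowly.
#'
#' @param x Numeric series.
#' @param tau Embedding delay in samples.
#' @param max_m Largest dimension probed (default 10).
#' @param tol Saturation tolerance on successive `E1` differences
#'   (default 0.05).
#' @param n_max At most this many delay vectors are used (a contiguous
#'   prefix: even-stride subsampling would alias near-periodic signals) to
#'   bound the quadratic neighbour search (default 1000).
#' @return List with `m` (selected dimension; `max_m` when `E1` never
#'   saturates, flagged), `is_deterministic`, `E1`, `E2`, `flagged`.
#' @export
cao_embedding_dim <- function(x, tau, max_m = 10, tol = 0.05, n_max = 1000) {
  if (length(x) <= max_m * tau + 10)
    stop("series too short for max_m = ", max_m, " at tau = ", tau)
  E <- embed_delay(x, max_m + 1L, tau)
  if (nrow(E) > n_max) E <- E[seq_len(n_max), , drop = FALSE]
  res <- cao_cpp(E, max_m)
  E1 <- res$E[-1] / res$E[-max_m]              # E1(m), m = 1..max_m-1
  E2 <- res$Estar[-1] / res$Estar[-max_m]
  is_det <- any(abs(E2 - 1) > 0.1, na.rm = TRUE)
  m_sel <- NA_integer_
  for (m in seq_len(length(E1) - 1L)) {
    if (!is.na(E1[m]) && !is.na(E1[m + 1]) &&
        abs(E1[m + 1] - E1[m]) < tol && E1[m + 1] > 0.9) {
      m_sel <- m + 1L
      break
    }
  }
  flagged <- is.na(m_sel)
  if (flagged) m_sel <- as.integer(max_m)
  list(m = m_sel, is_deterministic = is_det, E1 = E1, E2 = E2,
       flagged = flagged)
}

#' Correlation dimension of a point cloud
#'
#' Grassberger-Procaccia estimate on explicit phase-space points: the
#' correlation integral `C(r)` is the fraction of point pairs closer than
#' `r` (Euclidean norm), evaluated on log-spaced radii between the 0.1th
#' and 8th percentile of pairwise distances (large radii are excluded
#' because attractor-boundary saturation depresses the local slope there);
#' the dimension is the least-squares slope of `ln C(r)` against `ln r`
#' over the longest contiguous run of at least 5 radii whose local slopes
#' stay within 10 percent of the run mean.
#'
#' @param points Numeric matrix of phase-space points (rows).
#' @param n_radii Number of log-spaced radii (default 24).
#' @param theiler Exclude pairs closer than this many rows in time
#'   (default 0: all pairs with `i != j` enter, the strict correlation-sum
#'   definition; a positive value suppresses temporal-autocorrelation bias).
#' @param n_max At most this many points are used, evenly subsampled
#'   (default 2000).
#' @param probs Distance-percentile bounds of the radius band
#'   (default `c(0.001, 0.08)`).
#' @return List with `d2` (estimate; `NA` on failure), `radii`, `C`,
#'   `scaling` (indices of the fitted run), `flagged`.
#' @export
corr_dim_points <- function(points, n_radii = 24, theiler = 0, n_max = 2000,
                            probs = c(0.001, 0.08)) {
  points <- as.matrix(points)
  idx <- seq_len(nrow(points))
  if (nrow(points) > n_max) {
    keep <- round(seq(1, nrow(points), length.out = n_max))
    points <- points[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  if (nrow(points) < 100) stop("need at least 100 points")
  d <- sort(pair_distances_cpp(points, as.integer(idx), as.integer(theiler)))
  d <- d[d > 0]
  if (length(d) < 100) stop("too few distinct pairwise distances")
  qs <- quantile(d, probs, names = FALSE)
  if (qs[1] <= 0 || qs[2] <= qs[1]) stop("degenerate distance distribution")
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  cnt <- findInterval(radii * (1 - 1e-12), d)    # pairs with distance < r
  keep <- cnt > 0
  radii <- radii[keep]; cnt <- cnt[keep]
  C <- cnt / length(d)
  lr <- log(radii); lC <- log(C)
  slopes <- diff(lC) / diff(lr)
  run <- longest_stable_run(slopes, rel_tol = 0.10, min_len = 4)
  if (is.null(run))
    return(list(d2 = NA_real_, radii = radii, C = C, scaling = NULL,
                flagged = TRUE))
  pts <- run[1]:(run[2] + 1L)                    # slopes k spans radii k, k+1
  fit <- lm(lC[pts] ~ lr[pts])
  list(d2 = unname(coef(fit)[2]), radii = radii, C = C, scaling = pts,
       flagged = FALSE)
}

# Longest contiguous run of at least `min_len` slopes whose spread stays
# within rel_tol of the run mean; returns c(start, end) indices or NULL.
longest_stable_run <- function(s, rel_tol, min_len) {
  n <- length(s)
  best <- NULL
  for (a in seq_len(n - min_len + 1L)) {
    for (b in seq(a + min_len - 1L, n)) {
      seg <- s[a:b]
      mu <- mean(seg)
      if (mu <= 0 || max(abs(seg - mu)) > rel_tol * mu) break
      if (is.null(best) || (b - a) > (best[2] - best[1])) best <- c(a, b)
    }
  }
  best
}

#' Correlation dimension of a time series
#'
#' Reconstructs the phase space of `x` with the given embedding parameters
#' and applies [corr_dim_points()].
#'
#' @param x Numeric series (the reconstruction needs at least 500 points).
#' @param m Embedding dimension.
#' @param tau Embedding delay (samples).
#' @inheritParams corr_dim_points
#' @return As [corr_dim_points()].
#' @export
correlation_dimension <- function(x, m, tau, n_radii = 24, theiler = 0,
                                  n_max = 2000, probs = c(0.001, 0.08)) {
  ps <- embed_delay(x, m, tau)
  if (nrow(ps) < 500) stop("need at least 500 phase-space points")
  corr_dim_points(ps, n_radii = n_radii, theiler = theiler, n_max = n_max,
                  probs = probs)
}

#' Approximate entropy
#'
#' Standard ApEn with Chebyshev distance and self-matches, tolerance
#' `r = r_frac * SD(x)`. When a sampling rate is supplied the statistic is
#' computed on consecutive one-second units and averaged, so long windows
#' contribute a stable regularity summary rather than one giant template
#' count; constant input returns 0 by convention.
#'
#' @param x Numeric series (`length(x) >= 50`).
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of the SD (default 0.25).
#' @param fs Optional sampling rate in Hz; if given and the series spans at
#'   least two seconds, ApEn is averaged over 1-s units (`unit_s`).
#' @param unit_s Unit duration in seconds (default 1).
#' @return Approximate entropy (natural-log units, `>= 0` up to estimator
#'   noise).
#' @export
approximate_entropy <- function(x, m = 2, r_frac = 0.25, fs = NULL,
                                unit_s = 1) {
  if (length(x) < 50) stop("need at least 50 samples")
  s <- sd(x)
  if (s == 0) return(0)
  if (!is.null(fs)) {
    ulen <- round(unit_s * fs)
    n_units <- floor(length(x) / ulen)
    if (n_units >= 2) {
      vals <- vapply(seq_len(n_units), function(k) {
        seg <- x[((k - 1) * ulen + 1):(k * ulen)]
        ssd <- sd(seg)
        if (ssd == 0) return(0)
        apen_cpp(seg, as.integer(m), r_frac * ssd)
      }, 0)
      return(mean(vals))
    }
  }
  apen_cpp(x, as.integer(m), r_frac * s)
}

#' Hurst exponent by rescaled-range analysis
#'
#' For a ladder of sub-series lengths `n` (geometric from `min_n` to half
#' the series, at least 8 rungs), each length is covered by non-overlapping
#' blocks; per block the cumulative deviation from the block mean gives the
#' range `R`, rescaled by the block SD `S`. The exponent is the slope of
#' `log(R/S)` against `log(n)`. With `corrected = TRUE` (default) the
#' small-sample Anis-Lloyd expectation of `R/S` under independence is
#' subtracted before fitting and 0.5 re-added, removing the well-known
#' upward bias of the raw statistic at these block sizes.
#'
#' @param x Numeric series, `length(x) >= 256`.
#' @param min_n Smallest block length (default 16).
#' @param corrected Apply the Anis-Lloyd small-sample correction
#'   (default `TRUE`).
#' @return Hurst estimate clipped to `[0, 1]`; attribute `flagged` is set
#'   when the raw slope fell outside `[0, 1]` or usable rungs were scarce.
#' @export
hurst_rs <- function(x, min_n = 16, corrected = TRUE) {
  N <- length(x)
  if (N < 256) stop("need at least 256 samples")
  sizes <- unique(round(exp(seq(log(min_n), log(N / 2),
                                length.out = max(8, round(log2(N)))))))
  rs <- rep(NA_real_, length(sizes))
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    nb <- floor(N / n)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * n + 1):(b * n)]
      s <- sqrt(mean((seg - mean(seg))^2))
      if (s == 0) return(NA_real_)
      w <- cumsum(seg - mean(seg))
      (max(w) - min(w)) / s
    }, 0)
    if (any(!is.na(vals))) rs[k] <- mean(vals, na.rm = TRUE)
  }
  ok <- !is.na(rs) & rs > 0
  if (sum(ok) < 3) stop("too few usable block sizes (zero-variance blocks?)")
  y <- log(rs[ok])
  if (corrected) y <- y - log(rs_expected(sizes[ok]))
  fit <- lm(y ~ log(sizes[ok]))
  h <- unname(coef(fit)[2]) + if (corrected) 0.5 else 0
  flagged <- h < 0 || h > 1
  structure(min(1, max(0, h)), flagged = flagged)
}

# Anis-Lloyd expected R/S of an i.i.d. series at block length n.
rs_expected <- function(n) {
  vapply(n, function(m) {
    i <- seq_len(m - 1)
    pre <- if (m <= 340) gamma((m - 1) / 2) / (sqrt(pi) * gamma(m / 2))
           else 1 / sqrt(m * pi / 2)
    ((m - 0.5) / m) * pre * sum(sqrt((m - i) / i))
  }, 0)
}

#' PCA eigenvalue-spread index
#'
#' Measures the anisotropy of the delay-embedded trajectory: the phase-space
#' matrix is column-centred, its covariance `A = Y'Y / n_points`
#' eigendecomposed, eigenvalues normalized by their sum `gamma`, and the
#' index is the population SD of `log10(p_i / gamma)`. An isotropic cloud
#' (equal eigenvalues) scores 0; strongly flattened trajectories score
#' high. Eigenvalues below `1e-12 * gamma` are floored there before the
#' logarithm (flagged), so rank-deficient embeddings remain finite.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (`>= 2`).
#' @param tau Embedding delay (samples).
#' @return The index (non-negative); attribute `flagged` marks floored
#'   eigenvalues.
#' @export
pcai <- function(x, m, tau) {
  if (m < 2) stop("`m` must be >= 2")
  Y <- embed_delay(x, m, tau)
  Y <- sweep(Y, 2, colMeans(Y))
  A <- crossprod(Y) / nrow(Y)
  p <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  pcai_from_eigenvalues(p)
}

#' @rdname pcai
#' @param p Covariance eigenvalues (non-negative, not all zero).
#' @export
pcai_from_eigenvalues <- function(p) {
  gam <- sum(p)
  if (gam <= 0) stop("constant signal: zero total variance in phase space")
  floor_at <- 1e-12 * gam
  flagged <- any(p < floor_at)
  p <- pmax(p, floor_at)
  lp <- log10(p / gam)
  structure(sqrt(mean((lp - mean(lp))^2)), flagged = flagged)
}

#' Per-channel, per-window nonlinear feature profiles
#'
#' Computes one value of each requested feature per channel per window.
#' Embedding parameters (delay from auto-MI, dimension from Cao's method)
#' are estimated once per channel on up to `global_n` samples of its
#' concatenated windows and reused everywhere (`policy = "global"`), or
#' re-estimated inside every window (`policy = "local"`); fixed parameters
#' can be supplied instead. Per-window estimation failures become missing
#' values and never abort the profile.
#'
#' @param ws A `window_set` from [segment_windows()].
#' @param features Subset of `c("CD", "ApEn", "HE", "PCAI")`.
#' @param policy `"global"` (default) or `"local"` embedding-parameter
#'   estimation.
#' @param params Optional list with `m` and `tau` overriding estimation.
#' @param max_m,max_lag Search bounds for the embedding estimation.
#' @param global_n Samples per channel used for global parameter estimation
#'   (default 6000).
#' @param cd_n_max Phase-space points per correlation-dimension estimate
#'   (default 600).
#' @return Long-format data frame: `channel`, `window`, `stage`, `feature`,
#'   `value`, `flagged`; attribute `params` holds the per-channel embedding
#'   parameters used.
#' @export
feature_profiles <- function(ws, features = c("CD", "ApEn", "HE", "PCAI"),
                             policy = c("global", "local"), params = NULL,
                             max_m = 8, max_lag = 40, global_n = 6000,
                             cd_n_max = 600) {
  stopifnot(inherits(ws, "window_set"))
  policy <- match.arg(policy)
  features <- match.arg(features, c("CD", "ApEn", "HE", "PCAI"),
                        several.ok = TRUE)
  nch <- length(ws$labels)
  nwin <- length(ws$windows)
  if (nwin < 1) stop("empty window set")
  need_embed <- any(c("CD", "PCAI") %in% features)
  est_params <- function(x) {
    tau <- tryCatch(as.integer(delay_from_automi(x, max_lag = max_lag)),
                    error = function(e) 1L)
    m <- tryCatch(cao_embedding_dim(x, tau, max_m = max_m)$m,
                  error = function(e) as.integer(max_m))
    list(m = max(2L, m), tau = max(1L, tau))
  }
  chan_params <- vector("list", nch)
  if (need_embed && is.null(params) && policy == "global") {
    for (i in seq_len(nch)) {
      x <- unlist(lapply(ws$windows, function(w) w[i, ]))
      chan_params[[i]] <- est_params(x[seq_len(min(length(x), global_n))])
    }
  }
  out <- vector("list", nch * nwin * length(features))
  k <- 0L
  for (i in seq_len(nch)) {
    for (w in seq_len(nwin)) {
      x <- ws$windows[[w]][i, ]
      pars <- if (!is.null(params)) params
              else if (policy == "global") chan_params[[i]]
              else if (need_embed) est_params(x) else NULL
      for (f in features) {
        val <- tryCatch(switch(f,
          CD = {
            r <- correlation_dimension(x, pars$m, pars$tau, n_max = cd_n_max)
            structure(r$d2, flagged = r$flagged)
          },
          ApEn = approximate_entropy(x, fs = ws$fs),
          HE = hurst_rs(x),
          PCAI = pcai(x, pars$m, pars$tau)),
          error = function(e) structure(NA_real_, flagged = TRUE))
        k <- k + 1L
        out[[k]] <- data.frame(channel = ws$labels[i], window = w,
                               stage = ws$stage_of_window[w], feature = f,
                               value = as.numeric(val),
                               flagged = isTRUE(attr(val, "flagged")))
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "params") <- chan_params
  res
}
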