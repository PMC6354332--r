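# Independent oracle implementations, deliberately written without reusing
# any package internals, plus small fixture builders.

# Pooled two-sample t, transcribed directly from the defining formulas.
brute_pooled_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  s1 <- sum((a - m1)^2) / (n1 - 1)
  s2 <- sum((b - m2)^2) / (n2 - 1)
  sc <- (s1 * (n1 - 1) + s2 * (n2 - 1)) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sc * (1 / n1 + 1 / n2))
}

# Correlation-integral slope by direct pair counting with stats::dist,
# fit over a fixed radius band.
brute_corr_dim <- function(points, probs = c(0.001, 0.08), n_radii = 16) {
  d <- as.numeric(dist(points))
  d <- sort(d[d > 0])
  qs <- quantile(d, probs, names = FALSE)
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  C <- vapply(radii, function(r) sum(d < r), 0) / length(d)
  unname(coef(lm(log(C) ~ log(radii)))[2])
}

# Direct-definition ApEn (no unit splitting), natural logs, self-matches.
brute_apen <- function(x, m = 2, r = 0.25 * sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    tmpl <- sapply(seq_len(nm), function(i) x[i:(i + mm - 1)])
    cnt <- vapply(seq_len(nm), function(i) {
      di <- apply(abs(tmpl - tmpl[, i]), 2, max)
      sum(di <= r)
    }, 0)
    mean(log(cnt / nm))
  }
  phi(m) - phi(m + 1)
}

# Gaussian mutual information in log10 units.
gaussian_mi_lg <- function(rho) -0.5 * log(1 - rho^2) / log(10)

# A window_set built directly from a channels x samples matrix.
make_window_set <- function(mats, labels, fs = 250, window_s = NULL,
                            stages = NULL) {
  if (is.null(window_s)) window_s <- ncol(mats[[1]]) / fs
  structure(list(windows = mats,
                 starts_s = seq(0, by = window_s, length.out = length(mats)),
                 window_s = window_s, overlap_frac = 0,
                 stage_of_window = stages %||%
                   rep(NA_character_, length(mats)),
                 labels = labels, fs = fs),
            class = "window_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

offdiag_values <- function(m) {
  v <- if (is.list(m)) m$values else m
  v[row(v) != col(v)]
}

# A synthetic mi_matrix with prescribed off-diagonal values.
make_mi_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- sprintf("chan%02d", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, bins = 16, window = NA),
            class = "mi_matrix")
}

# A brain_network whose core node set is forced: `hub` channels are joined
# to all `spokes`.
make_star_network <- function(hub, spokes, labels) {
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (h in hub) for (s in spokes) m[h, s] <- m[s, h] <- 1
  threshold_network(m, rule = "fixed", value = 0.5)
}
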