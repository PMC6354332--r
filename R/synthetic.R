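# Synthetic multichannel EEG with planted, stage-dependent coupling. Every
# downstream stage of the method is validated against recordings whose focus
# channel and coupling schedule are known exactly.

#' Synthetic-recording configuration
#'
#' @param n_channels Number of channels (default 22, labelled with
#'   [montage_10_20()]).
#' @param fs Sampling rate in Hz (default 250; clinical rates such as
#'   2000 Hz are supported but unnecessary for validation).
#' @param stage_plan Data frame with columns `stage` (`AS`/`SS`/`IS`) and
#'   `duration_s`, in temporal order.
#' @param focus_channel Label of the planted focus (driver) channel.
#' @param driven_channels Labels of channels driven by the focus.
#' @param coupling Named numeric vector mapping stage to coupling strength
#'   in `[0, 1]`. A driven channel is the variance-normalized mixture
#'   `sqrt(1 - c^2) * own_noise + c * lagged(focus)`, so its variance does
#'   not depend on the coupling.
#' @param lag_ms Driver-to-driven lag in milliseconds.
#' @param base_kind Baseline dynamics: `"ar2_alpha"` (AR(2) processes with
#'   channel-specific spectral peaks spread over 8.5-11.5 Hz, mimicking
#'   the within-subject spatial variability of the scalp alpha rhythm),
#'   `"white"` (Gaussian noise), or `"fgn"` (fractional Gaussian noise
#'   with Hurst exponent `hurst`).
#' @param hurst Hurst exponent for `base_kind = "fgn"`.
#' @param ictal_focus During ictal stages the focus channel itself emits a
#'   spike-wave-like discharge (a harmonic-rich nonlinear oscillation at
#'   `ictal_spike_hz`, lightly mixed with its background process) instead of
#'   its background rhythm, as a real seizure-onset channel does; the
#'   discharge is what propagates to the driven channels (default `TRUE`).
#' @param ictal_spike_hz Fundamental frequency of the ictal discharge
#'   (default 3.7 Hz, in the clinical spike-wave range).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   recording bit for bit.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 22,
                         fs = 250,
                         stage_plan = data.frame(
                           stage = c("AS", "SS", "IS"),
                           duration_s = c(60, 60, 60)),
                         focus_channel = "T3",
                         driven_channels = c("T5", "F7", "C3", "P3", "m1"),
                         coupling = c(AS = 0.1, SS = 0.4, IS = 0.9),
                         lag_ms = 8,
                         base_kind = c("ar2_alpha", "white", "fgn"),
                         hurst = 0.7,
                         ictal_focus = TRUE,
                         ictal_spike_hz = 3.7,
                         seed = 1) {
  base_kind <- match.arg(base_kind)
  labels <- if (n_channels == 22) montage_10_20()
            else sprintf("chan%02d", seq_len(n_channels))
  if (!focus_channel %in% labels)
    stop("focus channel ", focus_channel, " not in montage")
  if (!all(driven_channels %in% setdiff(labels, focus_channel)))
    stop("driven channels must be montage labels other than the focus")
  stage_plan <- as.data.frame(stage_plan)
  stopifnot(all(stage_plan$stage %in% STAGES), all(stage_plan$duration_s > 0))
  if (any(coupling < 0 | coupling > 1)) stop("coupling must lie in [0, 1]")
  if (!all(unique(stage_plan$stage) %in% names(coupling)))
    stop("coupling must name every stage in the plan")
  structure(list(n_channels = n_channels, fs = fs, stage_plan = stage_plan,
                 labels = labels, focus_channel = focus_channel,
                 driven_channels = driven_channels, coupling = coupling,
                 lag_ms = lag_ms, base_kind = base_kind, hurst = hurst,
                 ictal_focus = ictal_focus, ictal_spike_hz = ictal_spike_hz,
                 seed = seed),
            class = "synth_config")
}

# Unit-variance AR(2) with spectral peak at f0 Hz (pole radius rho).
ar2_series <- function(n, f0, fs, rho = 0.95) {
  x <- as.numeric(arima.sim(list(ar = c(2 * rho * cos(2 * pi * f0 / fs),
                                        -rho^2)), n))
  x / sd(x)
}

#' Generate a synthetic recording with a planted focus
#'
#' Each channel receives an independent baseline process; during each stage,
#' every driven channel is replaced by the variance-normalized mixture
#' `sqrt(1 - c^2) * own + c * lag(focus)` with `c` the stage's coupling
#' strength. Stage annotations follow the configuration's plan.
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` (an [eeg_recording()]) and `truth` (list
#'   with `focus_channel`, `driven_channels`, `coupling`, `lag_samples`,
#'   `seed`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  lag <- round(cfg$lag_ms / 1000 * fs)
  seg_n <- round(cfg$stage_plan$duration_s * fs)
  n_tot <- sum(seg_n)
  wlen_max <- n_tot                       # lag sanity bound
  if (lag >= min(seg_n)) stop("lag exceeds one stage segment")
  nch <- cfg$n_channels
  peaks <- seq(8.5, 11.5, length.out = nch)  # channel-specific alpha peaks
  base <- matrix(0, nch, n_tot + lag)
  for (i in seq_len(nch)) {
    base[i, ] <- switch(cfg$base_kind,
      ar2_alpha = ar2_series(n_tot + lag, peaks[i], fs),
      white = rnorm(n_tot + lag),
      fgn = generate_fgn(cfg$hurst, n_tot + lag))
  }
  foc <- match(cfg$focus_channel, cfg$labels)
  drv <- match(cfg$driven_channels, cfg$labels)
  X <- base[, (lag + 1):(lag + n_tot), drop = FALSE]   # own signals
  ends <- cumsum(seg_n); starts <- c(1, head(ends, -1) + 1)
  driver <- X[foc, ]                       # focus output on the 1..n_tot grid
  if (cfg$ictal_focus) {
    for (s in which(cfg$stage_plan$stage == "IS")) {
      idx <- starts[s]:ends[s]
      t_s <- (idx - 1) / fs
      f0 <- cfg$ictal_spike_hz
      w <- sin(2 * pi * f0 * t_s) + 0.45 * sin(4 * pi * f0 * t_s + 1.2) +
        0.25 * sin(6 * pi * f0 * t_s + 2.3)
      w <- w / sd(w)
      driver[idx] <- sqrt(0.9) * w + sqrt(0.1) * X[foc, idx]
    }
    X[foc, ] <- driver
  }
  driver_lagged <- c(base[foc, seq_len(lag)], driver)[seq_len(n_tot)]
  for (s in seq_len(nrow(cfg$stage_plan))) {
    c0 <- unname(cfg$coupling[cfg$stage_plan$stage[s]])
    idx <- starts[s]:ends[s]
    for (i in drv)
      X[i, idx] <- sqrt(1 - c0^2) * base[i, idx + lag] +
        c0 * driver_lagged[idx]
  }
  stages <- data.frame(start_s = (starts - 1) / fs, end_s = ends / fs,
                       stage = cfg$stage_plan$stage)
  rec <- eeg_recording(X, fs = fs, labels = cfg$labels, stages = stages)
  truth <- list(focus_channel = cfg$focus_channel,
                driven_channels = cfg$driven_channels,
                coupling = cfg$coupling, lag_samples = lag, seed = cfg$seed)
  list(recording = rec, truth = truth)
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact (Davies-Harte) sampling of fractional Gaussian noise with Hurst
#' exponent `h`; `h = 0.5` reduces to white noise, `h > 0.5` gives
#' persistent increments with lag-1 autocorrelation `2^(2h-1) - 1`.
#'
#' @param h Hurst exponent in `(0, 1)`.
#' @param n Series length (`>= 256`; shorter series make downstream Hurst
#'   estimation unreliable).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`, unit marginal variance.
#' @export
generate_fgn <- function(h, n, seed = NULL) {
  if (h <= 0 || h >= 1) stop("`h` must lie in (0, 1)")
  if (n < 256) stop("`n` must be >= 256")
  if (!is.null(seed)) set.seed(seed)
  acov <- function(k) 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) +
                               abs(k - 1)^(2 * h))
  m <- 2^ceiling(log2(2 * (n - 1)))
  g <- acov(0:(m / 2))
  circ <- c(g, rev(g[2:(m / 2)]))
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0                 # clip tiny negative round-off
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  w <- fft(sqrt(lambda / (2 * m)) * z)
  Re(w)[seq_len(n)]
}

#' x-component of the Lorenz system
#'
#' Deterministic chaotic test signal (sigma = 10, rho = 28, beta = 8/3)
#' integrated with `deSolve`, transient discarded. Used as a known-attractor
#' input for embedding and correlation-dimension checks.
#'
#' @param n Number of samples to return.
#' @param dt Sampling interval of the returned series (default 0.02).
#' @param transient Number of initial samples discarded (default 500).
#' @return Numeric vector of length `n`.
#' @export
lorenz_series <- function(n, dt = 0.02, transient = 500) {
  deriv <- function(t, y, p)
    list(c(10 * (y[2] - y[1]),
           y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  times <- seq(0, (n + transient) * dt, by = dt)
  out <- deSolve::ode(c(1, 1, 20), times, deriv, NULL, method = "ode45")
  out[(transient + 1):(transient + n), 2]
}
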