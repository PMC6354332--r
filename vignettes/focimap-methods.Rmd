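---
title: "Mapping dynamic brain-network synchronization to localize epileptic foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dynamic brain-network synchronization to localize epileptic foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focimap)
```

## The problem and the model

Epileptic seizures are episodes of abnormal, hyper-synchronous neuronal
discharge. Where that discharge originates (the epileptogenic focus) is the
key clinical question for surgical planning, and scalp EEG is the cheapest
window onto it. `focimap` localizes candidate foci by mapping how
**synchronization between EEG channels** changes across vigilance stages —
awake (AS), sleep (SS) and ictal (IS) — on two complementary time scales:

1. **Short-term synchronization** is measured window-by-window with binned
   mutual information. For channels $X$ and $Y$ discretized on an
   $N \times N$ partition, with marginal cell probabilities $p_i$ and joint
   probabilities $p_{ij}$,
   $$H_{xy} = -\sum_{i,j} p_{ij}\,\lg p_{ij}, \qquad
     I_{xy} = H_x + H_y - H_{xy},$$
   using decimal logarithms throughout. $I_{xy}$ is zero iff the binned
   signals are independent, and is estimated per channel pair per sliding
   window.

2. **Long-term synchronization** compares the *dynamics* of nonlinear
   features between channels. Each channel's signal is reduced, one value
   per window, to four phase-space descriptors — correlation dimension
   (CD), approximate entropy (ApEn), Hurst exponent (HE), and a PCA
   eigenvalue-spread index (PCAI) — and two channels are compared by the
   pooled-variance two-sample statistic
   $$T = \frac{\bar X_1 - \bar X_2}
              {\sqrt{S_C^2\left(\frac{1}{n_1}+\frac{1}{n_2}\right)}},
     \qquad
     S_C^2 = \frac{(n_1-1)S_1^2 + (n_2-1)S_2^2}{n_1+n_2-2},$$
   over their per-window feature values within one stage. Channels with
   concordant feature dynamics have $|T|$ near zero.

Synchronization matrices are thresholded into undirected **brain networks**
on the channel labels, and the **core node** — the maximum-degree node — is
the localization readout: tracked across windows it traces the *main path*
of discharge propagation, and a consensus over the four feature networks
nominates the focus.

## Preprocessing defaults

* Band-pass 0.3–75 Hz, fourth-order Butterworth applied forward–backward
  (`signal::filtfilt`), realized as a high-pass/low-pass cascade. Zero-phase
  filtering is essential here: a causal filter would add frequency-dependent
  lag that distorts the lagged driver→driven coupling the method is trying
  to detect. The cascade form stays numerically stable when the low edge is
  a tiny fraction of the sampling rate (0.3 Hz at 2000 Hz).
* Sliding windows of 12 s with 50 % overlap; the trailing partial window is
  dropped. A window's stage is the annotation covering its midpoint;
  windows straddling a boundary are deliberately not split (simple and
  deterministic).
* Mutual information uses $N = 16$ bins per axis. At the validation scale
  (12 s × 250 Hz = 3000 samples per window) this leaves roughly ten
  expected counts per occupied joint cell. The bin range is *robust* by
  default: equal-width bins span the mean ± 3 SD (clamped to the observed
  range) and outliers fall into the edge bins. Spanning the raw min–max
  instead (available as `range = "minmax"`) lets single outliers stretch
  the partition and measurably worsens the estimator — with min–max bins
  the bivariate-Gaussian benchmark at $\rho = 0.9$ is recovered ~11 % low,
  with robust bins ~6 % low. Marginal entropies are always computed from
  the margins of the joint histogram, so $I = H_x + H_y - H_{xy}$ is an
  identity and $I \ge 0$ holds structurally.

## Nonlinear features: estimator choices

**Embedding.** The delay $\tau$ is the first local minimum of the
auto-mutual-information profile (fallback: first drop below $1/e$ of the
lag-1 value; last resort: the maximum lag, flagged). The dimension $m$
comes from Cao's nearest-neighbour method: $E1(m)$ is the mean ratio of
$(m+1)$- to $m$-dimensional neighbour distances, and $m$ is selected where
$E1$ saturates ($|E1(m{+}1)-E1(m)| < 0.05$, $E1 > 0.9$); the companion
$E2$ statistic flags stochastic signals, for which $E1$ saturates only
slowly and the selected $m$ is the search bound, flagged. Candidate delay
vectors are a contiguous prefix (at most 1000): an even-stride subsample
can resonate with near-periodic signals and collapse the sampled attractor
onto a few points. By default embedding parameters are estimated once per
channel on the full recording and reused in every window
(`policy = "global"`); per-window estimation is available but makes
profiles noisier.

**Correlation dimension** follows Grassberger–Procaccia: pair counts of the
phase-space points on log-spaced radii, $d_2$ = least-squares slope of
$\ln C(r)$ vs $\ln r$ over a scaling region. The scaling region is chosen
deterministically: radii between the 0.1th and 8th percentile of pairwise
distances, longest contiguous run of at least five radii whose local
slopes stay within 10 % of the run mean. The upper bound matters: at radii
approaching the attractor diameter, boundary saturation depresses the
slope (a uniform unit square reads ~1.7 when the band extends to the
median distance, ~1.93 with this band; the Lorenz attractor reads ~2.0
against the literature ~2.05). Pairs are counted strictly as $i \ne j$
(the textbook correlation sum); a Theiler window for suppressing
temporal-autocorrelation bias is available (`theiler`) but off by default
so the statistic matches the strict definition.

**Approximate entropy** is the standard Pincus ApEn($m{=}2$,
$r = 0.25\,\mathrm{SD}$) with Chebyshev distance and self-matches. Long
windows are split into one-second units and the per-unit values averaged,
so a 12-s window contributes a stable regularity summary rather than one
giant template count. Constant input returns 0 by convention.

**Hurst exponent** uses rescaled-range analysis on a geometric ladder of
block sizes (16 up to half the series, ≥ 8 rungs, non-overlapping blocks
averaged per rung). The raw log–log slope carries the well-known
small-sample upward bias at these block sizes, which is large enough to
push strongly anti-persistent series ($h = 0.3$) outside a ±0.1 recovery
band; the default therefore subtracts the Anis–Lloyd expectation of
$R/S$ under independence before fitting (`corrected = TRUE`), restoring
recovery to ±0.07 across $h \in \{0.3, 0.5, 0.8\}$. Estimates are clipped
to $[0,1]$ and flagged if the raw slope fell outside.

**PCAI** is the population SD of $\log_{10}(p_i/\gamma)$ over the
eigenvalues $p_i$ of the embedded trajectory's covariance matrix
($\gamma = \sum_i p_i$): 0 for an isotropic cloud, large for flattened
trajectories. Eigenvalues below $10^{-12}\gamma$ are floored there before
the logarithm (flagged) so rank-deficient embeddings stay finite.
Estimation failures inside a window become missing values in the feature
profile — never aborts — and missing windows are dropped pairwise in the
T-index.

## Networks and localization

For MI matrices, an edge joins two channels when their MI strictly exceeds
the threshold: the matrix's own off-diagonal mean (`rule = "mean"`) or a
fixed value. Two different questions need two different threshold scopes:

* **Core-node tracking within a window** uses the window's own mean — the
  question is *which channels are most synchronized right now*, a relative
  readout.
* **Degree dynamics across stages** use one recording-wide fixed threshold
  (the pooled off-diagonal mean over all windows). A per-window threshold
  is self-normalizing — it rises exactly when the window's synchronization
  rises — and in simulation it *reverses* the expected ordering of mean
  degree across stages; holding the threshold fixed makes degree
  comparable across time, and the awake < sleep < ictal ordering emerges
  as expected.

For **T-index networks** the package's default direction is *anomaly*: an
edge joins channels whose $|T|$ *exceeds* the threshold, and the core node
is the channel whose feature dynamics diverge from the most others. The
reasoning: during a seizure the focus channel's nonlinear features break
away from the background (its row of the T matrix "lights up"), while the
similarity reading (edges for small $|T|$) cannot distinguish *coupled*
channel pairs from *independent channels with the same feature
distribution* — with realistic profile lengths, identically-distributed
pairs dominate the small-$|T|$ range (for two 9-window profiles,
$P(|t_{16}| < 0.3) \approx 0.23$), so a similarity network has no unique
hub. Planted-focus simulations confirm this: consensus recovery is ~20 %
under the similarity direction and ~87 % under the anomaly direction. The
similarity direction remains available (`direction = "similarity"`).

The **consensus focus** counts, across the four feature networks of the
ictal stage, how often each channel appears among the core nodes; ties
break by summed degree, then label. The ictal stage is used because that
is when the focus is electrographically active.

## The synthetic generator as ground truth

No clinical recordings ship with the package, so every claim is validated
against `generate_recording()`, which emulates:

* **Background**: each channel an independent AR(2) process with unit
  variance and a channel-specific spectral peak spread over 8.5–11.5 Hz,
  matching the within-subject spatial variability of the alpha rhythm
  (individual peak frequencies differ by roughly ±1–1.5 Hz across scalp
  sites, with heavily overlapping feature distributions). The scale of
  this heterogeneity is a genuine sensitivity of the nonlinear track and
  was chosen for realism, not convenience: because the pooled-T statistic
  divides mean differences by window-to-window variability, background
  channels with *strongly* separated, stable rhythms (say a 6 Hz
  peak-frequency gradient) would register as stronger "anomalies" than a
  true discharge channel, whose features are distinctive in mean but
  noisier window to window. Exaggerated background heterogeneity is
  therefore the adversarial case for T-index localization — worth knowing
  when interpreting real recordings with, e.g., a strong regional theta
  asymmetry. White-noise and fractional-Gaussian-noise backgrounds (exact
  Davies–Harte synthesis, known Hurst exponent) are available for
  estimator checks.
* **Ictal discharge**: during IS the focus channel emits a harmonic-rich
  3.7 Hz spike-wave-like oscillation (90 % variance share over its
  background process), as a seizure-onset channel does.
* **Coupling**: each driven channel is the variance-normalized mixture
  $y = \sqrt{1-c^2}\,\mathrm{own} + c\,\mathrm{lag}(\mathrm{focus})$ with
  $c$ set per stage (defaults AS 0.1, SS 0.4, IS 0.9) and an 8 ms lag.
  Normalized mixing keeps channel variance coupling-invariant, so synchrony
  changes are not confounded with amplitude changes.
* Everything is reproducible bit-for-bit from an integer seed, and the
  planted focus/coupling schedule is returned as ground truth.

Validation scale: 22 channels at 250 Hz, 60 s per stage (nine 12-s windows
at 50 % overlap per stage), 20 independent seeds for recovery rates. The
paper-scale 2000 Hz rate is supported but adds nothing at desk scale. Two
study configurations are used: the *localization* condition (focus driving
five neighbours, ictal coupling 0.9) and the *stage-dynamics* condition
(focus driving all 21 others at AS 0.1 / SS 0.4 / IS 0.8, i.e. global
hypersynchrony rising into seizure — with only five driven channels the
mean-degree ordering between SS and IS is nearly degenerate because the
five-channel clique saturates).

**What passing these tests does and does not show.** The generator omits
volume conduction, muscle/eye artifacts, electrode drift, non-stationary
background, and biophysical neural-mass dynamics. Recovery of the planted
focus demonstrates that the statistical machinery is sound — that the
pipeline finds a channel that genuinely drives its neighbours and deviates
in nonlinear dynamics — not that scalp EEG of a given patient will yield
the clinical focus. On real data the method's weakest links are the ones
the generator idealizes away: reference-electrode choices, artifacts
masquerading as anomalies, and stage annotation quality.

## Degenerate inputs and numerical conventions

Constant sequences: entropy 0, ApEn 0, auto-MI delay and Hurst and PCAI
are errors (no structure to estimate). Zero pooled variance in the
T statistic: 0 for equal means, signed infinity otherwise. Edgeless
networks yield an empty, flagged core set; window-level estimation
failures propagate as missing values; all thresholds use strict
inequality; all tie-breaks are lexicographic. Population (not sample) SD
is used where a spread is reported as a descriptive statistic (stage CV,
PCAI).

## Known limitations

* Binned MI is biased upward at small samples (≈ $(N-1)^2/(2n\ln 10)$
  hartley); stage *comparisons* are unaffected since the bias is common,
  but absolute MI values should not be compared across different window
  lengths or bin counts.
* The T-index treats per-window feature values as independent samples;
  overlapping windows violate this mildly. The statistic is used as a
  synchronization *index*, not as a calibrated significance test.
* Localization presumes the montage covers the focus; a deep or midline
  source appears only through its propagation targets.
* With fewer than ~6 windows per stage the T-index matrices are too noisy
  to rank channels stably.
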