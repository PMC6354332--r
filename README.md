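# focimap

Mapping the synchronization of dynamic brain networks from multichannel
scalp EEG, and localizing candidate epileptic foci as the networks' core
nodes.

## What it does, and for whom

For researchers analyzing long-term scalp EEG of focal epilepsy, `focimap`
quantifies between-channel synchronization on two time scales and turns it
into a localization readout:

* **Short-term**: binned mutual information per channel pair per sliding
  window, in decimal-log units:
  `H_xy = -Σ p_ij lg p_ij`, `I_xy = H_x + H_y - H_xy`.
* **Long-term**: per-channel, per-window nonlinear features — correlation
  dimension (CD), approximate entropy (ApEn, m = 2, r = 0.25 SD), Hurst
  exponent (rescaled-range), and a PCA eigenvalue-spread index (PCAI) —
  compared between channels by the pooled-variance T statistic
  `T = (X̄₁ - X̄₂) / sqrt(S_C² (1/n₁ + 1/n₂))` within each vigilance stage
  (awake / sleep / ictal).

Synchronization matrices are thresholded into undirected **brain
networks**; the maximum-degree **core node** per window traces the main
propagation path of epileptiform activity, and a consensus over the four
nonlinear-feature networks of the ictal stage nominates the focus
channels. A seeded synthetic-EEG generator with a planted focus provides
ground truth for every stage of the pipeline.

## Worked example

```r
library(focimap)

demo <- demo_dataset(seed = 7)     # 22 channels, AS/SS/IS x 60 s, focus "T3"
report <- run_pipeline(demo$config)
report
```

```
<localization_report>
  MI AS: mean 0.0249, CV 11.0% (9 windows)
  MI SS: mean 0.0257, CV 19.3% (10 windows)
  MI IS: mean 0.0394, CV 135.3% (10 windows)
  mean degree by stage: AS=0.71 IS=2.90 SS=1.75
  main path: (C3\P3\T5)-(C3\F7\m1\P3\T3\T5)-(C3\P3)-(C3\F7\m1\P3\T3\T5)
  ictal MI core node(s): C3, F7, m1, P3, T3, T5
  consensus foci: P3, T3
```

Reading the output: mean off-diagonal MI rises from awake (0.0249)
through sleep to seizure (0.0394), and so does the network's mean degree
under the recording-wide threshold (AS 0.71 < SS 1.75 < IS 2.90) — the
brain network is densest during the seizure. The ictal MI network's core
nodes are exactly the planted focus `T3` and the five channels it drives
(`T5, F7, C3, P3, m1`); the main path stays on that set throughout the
seizure; and the consensus over the four nonlinear-feature networks
places the true focus `T3` in its top two channels.

The same analysis runs from the shell on an EDF or CSV recording:

```sh
Rscript inst/cli/epinet.R demo --seed 7 --out epinet_out
Rscript inst/cli/epinet.R run --input patient.edf --stages stages.csv --out out/
```

Main function groups (see `?focimap`): `read_recording()` /
`bandpass_filter()` / `segment_windows()`; `mi_matrix()` /
`mi_stage_stats()`; `feature_profiles()` / `t_index_matrix()`;
`threshold_network()` / `core_nodes()` / `main_path()` /
`consensus_foci()`; `generate_recording()` / `generate_fgn()`.

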