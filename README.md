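# meaburst

Spike detection and synchronized-burst analysis for in vitro
multielectrode array (MEA) recordings, with a ground-truth-preserving
simulator for validation.

## The problem

Neuronal cultures grown on MEA plates (here: 16 extracellular electrodes
in a 4×4 grid per well, sampled at 12.5 kHz per channel) reveal their
connectivity through *synchronized bursts* (SBs) — transient surges of
firing across many electrodes at once. Two wells can have similar overall
spike counts yet completely different network organization: a healthy
excitatory network shows a regular SB pattern, while a hyperexcitable,
poorly connected one fires more but without synchrony. `meaburst`
implements the standard analysis chain for such experiments, for
electrophysiologists who want a scriptable, testable alternative to
vendor GUIs:

1. **Filter** — Butterworth band-pass, 200–3000 Hz, applied
   forward-backward (zero phase).
2. **Detect** — per-electrode adaptive threshold at −5.5 σ, where
   σ = median(|x|)/0.6745 is the spike-robust MAD noise estimate;
   1 ms dead time; trough-aligned timestamps.
3. **Bin** — array-wide spike detection rate (ASDR): spikes summed over
   electrodes in 200 ms bins.
4. **Burst-detect** — envelope algorithm on the ASDR: candidate bins
   exceed mean + 1.25 SD, edges extend to return-to-mean, bursts < 200 ms
   apart merge, and ≥ 35% of active electrodes must participate (fire at
   ≥ 2× their own average rate inside the window).
5. **Summarize** — per-well metrics: mean firing rate, SB frequency /
   interval / duration, spikes per SB, max ASDR; percent-of-control
   normalization.
6. **Compare** — per group and metric: ROUT outlier removal (robust
   location/scale + FDR flagging at Q = 10%), one-way ANOVA with
   mean ± SEM; plus 2^−ΔΔCt qPCR fold changes.

A statistical simulator (`simulate_spike_trains()`,
`synthesize_voltage()`, `make_fixture()`) generates recordings with
Poisson background firing, renewal-process network bursts with partial
electrode participation, biphasic 1.5 ms waveforms and Gaussian noise —
retaining every true spike time and burst window, so each stage is
validated by parameter recovery. See the vignette
(`vignettes/mea-network-analysis.Rmd`) for the methods account.

## Worked example

```r
library(meaburst)

fx <- make_fixture("synchronous_network")   # 60 s, fixed seed
fx$recording
#> <voltage_recording> 16 electrodes x 750000 samples (60 s at 12.5 kHz)
#>   amplitude range: [-212.4, 77.4] uV

det <- detect_all(fx$recording)             # filter + sigma + threshold
det
#> <spike_train_set> 16 electrodes, 4115 spikes over 60 s
#>   spikes/electrode: min 202, median 260.5, max 309

well_metrics(det)
#> <well_metrics>
#>   mean firing rate:    4.286 Hz
#>   active electrodes:   16
#>   SB frequency:        10 /min  (10 bursts)
#>   mean SB duration:    0.66 s
#>   mean SB interval:    5.2 s
#>   mean spikes per SB:  285.3
#>   max ASDR:            133 spikes/bin
```

The simulator planted 10 burst windows in this fixture; the pipeline
recovers all 10 (SB frequency 10/min over 60 s), and the detected 4115
spikes sit within 3% of the 4211 ground-truth spikes. Contrast with the
asynchronous phenotype:

```r
hy <- make_fixture("hyperexcitable_asynchronous")
res <- run_pipeline(list(synchronous = list(fx$recording),
                         hyperexcitable = list(hy$recording)))
res$metrics[, c("condition", "n_spikes", "mean_firing_rate",
                "sb_frequency", "max_asdr")]
#>        condition n_spikes mean_firing_rate sb_frequency max_asdr
#> 1    synchronous     4115             4.29           10      133
#> 2 hyperexcitable     7702             8.02            0       43
```

The hyperexcitable well fires almost twice as much (8.0 vs 4.3 Hz) yet
shows zero synchronized bursts and a three-fold lower peak ASDR — more
activity, less network: the dissociation these metrics exist to expose.

A thin CLI over the same functions is installed at
`inst/scripts/mea` (verbs `simulate`, `detect`, `netburst`, `compare`,
`ddct`, `run`; all accept `--config <yaml>` and write a manifest).

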