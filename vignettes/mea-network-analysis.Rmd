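---
title: "From raw MEA voltage to synchronized-burst statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw MEA voltage to synchronized-burst statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

# The problem

Cultured neuronal networks on multielectrode arrays (MEAs) — here a 4×4
electrode grid per well sampled at 12.5 kHz per channel — express their
maturation and connectivity through two observables: the overall level of
spontaneous spiking, and the degree to which that spiking is organized
into *synchronized bursts* (SBs), transient array-wide surges of firing
separated by quiescent intervals. A well-connected excitatory network
shows a regular SB pattern; a hyperexcitable but poorly connected one
fires more overall yet shows no clear SB pattern. `meaburst` implements
the full chain from raw extracellular voltage to well-level SB
statistics and group comparisons, together with a ground-truth-preserving
simulator so that every stage can be validated by parameter recovery
rather than by eye.

# The analysis chain

## Band-pass filtering

Raw traces are filtered with a Butterworth band-pass, high-pass cutoff
200 Hz and low-pass cutoff 3000 Hz — the spike band; slower local-field
components and high-frequency noise are removed. The filter order is
configurable and defaults to 2, applied forward and backward
(`zero_phase = TRUE`), which cancels phase shift (so spike timestamps are
not biased by group delay) and doubles the effective order to 4. Edge
transients are controlled by odd-reflection padding of
`3 * sampling_rate / high_pass` samples (three times the impulse-response
scale of the slowest cutoff) before filtering; the padding is discarded
afterwards.

## Noise estimation

The detection threshold adapts to each electrode's noise level. The
noise SD is estimated from the filtered trace as

$$\hat\sigma = \mathrm{median}(|x|)\, /\, 0.6745,$$

the median-absolute-deviation estimator (for a zero-centred signal the
median of $|x|$ *is* the MAD about zero). For Gaussian noise this is a
consistent estimator of the SD, and because spikes occupy well under 1%
of samples at physiological firing rates, it is essentially unaffected by
them — unlike the raw SD, which spikes inflate and which would therefore
raise the threshold exactly where activity is highest. Sigma is computed
once per electrode over the whole recording; a sliding-window variant
would adapt to slow noise drift but makes the detector's behaviour
time-dependent, and recordings at this scale (minutes) rarely drift
enough to matter.

## Spike detection

A spike is recorded where the filtered signal first crosses below
$-5.5\,\hat\sigma$ (negative-going only: the dominant extracellular spike
polarity). Subsequent crossings within a dead time (default 1 ms, a
standard multi-unit refractory guard) are suppressed, and the timestamp
is the local minimum of the trace within the dead-time window after the
crossing — aligning to the waveform trough is stable against noise,
whereas the first-crossing sample moves with the noise realization. At
5.5 sigma the false-crossing probability per sample for Gaussian noise is
about $2\times10^{-8}$, giving well under 0.1 false spikes per electrode
per minute; sensitivity then depends on the spike-amplitude-to-noise
ratio (at SNR 10 recovery is essentially complete; see the test suite).

The detector is deliberately simple enough to be specified exactly, and
the test suite holds it equal to an exhaustive sample-by-sample scan on
random traces. One subtlety: "raising the threshold never increases the
spike count" is not a theorem for crossing detectors with dead time — a
single long sub-threshold excursion can split into two distinct crossings
at a higher threshold — but for noise-like traces the required geometry
(12+ samples below one threshold and back above another) essentially
never occurs, and the property is tested on random traces.

## ASDR and the envelope burst detector

Network activity is summarized by the array-wide spike detection rate
(ASDR): spikes summed over all electrodes in 200 ms bins, with a partial
trailing bin dropped. Synchronized bursts are then detected from the
ASDR histogram by an envelope method:

1. candidate bins exceed `mean + 1.25 * SD` of the bin counts;
2. each maximal run of candidate bins is extended outward while counts
   stay above the mean (the envelope edges);
3. bursts whose gap is below 200 ms are merged;
4. a burst is retained only if at least 35% of the well's *active*
   electrodes participate in it.

Two readings of the published parameters were genuinely open and were
resolved as follows.

*"Above or below the mean".* Taken literally, a two-sided threshold
would classify deep pauses as bursts. We threshold upward for burst
onset and use the return to the mean as the envelope edge — the
downward criterion defines the burst's extent, not a separate event
class.

*What "35% of electrodes included" means.* The participation denominator
is the set of **active** electrodes (firing at ≥ 5 spikes/min over the
recording, a common vendor default) rather than all 16, so that dead
electrodes cannot veto genuine network events; both the cutoff and the
behaviour are configurable. The participation *numerator* requires more
than the presence of a spike: an electrode participates when it fires at
least one spike inside the window **and** its within-window rate is at
least twice its own recording-average rate
(`participation_min_rate_factor = 2`). The elevated-rate requirement is
what makes the detector specific. A mean + 1.25 SD threshold is a
z-score criterion, and any stationary process — including fully
asynchronous Poisson firing — spends roughly 10% of bins above it; at
moderate firing rates every electrode also trivially has ≥ 1 spike in
any 200 ms window, so a "one spike counts" rule would report dozens of
spurious bursts per minute in a well with no network structure at all.
Requiring at-least-doubled firing identifies electrodes that are
*bursting*, not merely firing: in a genuine SB, recruited electrodes jump
an order of magnitude above baseline and pass easily, while in a chance
fluctuation each electrode fires at about its usual rate and fails. With
this rule the asynchronous benchmark scenario yields zero or near-zero
SBs, as it should.

## Well metrics

Per well we report: mean firing rate (mean of per-electrode rates over
active electrodes — undefined, reported as `NA` with a warning, when no
electrode is active), SB frequency (per minute), mean SB duration, mean
SB interval, mean spikes per SB, and the maximum ASDR bin count of the
recording. The SB interval is the *gap* from one burst's end to the
next one's start (matching how duration and interval are annotated on
raster plots); onset-to-onset is available via `interval_mode = "onset"`.
Max ASDR is the per-recording maximum, not an average of per-burst
peaks. Metrics that are undefined for the observed burst count (all
shape metrics with zero bursts; the interval with fewer than two) are
`NA`, never 0 — a well with no bursts has *no* burst duration, not a
zero one. Normalization to a control condition is
`100 × value / control`, with non-positive or missing control values
flagged as non-normalizable rather than propagated.

# The statistics layer

Group comparisons across wells use, per metric and per group, robust
outlier removal followed by one-way ANOVA with mean ± SEM reporting.

*ROUT.* The robust outlier procedure is applied in its one-sample
reduction: location = median; scale = the 68.27th percentile of the
absolute residuals inflated by $n/(n-1)$ for the one fitted parameter
(the robust SD of the residuals, RSDR); each point's two-sided p-value
from $t = |r|/\mathrm{RSDR}$ on $n-1$ df; and outliers flagged by a
Benjamini–Hochberg step-up at the maximum desired FDR $Q$ (default 10%).
Whether the original analyses pooled groups or treated them separately
is not recoverable; we apply it per group and per metric, which is the
conservative choice (group differences can never be mistaken for
outliers). On clean Gaussian data at $n = 10$ the procedure removes
about 1% of points at $Q = 10\%$ — the FDR is a ceiling on the
expected false-removal fraction among flagged points, not a target
removal rate, so far fewer than $Q$ of clean points are touched.

*ANOVA.* The omnibus F test is delegated to `stats::lm()`/`anova()` and
is held, in the tests, to a hand-computed textbook oracle at $10^{-10}$.
Degeneracy (every group with exactly zero within-group variance) is
signalled, not silently returned as an infinite F. Post-hoc tests are
deliberately not provided beyond exploratory unadjusted contrasts: which
multiple-comparison correction to use is a study-level decision.

*qPCR.* Relative expression uses $2^{-\Delta\Delta C_T}$ with technical
triplicates averaged on the Ct scale (cycles are the log domain;
averaging linearized quantities first would bias the estimate).

# The simulator

The generator (`simulate_spike_trains()`, `synthesize_voltage()`,
`make_fixture()`) is statistical, not biophysical: it emulates the
*observables* of a culture on an MEA, not membranes or synapses.

- Background firing: homogeneous Poisson per electrode.
- Network bursts: a renewal process at `burst_rate` per minute whose
  onset intervals are `burst_duration + 0.4 s + Exp(slack)`, the hard
  0.4 s floor (twice the burst-merge distance) guaranteeing ground-truth
  windows are unambiguously separable; within each window every
  electrode is recruited independently with `participation_prob` and
  fires Poisson at `burst_within_rate`. Infeasible settings (expected
  bursts tiling the recording) are rejected up front.
- Waveforms: a biphasic template, 1.5 ms total, negative lobe first with
  a positive lobe at 30% of the negative amplitude — the typical
  extracellular shape; the template is normalized so a spike's rendered
  peak is exactly `-spike_amplitude`. Coincident spikes on one electrode
  are deduplicated at one-sample resolution (they are physically one
  event at the electrode); near-coincident waveforms sum linearly.
- Noise: additive white Gaussian, SD `noise_sigma`, in physical µV
  (amplifier gain treated as already removed).
- Reproducibility: one generator seeded from the required `rng_seed`;
  identical parameters give bit-identical ground truth.

The benchmark fixtures pin the two phenotypes of interest at SNR 10
(100 µV spikes over 10 µV noise — a deliberate choice; the source
recordings' amplitude statistics are not published):
`synchronous_network` (background 1.5 Hz, 10 bursts/min × 0.5 s at
40 Hz within-burst, 90% participation, 60 s) and
`hyperexcitable_asynchronous` (background 8 Hz, no bursts, 60 s), plus
`silent` (10 s) and `single_electrode_tonic` (30 s) for degenerate-case
handling. The asynchronous scenario's 8 Hz background makes its mean
firing rate strictly exceed the synchronous well's ≈4.5 Hz
(1.5 Hz background + ≈3 Hz contributed by bursts) while carrying no
network structure — the qualitative contrast of interest.

What the simulator does **not** reproduce — and hence what passing its
recovery tests does not establish about real data: correlated or
non-stationary noise, electrode-to-electrode amplitude variation and
drift, bursty single-channel (non-network) firing, refractory structure
beyond the dead time, waveform diversity and overlap sorting, and any
pharmacology. Recovery results here certify the *algorithms*, not any
particular biological recording.

# Numerical choices and degenerate inputs

- Filter cutoffs must satisfy `0 < high < low < Nyquist`; violations are
  errors, not warnings.
- `sigma = 0` with a nonzero trace is a degenerate threshold and is
  signalled; a flat zero trace simply has no spikes.
- A flat ASDR (SD = 0) has no bursts by construction.
- Binning uses half-open intervals `[kw, (k+1)w)`; the trailing partial
  bin is dropped from the series and from `max_asdr`.
- Spike trains are validated as strictly increasing within electrode;
  unsorted external CSVs are sorted on load with a warning, negative
  times are rejected.
- All times are seconds, amplitudes µV, electrode ids 0-based row-major
  over the grid.

# Problem sizes used in the tests

The validation suite was sized to run comfortably on a laptop: noise
calibration on 10 s of 12.5 kHz noise; detector-oracle equivalence on
100 random 1 s traces; spike recovery on one 60 s 16-electrode
recording; rate recovery on 20 seeded 300 s spike-train simulations;
burst recovery on a 300 s simulation with ≈60 true bursts; ROUT
calibration on 1000 replicates of n = 10. These sizes give binomial /
Poisson standard errors comfortably below the margins being asserted.

# Known limitations

- The envelope burst detector's exact boundaries are bin-quantized
  (≤ one 200 ms bin of slack per edge) and will not byte-match any
  proprietary implementation; validation is against simulator ground
  truth.
- Per-electrode (single-channel) burst detection, spike sorting, and
  connectivity inference are out of scope.
- The voltage container is a plain-text interchange format for
  reproducibility and portability, not a high-performance store; for
  hour-long recordings, detect once and work with spike CSVs.
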