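---
title: "Phenotyping neuronal networks on multiwell MEAs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping neuronal networks on multiwell MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaphenotype)
```

## The measurement problem

Cultured human neuronal networks (for example hiPSC-derived excitatory
neurons maturing on astrocyte feeder layers) develop spontaneous activity
that a multiwell micro-electrode array (MEA) samples non-invasively: each
well of a 24-well plate carries 12 extracellular electrodes, and each
electrode reports multi-unit spike times.  Mature networks produce three
distinguishable kinds of events:

* **random spikes** — isolated, asynchronous action potentials;
* **single-channel bursts** — high-frequency spike runs on one electrode;
* **network bursts** — rhythmic, near-synchronous events recruiting a
  large fraction of the well's electrodes.

A well is summarised by 17 parameters covering general activity (MFR,
PRS), channel bursting (BR, BD, BSR, IBI), network bursting (NBR, NBD,
NIBI, CV~NIBI~, rise time RT, decay time DT, and a shape summary —
the full width at half maximum of the averaged network-burst profile),
and functional connectivity (C~0~, C~peak~, link weight, number of
connections).  Cohort analyses then compare these parameters across lines,
batches and disease groups.  `meaphenotype` implements the whole chain —
spike detection, event detection, parameter extraction, quality control,
pooling and cohort statistics — together with a ground-truth simulator that
makes every stage testable.

## Spike detection (optional front end)

When raw 10 kHz traces are available, they are band-passed with a
second-order high-pass Butterworth at 100 Hz and a fourth-order low-pass at
3500 Hz, and spikes are detected at ±4.5 noise standard deviations.  Three
choices here are assumptions rather than published facts and are therefore
explicit arguments:

* the noise SD is estimated robustly as `median(|x|)/0.6745`, because the
  plain SD is biased upward by the spikes themselves;
* filtering is zero-phase (forward–backward with odd-reflection padding of
  about three high-pass time constants), so detected spike times are not
  shifted by filter latency; the acquisition system's causal filter is not
  reproduced sample-exactly;
* both polarities are detected, the event time is the absolute extremum of
  each supra-threshold excursion, and a configurable 2 ms dead time merges
  double crossings.

## Event detection

**Single-channel bursts** use the classical max-interval ("string")
criterion: a maximal run of at least `min_spikes` spikes (default 5) with
every inter-spike interval at most `max_isi` (default 100 ms, boundary
inclusive).  The published record does not print the original settings, so
both are configurable and are serialised next to every result.

**Network bursts** are found on the well-wide spike count binned at 25 ms.
Contiguous bins at or above a threshold form candidates; candidates are
snapped to their first/last spike, merged when separated by less than
100 ms, and kept when at least 25% of the 12 electrodes participate (the
"channels in network burst > 25%" recommendation, interpreted per event
and summarised per well as the mean participation across events) and when
they contain at least `min_nb_spikes` spikes well-wide (default 30; this
rejects spurious coincidences of two or three single-channel bursts, which
otherwise masquerade as tiny network events and corrupt the regularity
measure CV~NIBI~).  The threshold defaults to
`max(1.5, 0.05 * peak bin count)` — the baseline dominates in practice, and
a low threshold is deliberate: detection that misses network bursts
inflates NIBI and CV~NIBI~, which is exactly the suboptimal-settings
failure mode the quality recommendations warn about.  A fixed
`rate_threshold` overrides the adaptive rule for per-recording tuning or
settings sweeps, and for developmental series the settings determined at
the latest day in vitro should be applied backwards to earlier time points.

NIBI is measured end-to-next-start (a gap, not an onset interval), and
CV~NIBI~ uses the sample SD; both need at least two (respectively three)
events, otherwise they are flagged undefined rather than silently zero.

**Shapes.**  The average network-burst shape bins the well-summed rate from
each event onset over a 3 s window at 5 ms resolution (events whose window
would cross the end of the recording are omitted).  RT and DT are measured
between the 10%-of-peak crossings and the peak, with linear interpolation
between bins; a profile already above threshold at onset (a boxcar) is
flagged degenerate, and a peak at the window edge leaves them undefined.

## Connectivity

The cross-correlogram counts spike-pair lag differences in 10 ms bins over
±0.5 s, normalised by `sqrt(N_a * N_b)` so an identical sparse pair scores
1 at zero lag.  C~0~ is the zero-lag value ("synchronization"), C~peak~
the maximum over lags ("correlation"); both are computed for all 66
electrode pairs, silent electrodes contributing zeros (the all-electrode
rule).  Functional links are pairs whose C~peak~ exceeds the 95th
percentile of the surrogate ensemble built by dithering every spike
uniformly by ±0.5 s — a null that preserves rates while destroying
fine-timescale correlation.  The surrogate seed is mandatory, making the
link set bit-reproducible.  These definitions are stated contracts of this
package: the original analysis software did not publish its exact
normalisation or thresholding rules.

## Quality control and pooling

A well is included when MFR > 0.1 spikes/s, BR > 0.4 bursts/min, NBR > 1
per minute, spikes occur on more than 80% of electrodes, and mean
network-burst participation exceeds 25%; wells without network bursts at
DIV 27 are excluded, and a metadata flag honours operator judgement about
cell density or clumping, which cannot be computed from spike data.  The
"active electrode" rate threshold (1 spike/min) is an assumption and is
reported with every QC report.  Every exclusion carries machine-readable
reason codes and is logged exactly once.  Cohort tables are pooled in the
stable window DIV 27–35; earlier recordings are discarded with a warning,
and mixed coating substrates are retained but flagged.  Each line should
contribute at least 12 wells over at least two MEA batches; the batch
sufficiency check warns otherwise.

## Cohort statistics

* **Stability**: per-parameter CV% within line, summarised across lines,
  with 50% as the stability cutoff.
* **PCA** on Z-scored parameters, with a fixed sign convention (largest
  loading positive) for reproducible embeddings.
* **Batch variance**: separate one-way linear models per parameter
  (R² = SS between / SS total, Benjamini–Hochberg across parameters); the
  "combined" share stacks Z-scored values of the chosen parameters and fits
  the same factor.  The combining rule is this package's interpretation:
  stacking assumes the batch shifts the standardised parameters in a
  consistent direction, which holds for the rate-linked parameters the
  simulator's multiplicative batch effects drive.  When validating recovery,
  the generative reference is the batch-factor R² of the multipliers the
  simulator actually applied (raw scale, since parameters scale with the
  raw multiplier) — with a handful of batch draws the realised share can sit
  far from its design value, and recovery is judged against what was
  realised.
* **Group comparisons**: two-group designs use Mann–Whitney with
  Bonferroni correction across parameters; multi-group designs gate on a
  Kolmogorov–Smirnov-type normality test (Lilliefors) and use one-way
  ANOVA with Tukey post hoc or Kruskal–Wallis with a hand-implemented
  Dunn post hoc.  Shape profiles are compared bin-wise with two-sample
  t tests under Holm–Šidák step-down correction.
* **Power**: two-sample noncentral-t power, also where groups were compared
  non-parametrically (the standard asymptotic-relative-efficiency
  shortcut); `wells_required()` returns the smallest group size reaching
  the target power (floor n = 2), and 0.8 is the default target.

## The simulator

`simulate_well()` draws network-burst onsets from a gamma-renewal process
(mean interval `60/nb_rate`, interval CV `nb_cv`; `nb_cv = 0` degenerates
to a clock).  Each event recruits each channel with probability
`participation`; recruited channels emit Poisson spike counts
(`intra_nb_rate × nb_duration`) with times drawn from a gamma-density
envelope of shape `1 + rise_tau/decay_tau` and scale `decay_tau`,
truncated at `nb_duration` — right-skewed like recorded network bursts and
analytically tractable for rise/decay oracles.  Independent single-channel
bursts (six spikes at ~60 Hz) and Poisson background spikes are added,
spike times are quantised to the 10 kHz grid, and amplitudes follow a
log-normal (median 30 µV).  Ground truth records every generative value,
the realised event times, and per-component spike counts, so attribution
is conserved and recovery is checkable well by well.

The control preset (`nb_rate` 3.2/min, `nb_cv` 0.3, `nb_duration` 1.28 s,
participation 0.9, `intra_nb_rate` 50 spikes/s, channel bursts 1.3/min,
background 0.2 spikes/s) is calibrated so the *pipeline's* estimates land
near the pooled values reported for mature control networks (≈3.5
spikes/s, ≈4.8 bursts/min, ≈3.2 network bursts/min, ≈1.28 s duration).
Disease presets shift only the published directions: the MELAS-like preset
lowers firing, network bursting and participation while raising background
(more random spikes, shorter channel bursts, weaker correlation); the
KS-like preset lowers event frequency while lengthening `nb_duration` and
`decay_tau` (longer, slower-decaying network bursts).  Batch effects are
multiplicative log-normal multipliers on `nb_rate`, `intra_nb_rate` and
`background_rate` only — matching which parameters real batches were found
to perturb — with one multiplier per MEA batch, per astrocyte batch and
per well.

What the simulator does **not** emulate: electrode-distance structure (the
300 µm geometry), burst propagation and latency maps, development across
days in vitro, super-burst substructure, and non-stationarities such as
drift within a session.  Passing recovery tests therefore demonstrates the
correctness of the analysis chain on data with the assumed statistical
structure, not robustness to every pathology of real recordings.

## Numerical choices and degenerate inputs

Timestamps are float64 seconds, zero-based, strictly increasing; intervals
are half-open `[start, end)` except that a spike exactly at a burst edge
counts inside (closed comparison on detected event edges).  Burst and
network-burst detection are deterministic; connectivity surrogates and the
simulator consume explicit seeds and restore the RNG state afterwards.
Undefined statistics (IBI with one burst, CV~NIBI~ with two events or
fewer, RT/DT on edge-peaked profiles, link weight with no links, SEM with
one well) are `NA` with explicit flags, never silent zeros.  Empty trains,
empty wells and all-excluded cohorts are legal inputs that produce empty,
flagged outputs.

Problem sizes used in the package's own validation were chosen for
desk-scale verification: 10-minute wells, cohorts of 12–32 wells, 1000
random trains against the burst oracle, 100 random pairs against the
correlogram oracle, and 20-well recovery runs; all reported checks
reproduce from fixed seeds.

## File formats

Peak trains travel as plain text in two dialects behind one reader:
`portable_csv` (commented metadata header plus `electrode,time_s,
amplitude_uV` rows) and `mcs_csv` (acquisition-style `ptrain_<k>` channel
sections with integer sample indices at 10 kHz).  Both list all 12
electrode slots explicitly so a silent electrode is distinguishable from a
missing one; converting deposited binary exports to either dialect is a
one-off step outside this package.  Metadata tables, parameter tables, QC
reports and configurations are CSV/YAML; run logs are JSON lines.

## Known limitations

Adaptive ISI-histogram burst detectors (logISI methods) are not
implemented; directed connectivity (transfer entropy, Granger) and
distance-dependent analyses are out of scope; the exact membership of the
original 17-parameter set is not printed in the source material, so this
package's enumeration (16 unambiguous parameters plus the shape FWHM) is
one defensible choice, and the parameter list is configurable throughout
the statistics layer.
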