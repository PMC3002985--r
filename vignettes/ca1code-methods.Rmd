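---
title: "A reduced CA1 surrogate for delay- and arrangement-coded burst analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced CA1 surrogate for delay- and arrangement-coded burst analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

A CA1 pyramidal neuron integrates Schaffer-collateral input on its
proximal apical dendrites (stratum radiatum, SR) with entorhinal input on
its distal tuft (stratum lacunosum-moleculare, SLM). Under a protocol in
which every SLM high-frequency subthreshold burst (10 pulses at 100 Hz,
once per second for 10 s) precedes the paired suprathreshold SR pulse by
a delay Δ, the neuron's output switches between two regimes: somatic
bursting at short Δ and GABA_B-mediated spike blocking at long Δ. Four
spatial arrangements of the fixed synaptic contacts (fully diffused,
fully clustered, SR clustered, SLM clustered) modulate both regimes.

`ca1code` replaces the full multicompartment reconstruction of this cell
with a reduced surrogate that preserves the phenomena the analysis
consumes, and implements the decoding statistics that read the input's
temporal (Δ) and spatial (clustered vs diffused) features back from the
output spike pattern.

## The surrogate

The surrogate is feedforward up to the soma, which makes it fast and
fully deterministic given a seed.

**Dendritic subunits.** Each layer is a pool of sigmoidal subunits
(20 SR branches, 10 SLM branches by default). A branch holding `k` of
the layer's contacts receives local drive `k / k_nominal`, mixed with
the layer mean through an electrotonic coupling term
(`dend_coupling = 0.35`) that represents charge sharing between sister
branches and damps the granularity of random diffuse placement. The
subunit nonlinearity is a logistic anchored at zero
(half-activation 1.4 nominal-drive units, slope 0.4), so concentrating
the fixed contact complement on 8 branches (clustering) yields a larger
summed output than scattering it — the two-layer-network view of
dendritic integration. Branch gains are log-normal
(`branch_sd = 0.25`): clustered layouts sample few branches, making
their responses more variable from trial to trial.

**Soma.** A leaky integrate-and-fire unit (rest −70 mV, threshold
−54 mV, reset −65 mV, τ_m = 20 ms, absolute refractory 5 ms, dt =
0.1 ms, explicit fixed-step update in compiled code). Excitatory drive
enters in mV units; inhibition as a conductance pulling toward −90 mV.

**SR events.** Each SR pulse evokes a somatic EPSP (difference of
exponentials, 1.5/5 ms) whose amplitude is the shunted subunit sum;
`g_ampa_sr = 70` is calibrated so SR input alone fires a single action
potential per event under a nominal diffused layout (1 Hz baseline,
occasionally 2 per event through layout variation — the basis of the
1–3 Hz acceptance filter).

**SLM events.** Each SLM pulse adds a small, strongly attenuated somatic
depolarization (`g_ampa_slm = 0.8`, calibrated so a full 10-pulse burst
depolarizes the soma by ≈2 mV), a slow NMDA "priming" trace
(τ = 90 ms) and a fast AMPA gating trace (τ = 30 ms). The SLM NMDA/AMPA
weight is twice the SR value, implementing the reported distance
dependence of the NMDA/AMPA ratio as a layer-level scalar (the original
distance-resolved formulas are not legible in the source material, so
layer scalars reproducing the described behaviour are used instead).

**Plateau and bursting.** At each SR event a plateau trigger is
evaluated from three pathways: NMDA (priming-gated), an R-type calcium
component gated by the fast SLM depolarization (this pathway survives
NMDA blockade and is why blockade leaves spike doublets), and an
h-current rebound proportional to the instantaneous GABA_B conductance
(which sustains occasional doublets at long delays while inhibition is
intact). If the trigger exceeds `plateau_threshold = 0.73`, a
depolarizing plateau current is injected: saturating amplitude
(gain 76 mV, half-saturation 1), exponential adaptation (τ = 60 ms),
duration 140 ms. Burst size (2–6 spikes) and the within-burst ISI
growth emerge from the integrate-and-fire dynamics under this decaying
current. The amplitude also carries the drive-weighted mean branch gain,
so clustered trials inherit single-branch heterogeneity. Mechanism
weights (`amp_w_*`) let 90% blockade of the calcium/h surrogates
reproduce the reported ordering of duty-cycle effects qualitatively
(NMDA ≫ R-type/h ≫ L/N/T ≈ 0).

**GABA_B and spike blocking.** Each SLM burst recruits a slow GABA_B
conductance (onset latency 50 ms, rise 100 ms, decay 250 ms) whose
single-burst course peaks ≈200 ms after burst onset, so SR events
delayed by 190–350 ms arrive at its maximum. The conductance divisively
shunts the SR subunit drive and adds a somatic potassium-like term.
Successive bursts desensitize by 22% each, so late events in a trial
partially escape blockade — the source of the doublets seen at long
delays. Clustering sensitivity enters through an interneuron-recruitment
sigmoid: clustered SLM layouts recruit more GABA_B (deeper blocking),
while clustered SR layouts saturate their subunits and push current
through the shunt (the rescue from blocking).

**Stochasticity.** Only two sources, as a design rule: per-trial layout
resampling (branch assignment and gains) and optional Gaussian somatic
voltage noise (stationary SD 0.15 mV). A seed is mandatory everywhere;
identical `(protocol, layout, params, seed)` give identical spikes.

## Calibration

The free parameters above were calibrated once, jointly, against the
target regime table — SR-alone 1–3 Hz; SLM-alone ≈2 mV; 4–5 spikes per
burst and ff ≈ 4–5 Hz at Δ ≤ 90 ms; ff below 1 Hz at Δ = 260 ms
(diffused); 90% SLM GABA_B blockade restoring ≈1 Hz; ≥40% duty-cycle
loss under NMDA blockade; <10% change under L/N/T-type blockade;
SR-clustered rescue; 1–2-spike bursts at Δ = 160–240 ms — and then
frozen in `ca1_params()` and `inst/extdata/default-params.yaml`. The
blockade compensation factors (`ampa_comp`, `gabaa_comp`) can be
re-derived with `calibrate_compensation()`, a seeded grid search that
matches single-pathway responses to control within 10%.

## The analysis stack and its conventions

- **Burst segmentation** uses a 50 ms intra-burst ISI criterion
  (configurable). The source experiments never state their criterion;
  50 ms cleanly separates plateau-driven spikes from the 1 Hz baseline.
  Doublets count as bursts.
- **Average firing frequency** is the mean over trials of spike count
  over the 10 s window; **mean burst ISI** averages per-trial mean
  intra-burst ISIs over trials that burst (never zero-filled).
- **Duty cycle** is burst span over onset-to-onset interval, averaged
  over consecutive burst pairs; undefined (flagged `NA`) below two
  bursts.
- **Return maps** embed the per-condition concatenated ISI vector as
  `(ISI_{i−1}, ISI_i, ISI_{i+1})` triplets that never straddle trial
  boundaries. **Normalized entropy** bins the map on a fixed
  10×10×10 grid over its bounding box (bin count configurable and
  reported); degenerate axes collapse to one bin.
- **KS comparisons** use the standard two-sample test on the raw ISI
  samples. The alternative reading — testing the binned density values
  against each other — was rejected because it cannot reproduce the
  basic anchor that fully disjoint samples give D = 1.
- **Nonlinear prediction** is the local-constant predictor in
  delay-embedding space (delay 6, dimension 10, ≥8 neighbours, horizon
  10 — all inputs, not estimated), with temporally adjacent indices
  (|i−j| ≤ delay) excluded from the neighbourhood and the per-step RMS
  error normalized by the series SD so that unpredictable series score
  ≈1. A constant series scores 0 by convention (exact prediction).
- **Sigmoid fits** use Levenberg–Marquardt least squares on
  `base + max/(1 + exp(−(x − xhalf)/rate))`; with this sign convention
  a falling ff curve has negative `max`. Non-convergence falls back to
  a flagged flat fit.
- **Signatures** are position-wise medians of the per-trial intra-burst
  ISI sequences, keeping positions covered by ≥50% of trials. Pairwise
  Spearman distances truncate ragged pairs to their common length
  (the source is silent on both choices). Agglomeration is complete
  linkage; ties resolve to the lowest index. Classification of a new
  pattern assigns the nearest reference row and its short (≤120 ms) or
  long (140–240 ms) sub-cluster; the ttfs decoder inversely
  interpolates the monotone SLM-referenced median latency curve, valid
  for Δ ≤ 100 ms where the latency is linear in Δ.

## Problem sizes

Desk-scale defaults keep everything on one CPU: unit and integration
tests use 8–24 trials per condition; the acceptance script simulates 26
trials per condition and reports statistics over the first 20 accepted.
The full published design (4 arrangements × 34 delays × 100 trials =
13,600 patterns) is enumerated and seeded by `enumerate_grid()` and can
be run with `run_grid()` when time permits; a 2-arrangement × 13-delay ×
62-trial signature grid takes a few minutes.

## What passing tests do and do not show

The generator reproduces the regime structure (facilitation, blocking,
rescue, blockade effects, latency coding, the ttfs identity) but it is a
surrogate, not the cell: its intra-burst ISI pattern is essentially a
one-parameter family indexed by plateau amplitude. Three consequences
are documented rather than hidden:

- **Dendrogram separation.** Median ISI signatures separate clustered
  from diffused conditions for 16–21 of 26 leaves depending on trials
  per condition (21/26 at 62 trials), against ≥24/26 in the reference
  analysis. Conditions whose plateau amplitudes happen to match across
  arrangements produce rank-identical signatures, which Spearman
  distance cannot tell apart; the full model's higher-dimensional burst
  dynamics (and even it misplaced one leaf) are not captured. The
  corresponding acceptance test states the ≥24/26 bound and fails
  honestly.
- **Entropy ordering.** Clustered return maps score higher normalized
  entropy than diffused ones at some but not all matched delays: the
  desensitization-driven within-trial ISI trend inflates diffused map
  occupancy. The entropy statistic itself is exact (anchor cases 0,
  0.5, 1 are tested); only this cross-condition ordering is partial.
- **Prediction-error comparisons across arrangements** are dominated by
  the SD normalization (clustered series are more spread, lowering
  their normalized error), so the package does not claim the
  diffused-more-predictable ordering; the statistic's own anchors
  (0 for deterministic, ≈1 for iid, shuffling never helps) are tested.

Real data differ in further ways the generator does not emulate:
morphological detail, active dendritic conductances beyond the plateau
abstraction, synaptic plasticity, and in-vivo background activity.

## Numerical notes

Fixed-step integration at dt = 0.1 ms (the step must divide the 10 ms
intra-burst pulse spacing; incompatible steps are rejected). Voltage
noise is pre-scaled so its stationary SD is dt-invariant. The subunit
sigmoid is anchored so zero drive gives exactly zero output, which puts
the half-activation point at 0.485 rather than exactly 0.5 of the
maximum — an accepted 3% deviation. Kernel filters are exact discrete
exponentials (recursive filters), with unit-peak normalization.
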