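---
title: "Models and methods behind tatabend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tatabend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatabend)
```

# Scope

`tatabend` analyses single-molecule FRET measurements of promoter DNA
bending by the TATA-binding protein (TBP) and transcription factor B.
Two experimental geometries are covered:

* **Confocal ALEX** (alternating laser excitation) of freely diffusing
  molecules: burst search, background/crosstalk correction, proximity
  ratio `E` and stoichiometry `S`, kernel-density (2CDE) filtering, and
  Gaussian population fitting of `E` histograms.
* **TIRF trajectories** of surface-immobilized molecules: trace
  correction, photobleaching truncation, hidden-Markov idealization of
  the frame-wise `E(t)` signal, Viterbi decoding, dwell-time extraction,
  and downstream kinetics (mono-exponential dwell fits, transition-rate
  derivation, survival-lifetime and binding-isotherm fits).

Because public single-molecule raw data for this system are not
available, the package ships a first-class synthetic-data generator
whose defaults are the measured parameters of the studied systems, so
that every analysis stage can be exercised and validated end to end.

# The conformational model

DNA bending is modelled as a continuous-time Markov chain over `K`
conformational states. Two topologies are supported:

* **two-state** (archaeal TBPs): unbent <-> bent, proximity ratios
  0.25 / 0.49 and mean dwell times 19.2 s / 0.18 s at room temperature
  for the *M. jannaschii* system (the package defaults);
* **linear-three-state** (eukaryotic TBP/TF(II)B): unbent (E = 0.32) <->
  intermediate (0.60) <-> fully bent (0.75), with direct
  unbent <-> fully-bent transitions forbidden by construction.

Dwells in state $i$ are exponential with mean $\tau_i$; the exit rate is
$1/\tau_i$. The middle state of the linear chain branches to its two
neighbours; the branching probability `p_21` (default 0.5) is a free
generator parameter because only the per-state dwell means, not the
branch ratio, are part of the reference state description. The
time-averaged occupancy used to initialize simulations is
$\pi_i \propto \nu_i \tau_i$ with $\nu$ the stationary distribution of
the embedded jump chain.

# Synthetic data

**Camera traces.** A state path is integrated per frame: the emitted
proximity ratio of a frame is the dwell-time-weighted average of the
state values over that frame, which reproduces the averaging artifacts a
real camera produces at transitions (an event shorter than about half a
frame is invisible in principle). Noise can be applied directly in `E`
space (`e_noise_sd`, default 0.07, matching the width of the measured
`E` populations) or per channel (`noise_sd`, additive Gaussian counts).
Donor leakage and direct acceptor excitation add to the acceptor
channel. Photobleaching is a single exponential-time step per
fluorophore, donor and acceptor independent: after an acceptor bleach
the acceptor falls to background and the donor de-quenches; after a
donor bleach both channels fall to background.

**Photon streams.** Background photons are homogeneous Poisson per
detection class. Each molecule transit is a rectangular envelope with
lognormal duration (median 1 ms) and lognormal photon rate (median 50
photons/ms), both configurable — diffusion-burst shape statistics are
not reported quantities in this assay, and everything downstream depends
only on per-burst count ratios, so the envelope is deliberately
phenomenological. Within a burst, a photon's excitation slot follows
from its (integer microsecond) timestamp and the 100 microsecond
alternation period (50/50 duty cycle by default); a dual-labelled
molecule emits the stoichiometry fraction `s_dual` of its photons in
donor-excitation slots, and a donor-excited photon lands in the acceptor
channel with probability $E + l\,(1-E)$ where $l$ is the leakage.
Donor-only and acceptor-only contaminant species are available for
filter validation. Timestamps are made strictly increasing by bumping
clock collisions one microsecond; slots are assigned after clock
quantization so the excitation gates are exact.

**Titrations and survival series.** The bent fraction at protein
concentration $c$ is $\mathrm{Binomial}(n, c/(c+K_d))/n$
(pseudo-first-order: protein in large excess over the 10 pM DNA), and
the surviving complex fraction at time $t$ is
$\mathrm{Binomial}(n, e^{-t/\tau})/n$. `n = Inf` gives the noiseless
curves used as exact fixtures.

All generators take an explicit integer seed, restore the caller's RNG
state, and are bit-reproducible for a fixed seed and configuration.

# ALEX burst analysis

The burst search applies the `T`/`M`/`N` criterion to all photons
pooled: a photon qualifies if at least `M` photons fall within a window
of length `T` around it, and a burst is a maximal run of at least `N`
consecutive qualifying photons (`T` = 500 us, `M` = 30, `N` = 120 for
the Cy3b/ATTO647n dye pair; `M` = 10, `N` = 50 for ATTO532/ATTO647n).
The window is centered on each photon; the burst-search literature is
ambiguous on anchoring, the centered form is symmetric, and a
start-anchored mode is available behind a flag. The implementation is
verified against a brute-force $O(n^2)$ oracle on 1000 random streams.

After class-wise background subtraction (rate times burst duration,
floored at zero; the default estimator is the class-wise stream rate
with burst regions excised, iterated once) the two reported quantities
are

$$E = \frac{F_A^D}{F_A^D + F_D^D}, \qquad
  S = \frac{F_A^D + F_D^D}{F_A^D + F_D^D + F_A^A},$$

computed from summed burst counts, not per-photon averages. These are
uncorrected proximity ratios; gamma-factor or distance calibration is
out of scope. Optional leakage/direct-excitation correction of
$F_A^D$ is off by default for confocal bursts (it is routinely applied
to the TIRF traces instead, where the crosstalk of the widefield
detection path matters).

The 2CDE filters score within-burst brightness fluctuation with an
exponential kernel of time constant 100 us:
`ALEX-2CDE = 100 - 50 (BR_DA + BR_AD)` compares the local densities of
the donor- and acceptor-excitation photon streams at each other's
arrival times, scoring near 0 for a static dual-labelled burst and high
for donor-only, acceptor-only, blinking or bleaching molecules;
`FRET-2CDE = 110 - 100 (<E>_D + <1-E>_A)` (with the $(1+2/N)$ no-burst
correction of the same-channel density) scores near 10 for
FRET-static bursts and departs from 10 when the FRET efficiency changes
within a burst. The working thresholds are `ALEX-2CDE <= 12` and, when
enabled, `8 <= FRET-2CDE <= 12`; the FRET-2CDE band is optional because
its applicability depends on the data. Absolute scores are kernel-bandwidth dependent — tests verify
threshold behaviour against a brute-force kernel oracle, not absolute
values.

`E` histograms use bin width 0.025 on [-0.1, 1.1], and populations are
least-squares fits of 1-3 Gaussians to the bin counts — fitting the
histogram rather than the raw sample is the convention for this kind of
population analysis. The "bent fraction" is the weight of the
highest-mean component.

# HMM idealization

The hidden-Markov model operates on the one-dimensional corrected
`E(t)` signal — matching the established smFRET trace-analysis
convention — with Gaussian emissions, a shared per-frame transition
matrix, and `K` fixed by the user (two for archaeal, three for
eukaryotic data); no model selection is performed. Parameters are
maximum-likelihood estimates from scaled Baum-Welch EM over all pooled
traces; the log-likelihood is recorded per iteration and asserted
non-decreasing. Initialization places state means at evenly spaced
quantiles of the pooled signal, with up to 9 additional random restarts
(means redrawn uniformly over the data range, best likelihood kept,
seed recorded) — the restarts matter when a state holds only a small
occupancy fraction, e.g. the 1% bent occupancy of the archaeal system
at room temperature. Emission standard deviations are floored at
`1e-3` to keep noiseless fixtures finite. Frames with undefined `E`
(zero total intensity, masked regions) are treated as missing emissions,
not zeros. States are relabelled ascending in mean, so state 1 is
always the unbent (low-FRET) state.

Viterbi decoding is deterministic with ties broken toward the
lower-index state; it is verified against exhaustive path enumeration on
short traces. Dwells are run-length encodings of the decoded paths in
seconds; the first and last dwell of each trace are censored by the
observation window and excluded from fitting by default (an
`include_censored` option is provided because censoring conventions
vary between analyses).

# Kinetics

Two mono-exponential dwell estimators are provided:

* **MLE**: $\hat\tau$ = sample mean, SE $= \hat\tau/\sqrt n$ — optimal
  for fully observed exponential data, but biased upward by the camera's
  detection dead time: dwells shorter than about one frame are never
  decoded, so the sample mean estimates $\tau + c$ with $c$ of order
  one frame period. At 50 Hz and $\tau = 0.18$ s this bias is material
  (about +15%).
* **histogram**: least-squares fit of $A e^{-t/\tau}$ to dwell counts
  binned at two frame periods with the first bin dropped. Dropping the
  missed-event bin makes the estimator insensitive to the dead time —
  this mirrors the standard mono-exponential dwell-histogram fitting of
  smFRET kinetics, and it is the estimator the acceptance pipeline
  uses for camera-limited dwell recovery.

Transition rates under a declared topology are
$k_{ij} = \mathrm{branch}(i \to j)/\tau_i$ with branching fractions from
the decoded transition counts restricted to allowed transitions; for
single-exit states this reduces to $k = 1/\tau$, so single-exit rates are
exact dwell-time reciprocals (e.g. $1/0.24 = 4.2\,$s$^{-1}$ at the
1-decimal reporting precision). Transitions forbidden by the linear
topology above a 5% count fraction trigger a warning — rare decoded
1 <-> 3 events arise from two true transitions inside one frame at 50 ms
resolution and are expected at the percent level. Row consistency
$\sum_j k_{ij}\,\tau_i = 1$ holds by construction. Temperature effects
are reported as dwell-time ratios rounded to the nearest integer,
matching the reporting precision of such factors; full-precision values
are always retained.

Survival series are fit by least squares to $e^{-t/\tau}$ with the
amplitude fixed at 1 by default (every complex present at $t = 0$).
Titrations are fit to the pseudo-first-order isotherm $c/(c+K_d)$ by
weighted least squares, with inverse binomial-variance weights when
per-point counts are known.

# Problem sizes and numerical choices

The recovery analyses in `scripts/acceptance.R` use 300 traces of 60 s
at 50 Hz for the two-state system, 200 traces of 30 s for the
three-state system (trace duration for the three-state runs is a
package choice; only the trace count is part of the stated recovery
setup), 500 molecules sampled every minute over 40 min for the survival
fit, and 8 log-spaced concentrations with 1000 molecules per point for
the titration. These sizes put the Monte-Carlo standard error of each
recovered quantity several-fold below its acceptance tolerance.
Burst-level recovery uses envelopes of median 3 ms and 150 photons/ms so
that bursts comfortably satisfy the `M` = 30 / `N` = 120 criterion; the
envelope is a configurable convention and only count ratios propagate
downstream. EM convergence uses a relative log-likelihood tolerance of
`1e-6`; Gaussian histogram fits and all nonlinear least squares use
Levenberg-Marquardt (`minpack.lm`), with quantile/log-linear starting
values.

# What the synthetic data do and do not show

The generator reproduces the statistical structure the analysis
assumes: exponential dwells, Markov switching, camera integration,
Gaussian noise, Poisson photons, crosstalk, contaminant species,
single-step bleaching, binomial titration/survival sampling. It does
not model optical point-spread functions, 3-D diffusion through a real
confocal volume, power-law blinking, spectral drift, or baseline
wander. Passing recovery tests therefore demonstrates that the
estimators are correct and well calibrated under the stated model — not
that the model captures every artifact of real recordings. Transitions
faster than about two frames are unreliable at any camera rate; dwell
estimates for states whose mean dwell approaches the frame period
should use the histogram estimator and be read with the dead-time
caveat above.

# Known limitations

* Proximity ratios only; no gamma correction, no distances, no TCSPC
  lifetimes.
* Photon streams are read and written as columnar TSV
  (`timestamp_us`, `channel`, `excitation_slot`).
* No Bayesian or nonparametric state-number inference; `K` is a user
  decision.
* No Arrhenius analysis of the temperature series; the package reports
  ratio factors only.
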