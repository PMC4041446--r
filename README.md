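# tatabend

Single-molecule FRET analysis of promoter DNA bending by the
TATA-binding protein (TBP) and transcription factor B (TFB/TF(II)B).

During transcription initiation, TBP recognizes the TATA-box and bends
the promoter DNA; TFB stabilizes the complex. With a donor/acceptor
pair flanking the TATA-box, bending shortens the dye-dye distance and
raises the FRET efficiency, so conformational dynamics can be read out
molecule by molecule. `tatabend` implements the two standard smFRET
readouts of this assay for analysts working with such data:

* **Confocal ALEX bursts** (diffusing molecules): sliding-window burst
  search (`T`/`M`/`N` criterion), background and crosstalk correction,
  the proximity ratio and stoichiometry

  *E* = F_A^D / (F_A^D + F_D^D),  *S* = (F_A^D + F_D^D) / (F_A^D + F_D^D + F_A^A),

  ALEX-2CDE / FRET-2CDE kernel-density filtering of donor-only,
  acceptor-only, blinking and bleaching molecules, and Gaussian
  population fits of *E* histograms (bent fraction = weight of the
  high-*E* component).
* **TIRF trajectories** (immobilized molecules): trace correction,
  photobleaching truncation, *K*-state Gaussian-emission hidden Markov
  idealization of *E*(t) (K = 2 archaeal, K = 3 eukaryotic), Viterbi
  decoding, dwell-time extraction with censoring, mono-exponential
  dwell fits (MLE and dead-time-robust histogram mode), transition
  frequencies and rates k_ij = branch(i→j)/τ_i under two-state or
  linear three-state topologies, survival-lifetime fits exp(−t/τ), and
  Langmuir isotherm fits f(c) = c/(c + K_d).

A seeded synthetic-data generator (continuous-time Markov state paths,
camera-frame integration, Poisson photon emission with alternation-slot
labels, contaminant species, bleaching, binomial titration/survival
sampling) emulates the experiments, so the whole pipeline is testable
without external data. See `vignettes/tatabend-methods.Rmd` for models,
assumptions and numerical choices.

## Worked example

Three-state eukaryotic dynamics at the measured state parameters
(proximity ratios 0.32/0.60/0.75, dwell means 0.24/0.31/0.44 s),
idealized at 50 Hz:

```r
library(tatabend)

cfg <- sim_config(n_states = 3, state_E = c(0.32, 0.60, 0.75),
                  dwell_means = c(0.24, 0.31, 0.44),
                  topology = "linear-three-state",
                  e_noise_sd = 0.05, frame_period = 0.02)
traces <- lapply(simulate_traces(cfg, 50, 20, rng_seed = 7), correct_trace)

fit <- fit_hmm(traces, K = 3, n_restarts = 4, seed = 1)
fit
#> <hmm_fit> K = 3, loglik = 66744.8
#>   means:  0.324, 0.599, 0.749
#>   sds:    0.054, 0.051, 0.050
```

The three emission means recover the configured bending states to
within 0.01. Decoding and dwell/rate analysis:

```r
paths  <- lapply(traces, function(tr) viterbi_path(fit, tr))
dwells <- extract_dwells(paths, frame_period = 0.02)
taus   <- sapply(1:3, function(s)
  fit_exponential(dwells, state = s, method = "histogram",
                  frame_period = 0.02)$tau)
round(taus, 3)
#> [1] 0.206 0.365 0.438

tf <- transition_frequencies(paths, n_states = 3, frame_period = 0.02)
derive_rates(taus, tf, topology = "linear-three-state")
#> <rate_matrix> linear-three-state (1/s, 1 dp)
#>      [,1] [,2] [,3]
#> [1,]   NA  4.9   NA
#> [2,]  1.4   NA  1.3
#> [3,]   NA  2.3   NA
```

The fully-bent exit rate k_32 = 2.3 s⁻¹ is the reciprocal of its 0.44 s
dwell; at this small scale (50 traces) the faster states carry a few
ten-percent sampling error, which shrinks at the acceptance-scale run
below. Equilibrium and stability readouts are one-liners:

```r
fit_kd(simulate_titration(48, 10^seq(0, 3, length.out = 8),
                          n_per_point = 1000, rng_seed = 1))
#> <kd_fit> Kd = 48.3 +/- 1.9 nM

fit_survival(simulate_survival(732, seq(0, 2400, 60),
                               n_molecules = 500, rng_seed = 1))
#> <survival_fit> lifetime = 752 s = 12.5 min (+/- 0.11 min)

temperature_factor(19.2, 1.14)$approx   # unbent-dwell reduction, 22 -> 60 C
#> [1] 17
```

A YAML-driven end-to-end pipeline (`run_pipeline()`, demo configuration
in `inst/extdata/demo-config.yaml`) and a thin CLI
(`inst/scripts/tatabend`) chain simulate → idealize → kinetics and
write CSV/JSON artifacts with a seed-stamped manifest.

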