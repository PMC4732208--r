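---
title: "Quantifying information transfer in stochastic ERK signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information transfer in stochastic ERK signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erksense)
```

## The question

Single cells sense hormones through noisy biochemical relays. Averaged over a
population, a dose-response curve may look beautifully graded while each
individual cell barely distinguishes "hormone present" from "hormone absent".
The natural currency for this distinction is the mutual information between
stimulus and single-cell response,

$$ I(S;Z) \;=\; H(Z) - H(Z \mid S), $$

in bits: the reduction in uncertainty about the stimulus $S$ achieved by
observing the response $Z$. One bit is the capacity needed to discriminate two
equally probable stimulus levels without error; an estimate below one bit
means single cells cannot do even that. `erksense` packages the two halves of
this analysis — a stochastic model of ERK activation whose information
transfer can be mapped across feedback strengths, and an MI estimator for
paired stimulus/response snapshot data (simulated or imaging-like) — plus a
synthetic single-cell data generator that stands in for imaging data so the
whole pipeline is testable end-to-end.

## The stochastic ERK activation model

The model is a mass-action jump process over 11 species. A stimulus $S$
(copy number, constant within a run) converts an upstream effector between
inactive and active forms, and both forms phosphorylate the substrate — the
active form rapidly, the inactive form at a much lower constitutive *leak*
rate. Phosphorylated substrate (`pSub`, the measured response; the model's
stand-in for doubly phosphorylated ERK) is removed by a constitutive
phosphatase. Two negative feedback loops close the circuit:

* **Fast feedback**: `pSub` binds reversibly to both effector forms;
  the bound effector cannot phosphorylate substrate. The binding strength
  `fast_fb` is the control parameter (the experimental analogue is
  ERK-mediated inhibitory phosphorylation of upstream kinases, acting within
  minutes).
* **Slow feedback**: `pSub` activates promoter copies (binding one `pSub`
  each); active promoters express a second phosphatase that is removed by
  first-order decay. The number of promoter copies `slow_fb` is the control
  parameter (the analogue of stimulus-induced nuclear phosphatase
  expression, acting over tens of minutes to hours).

Three protocol elements are fixed by design: total substrate is drawn per
run from a log10-normal law (mean 3.9, SD 0.1 on the log10 scale; the
dispersion is an overridable parameter),
the signal is drawn log-uniformly on 10–1000 molecules, and every run is
equilibrated without stimulation before the signal is introduced.

### Default rate constants and why

The rate constants are this package's own default parameterization,
declared and reasoned about here rather than inherited from elsewhere; all
values are per second (first order) or per molecule per second (second
order) and every one is a visible argument of `erk_params()`.

| parameter | default | role |
|---|---|---|
| `active_rate` | 1.75e-4 | phosphorylation by active effector |
| `leak_rate` | 1.75e-5 | constitutive phosphorylation (10× lower) |
| `e_total` | 60 | effector copies |
| `pase1_count`, `k_pase1` | 50, 4e-5 | constitutive dephosphorylation, 2e-3/s in total |
| `k_act`, `k_deact` | 2e-4, 0.01 | effector activation/deactivation; half-activation at S = 50 |
| `fb_unit`, `fb_off` | 0.015, 0.1 | fast-feedback binding unit and unbinding |
| `k_prom_on`, `k_prom_off` | 2e-7, 6e-5 | promoter binding (Kd ≈ 300, slow exchange) |
| `k_pase2_prod`, `k_pase2_deg`, `k_pase2` | 1e-3, 2e-4, 1e-5 | inducible phosphatase expression, decay, activity |

The guiding constraints, in order of importance:

1. **The leak must be able to saturate the cycle.** With feedback off, the
   maximal phosphorylation flux is ~4.6× the dephosphorylation rate and the
   basal (S = 0) flux ~0.5×, so an unfettered cell sits high on its transfer
   curve: basal `pSub` ≈ 2 500 of ~7 900 substrate copies, and the 10–1000
   molecule signal range maps onto a compressed response band. Compression
   against a fixed ~23 % cell-to-cell CV in total substrate is what makes
   weak feedback a poor information channel at steady state.
2. **Intermediate fast feedback must desaturate and buffer.** Sequestration
   of the effector by `pSub` is self-limiting (free effector scales as
   Kd/`pSub`), which both restores a graded response and halves the
   sensitivity of `pSub` to the heterogeneous substrate total (log-log
   elasticity drops from ~1 to ~0.5). At the intermediate anchor
   `fast_fb = 1.66`, responses sit at a few hundred molecules — large enough
   that counting noise stays small.
3. **Strong fast feedback must crush the response into shot noise.** The
   equilibrium of the sequestration loop forces `pSub` to scale as the
   square root of the binding Kd, so spanning the strength scale
   (10^-0.5 to 10^3.5) moves the 60-min response from thousands of molecules
   down to ~10, where counting noise destroys discrimination. `fb_unit`
   places that collapse at the top of the scale.
4. **The slow loop works on the transcription time scale.** Promoter
   exchange (hours) and phosphatase turnover (~1.4 h) make the inducible
   phosphatase level during the first hour of stimulation largely a record
   of each cell's *pre-stimulus* basal activity: it opposes the constitutive
   leak and partially normalizes cell-to-cell differences, while very many
   promoter copies both soak up `pSub` stoichiometrically and overexpress
   phosphatase, crushing the response.

The named feedback-strength anchors (0.01 / 1.66 / 330 and the 10^-0.5 to
10^3.5 sweep) define the `fast_fb` scale; `fast_fb` multiplies
`fb_unit` to give the association rate constant. Used literally as
association constants at these copy numbers, the same numbers would make the
weak end of the scale already saturating, so the unit constant is the one
degree of freedom that anchors the scale to the negligible-to-overwhelming
range.

A known limitation of this calibration: the slow loop's benefit to
information transfer is modest. The inducible phosphatase is expressed from
few active promoter copies, and its own copy-number noise (binomial promoter
occupancy times Poisson expression) returns much of the variance that
per-cell normalization removes. The MI-versus-`slow_fb` curve at intermediate
fast feedback therefore has a shallow interior maximum rather than a
pronounced one; the test suite asserts the strong form of this property and
documents its failure rather than relaxing it.

## The simulator

`gillespie()` implements the exact direct method: two uniform random numbers
per event, propensities recomputed per event (the network has 14 reactions;
exactness was preferred over speed, and the Rcpp core advances ~10^7 events
per second). The recorded state at a readout time is the instantaneous jump
process value — the state immediately before the first event after that time
— emulating a fixed-cell snapshot stain rather than a window average. A state
with zero total propensity is absorbing and is held to the end of the run. A
cap (default 10^8 events per run) turns parameter pathologies into errors
rather than hangs.

`equilibrate()` runs the unstimulated network for ten times the slowest
mean-field relaxation time, computed from the Jacobian eigenvalues at the
S = 0 fixed point (conservation-law zero modes excluded; the fixed point
itself comes from long integration of the mass-action ODE via deSolve). The
burn-in is capped at 2×10^5 s with a warning recorded in the returned
state's metadata if the cap binds. A split-half test in the suite checks
that doubling the burn-in does not move the ensemble mean.

`simulate()` on an `erk_model` draws per-run child seeds from the root seed
by a counter-based map, so ensembles are bitwise reproducible and
independent of evaluation order. Each run: draw the substrate total, burn
in at S = 0, draw the signal, simulate, record `pSub` at the readout times.

The mean-field ODE (`mean_field()`) doubles as a verification oracle: at
100-fold copy numbers (second-order constants scaled down 100-fold) the
ensemble mean tracks the ODE solution to well under a percent, and in the
feedback-free unstimulated model — which is linear in the phosphorylated
substrate — the stochastic stationary mean equals the ODE fixed point
exactly, a sharp test of the burn-in.

## The MI estimator

`mi()` estimates $I(S;Z)$ from paired records. Choices, all declared rather
than inherited:

* **Response discretization**: equal-count (quantile) bins, default
  $\lfloor\sqrt{n/10}\rfloor$ capped at 64 — stable occupancy of the joint
  table. Equal-count binning makes the estimate invariant under strictly
  monotone transforms of the response (a property of MI itself, and a test).
* **Signal discretization**: categorical stimuli (e.g. the 8 assay
  concentrations including 0) keep their labels; a continuous simulated
  signal is split into 8 equal-count bins on the log10 scale, matching the
  log-uniform sampling law. Ties are assigned left-closed,
  deterministically.
* **Bias correction**: the plug-in estimator is biased upward by
  finite sampling; the package computes it at sample fractions 1, 1/2 and
  1/4 (disjoint random splits, averaged) and extrapolates the linear model
  $\mathrm{MI}(n) = \mathrm{MI}_\infty + a/n$ to infinite $n$. On
  independent data at $n = 10^4$ this drives the estimate from ~0.015 bits
  (plug-in at default bins) below 0.02 bits.
* **Uncertainty**: nonparametric bootstrap over cells (default 100
  resamples).
* Estimates are clamped to $[0, \min(\log_2 \#S, \log_2 \#Z)]$; raw AFU
  values are binned as-is (backgrounds are never subtracted).

k-nearest-neighbour and kernel estimators, channel-capacity optimization
over input distributions, and trajectory (multi-time) MI are deliberately
out of scope.

## The synthetic single-cell assay

`simulate_cells()` generates imaging-like tables with the statistical
structure of a high-content dose-response experiment: 8 stimulus levels
(0 plus 10^-12 to 10^-6 M in decade steps), times 5–360 min, a Hill
dose-response (EC50 10^-9 M) modulated by a unit-peak kinetic profile —
*transient* (rise ~2 min, decay ~25 min; near basal by 60–360 min) or
*sustained* (rise to plateau) — log-normal per-cell amplitude (CV 0.5) and
EC50 (sdlog 0.35) heterogeneity, multiplicative log-normal measurement noise
(CV 0.2), and an additive uniform 120–150 AFU background that is never
subtracted. Cells are assigned to 3 replicate wells per condition and pooled
before analysis, mirroring imaging practice. An optional log-normal per-cell
receptor covariate scales the response amplitude saturably, enabling MI
between receptor expression and response at a fixed saturating stimulus.

This generator is phenomenological plumbing, not mechanism: it reproduces
the marginal structure (graded means, heavy right tails, unsubtracted
background, transient-versus-sustained kinetics, receptor dependence) but
not image segmentation artefacts, spatial or cell-cycle covariance, or any
receptor-level biochemistry. Tests passing on synthetic data therefore
validate the estimator and pipeline logic, not biological conclusions about
real cells.

## In-silico experiments

`feedback_grid()` sweeps (fast, slow) feedback strengths — default 9×9 over
10^-0.5…10^3.5 and 10^0…10^4 on log10 scales — estimating MI (signal in 8
log-quantile bins) and the population response range (max − min of the
signal-binned mean response) per readout time, with per-cell seeds derived
from the root seed and failed cells marked rather than dropped. The two
surfaces deliberately dissociate: the settings that maximize the
population-averaged response are weak-feedback settings, while MI peaks at
intermediate feedback.

`apply_perturbation()` encodes the experimental analogues: `feedback_broken`
(both loops off — catalytically dead kinase), `slow_fb_increased` (promoter
copies multiplied), and `slow_fb_removed` (inducible-phosphatase production
disabled from stimulus onset while pre-equilibration retains it — a protein
synthesis block added shortly before stimulation, which is why the 5-min
response is untouched while later responses become larger and more
sustained).

## Problem sizes and numerical choices

The suite runs the behavioural assertions at 500 runs per condition (the
headline simulation protocol uses 2000; the acceptance script runs both),
asserts distributional exactness of the simulator at α = 0.01
(birth–death stationarity by chi-square, waiting times by
Kolmogorov–Smirnov), requires estimator-versus-oracle agreement to 10^-12
bits on explicit joint tables, and uses fixed 3-standard-error margins for
ensemble comparisons rather than formally corrected tests — these are
acceptance properties, not inference. Readout times of 60 and 180 min are
used for steady-state properties because the phosphorylation cycle relaxes
in ~10 min and the slow loop in ~1–2 h; 5-min readouts are dominated by
carried-over pre-stimulus state and are used only where that is the point
(the synthesis-block control). Sample-fraction splits and bootstrap draws
inside `mi()` honour a local seed without disturbing the caller's RNG
stream.

## Known limitations

* Rate constants are this package's calibration; conclusions should be
  read as properties of the model class, anchored to the named feedback
  strength scales.
* One-bin-per-promoter-state sequestration of `pSub` by promoters is a
  modelling convenience; at 10^4 promoter copies it contributes materially
  to the crush of the response.
* The receptor level enters the synthetic assay as a static covariate; no
  receptor-level mechanism (G-protein coupling, desensitization) is
  modelled.
* Per-time-point MI on snapshots underestimates the information available
  in response trajectories; trajectory MI is out of scope.
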