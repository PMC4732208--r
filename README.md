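# erksense

Information transfer through a noisy kinase signalling pathway, measured the
way a single cell experiences it. `erksense` quantifies how reliably
individual cells can infer an extracellular stimulus concentration from a
single-cell readout of ERK activation, using the mutual information (MI)

    I(S; Z) = H(Z) − H(Z | S)

between a stimulus *S* and a response *Z* (in bits). An MI below 1 bit means
a cell cannot unambiguously distinguish even two equally probable stimulus
levels. The package is aimed at systems biologists studying signalling
fidelity: it couples an exact stochastic simulator of an ERK activation model
with negative feedback to a bias-corrected MI estimator and a synthetic
single-cell imaging data generator, so the full analysis pipeline runs
end-to-end with no external data.

## What is inside

**Stochastic ERK activation model** (`erk_model()`, `build_erk_network()`).
A mass-action jump process in which a stimulus *S* activates an upstream
effector (E → E*), both effector forms phosphorylate ERK (Sub → pSub, the
inactive form at a much lower constitutive "leak" rate), and a constitutive
phosphatase dephosphorylates pSub. Two negative feedback loops act on
different time scales:

* *fast feedback* — reversible, inactivating binding of pSub to E and E*
  (strength `fast_fb`; anchors 0.01 / 1.66 / 330 for low / intermediate /
  high);
* *slow feedback* — pSub-dependent activation of `slow_fb` promoter copies
  expressing a second phosphatase (anchors 1 / 100 / 10000).

Per run, total substrate is drawn log10-normally (mean 3.9, SD 0.1) and the
signal log-uniformly on 10–1000 molecules; the model is pre-equilibrated
without stimulation before the signal is introduced. Simulation is the exact
Gillespie direct method (Rcpp core), with the matching mean-field ODE
available through `mean_field()` / `steady_state()`.

**MI estimator** (`mi()`, `entropy_bits()`, `discretize_signal()`).
Equal-count response binning, plug-in estimate on the joint table,
finite-sample bias correction by subsampling extrapolation (plug-in MI at
sample fractions 1, 1/2, 1/4, extrapolated to infinite n), and a
nonparametric bootstrap SE over cells.

**Synthetic single-cell imaging assay** (`assay_config()`,
`simulate_cells()`). Hill dose–response × kinetic profile (transient or
sustained) with log-normal cell-to-cell heterogeneity, multiplicative
measurement noise, an additive unsubtracted 120–150 AFU background, and an
optional per-cell receptor-expression covariate that scales the response.

**Experiment orchestration** (`feedback_grid()`, `apply_perturbation()`,
`mi_timecourse()`, `population_summary()`). Feedback-strength sweeps
producing MI and response-range surfaces, per-time-point MI curves, and model
analogues of classic perturbations: catalytically dead kinase (both loops
broken), promoter-driven extra phosphatase (slow loop increased), and a
protein-synthesis block at stimulus onset (slow loop removed, basal
phosphatase retained).

## Worked example

```r
library(erksense)

model <- erk_model(fast_fb = 1.66, slow_fb = 100)
model
#> Stochastic ERK activation model (two negative feedback loops)
#>   fast feedback strength: 1.66   slow feedback promoters: 100
#>   leak/active phosphorylation: 1.75e-05 / 0.000175 per molecule per s
#>   total substrate: log10-normal(3.9, 0.1); signal: log-uniform [10, 1000]
#>   mean-field basal pSub: 98.6; burn-in: 95943 s (10x relaxation 9594 s)

ens <- simulate(model, nsim = 300, seed = 42, times = c(5, 60))
head(ens, 3)
#>   run    seed  S total_sub time_min pSub
#> 1   1 3005628 47      5217        5  106
#> 2   1 3005628 47      5217       60  174
#> 3   2 3110357 54      8959        5  132

mi(pSub ~ S, ens[ens$time_min == 60, ], seed = 7)
#> Mutual information: 0.8561 bits (bootstrap SE 0.0602)
#>   n = 300 cells, 8 signal levels x 5 response bins, correction: jackknife
```

300 single-cell runs at intermediate feedback transmit about 0.86 bits at
60 min — far below the 3 bits an 8-level log-quantile-binned input could
carry, and below the 1 bit needed to tell two equiprobable levels apart.
The same estimator applied to the synthetic imaging assay shows the
transient kinetics collapsing information at late times:

```r
cells <- simulate_cells(assay_config(times = c(5, 360)), seed = 1)
mi_timecourse(cells, response ~ stimulus, boot = 40, seed = 2)
#>   time_min     mi_bits     se_bits    n
#> 1        5 0.799639471 0.009298197 8000
#> 2      360 0.003047711 0.003611736 8000
```

Feedback-strength surfaces (MI and population response range per grid cell)
come from `feedback_grid()`, with a base-graphics heat map via `plot()`.

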