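# peatcausal

Causal analysis of peatland carbon-water flux time series in R.

Peatlands store more carbon per unit area than any other ecosystem, and that
store is controlled by water: vascular plants throttle photosynthesis (GPP)
through stomata as vapour pressure deficit (VPD) rises, while mosses simply
dry out once the surface water pool is drawn down past a threshold. Given a
weekly flux-tower table (AmeriFlux-style columns), `peatcausal` derives the
micrometeorological quantities, computes drought indicators, and runs an
equation-free causal analysis to separate the two modes of water limitation:

* **micromet** — Penman potential evapotranspiration
  $PET = \tfrac{s}{s+\gamma}\tfrac{R_n}{\lambda} +
  \tfrac{\gamma}{s+\gamma}(2.626 + 1.381u)\,D$; bulk surface conductance by
  inverting the big-leaf Penman-Monteith equation,
  $G_{sw} = \gamma\lambda E G_{ah} / [s(H{+}\lambda E) + \rho c_p G_{ah} D -
  \lambda E(s{+}\gamma)]$; aerodynamic conductances
  $G_{am}=u_*^2/u$, $G_{bh}=(6.2u_*^{-0.67})^{-1}$ in series; evaporative
  fraction $EF = \lambda E/(\lambda E + H)$.
* **drought** — moisture coefficient ET/PET (weekly stress below 0.6), a
  log-logistic SPEI re-implemented from probability-weighted moments, and
  the six-way annual high/low classification (stress, drought severity,
  conductance, ET, SWC decline, EF).
* **edm** — empirical dynamic modelling from first principles: time-delay
  embedding, simplex projection (selects the embedding dimension), S-map
  locally linear coefficients as weekly interaction strengths
  ($\partial GPP/\partial SWC$, ...), and convergent cross mapping (CCM)
  with the analytic standard error $SE = \sqrt{(1-\rho^2)/(N-3)}$.
* **attribution** — exact 52-bin weekly aggregation with omission
  bookkeeping, lagged cross-correlation (e.g. ET leading soil-water
  decline), segmented-regression threshold estimation for the GPP-SWC knee,
  and redundancy analysis (constrained ordination) of the weekly causal
  strengths.
* **synthetic_data** — a seeded synthetic bog with known causal structure:
  prescribed conductance with VPD down-regulation, a soil-water bucket whose
  decline lags ET by a configurable memory (14 weeks by default), a GPP
  limitation that switches on below 82.5 % SWC, and queryable ground truth.

## Worked example

Five simulated years, first week omitted (the classic bookkeeping of a
record whose first fluxes are missing), full pipeline:

```r
library(peatcausal)
cfg <- run_config(sim = sim_config(seed = 42),
                  omit_weeks = data.frame(YEAR = 2016, WEEK = 1),
                  lib_sizes = c(30, 80, 150, 250), n_samples = 30, seed = 42)
out <- run_all(cfg, out_dir = "run42")
str(out$summary, max.level = 1)
#> List of 10
#>  $ retained_weeks          : int 259
#>  $ seed                    : int 42
#>  $ annual_classification   :'data.frame':  5 obs. of  7 variables:
#>  $ converged_gpp_drivers   : chr [1:7] "TA" "SW_IN" "VPD" "SWC" ...
#>  $ best_lag_weeks          : int 13
#>  $ lag_r                   : num 0.887
#>  $ threshold_swc           : num 83
#>  $ threshold_has_break     : logi TRUE
#>  $ rda_proportion_explained: num [1:2] 0.695 0.196
#>  $ implanted_gpp_drivers   : chr [1:3] "SW_IN" "VPD" "SWC"
```

Reading the numbers: 259 of 260 weeks survive the omission bookkeeping (so
the conventional cross-correlation test runs on 257 degrees of freedom). ET
leads the soil-water decline by 13 weeks at this noise level (r = 0.89; the
implanted hydraulic memory is 14, recovered exactly when observation noise
is low). The segmented GPP-SWC regression places the water-limitation knee
at 83 % SWC against an implanted 82.5 %. The CCM screen ranks the implanted
drivers (radiation, VPD, soil moisture: cross-map skills 0.84-0.90) above
the non-coupled CO2 channel (0.67), and the first RDA axis of the weekly
S-map strengths explains 70 % of the GPP/Reco variance.

```r
print(out$threshold)
#> breakpoint at 83.00 (95% bootstrap CI 82.00..95.51)
```

Single stages are available directly: `derive_micromet()`, `spei()`,
`classify_years()`, `simplex()`, `smap()`, `ccm()`, `cross_correlation()`,
`breakpoint()`, `rda_ordination()`. A command-line front end ships in
`inst/cli/peatcausal` (subcommands `simulate`, `derive`, `drought`, `edm`,
`attribute`, `run-all`).

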