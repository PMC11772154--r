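---
title: "Methods: carbon-water coupling and causal inference in a synthetic bog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-water coupling and causal inference in a synthetic bog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatcausal)
```

## The problem

Peatlands fix carbon when photosynthesis (GPP) outpaces decomposition, and
both halves of that balance run through water. Vascular plants close stomata
as atmospheric demand (vapour pressure deficit, $D$) rises; mosses have no
stomata and simply dry out as the surface water pool is drawn down. A weekly
eddy-covariance record therefore carries two distinct fingerprints of water
limitation: an immediate, $D$-driven down-regulation of the bulk surface
conductance $G_{sw}$, and a delayed, soil-moisture-driven suppression of GPP
that switches on only once volumetric soil water content (SWC) falls below a
site threshold. This package implements the full chain needed to separate
the two on weekly flux-tower tables: micrometeorological derivations,
drought indices, empirical dynamic modelling (EDM) for causal inference, and
lag/threshold attribution — plus a synthetic bog generator whose causal
structure is known exactly, so every stage is testable without tower data.

## Micrometeorological derivations

Potential evapotranspiration uses the Penman combination form

$$PET = \frac{s}{s+\gamma}\,\frac{R_n}{\lambda}
      + \frac{\gamma}{s+\gamma}\, f(u)\,D, \qquad f(u) = 2.626 + 1.381\,u,$$

with $R_n$ in MJ m$^{-2}$ day$^{-1}$, $D$ in kPa and PET in mm day$^{-1}$.
Saturation vapour pressure comes from the Magnus formula
$0.6108\,e^{17.27T/(T+237.3)}$ kPa, $\lambda = 2.501 - 0.002361\,T$ MJ
kg$^{-1}$, and $\gamma = c_p\,p/(0.622\,\lambda)$; these standard
micrometeorological closures are an interpretation — the source symbols name
the quantities but not the formulas. Air pressure defaults to sea level
(101.325 kPa, appropriate for a delta site) unless supplied.

Bulk surface conductance inverts the big-leaf Penman-Monteith equation with
available energy approximated as $A = H + \lambda E$:

$$G_{sw} = \frac{\gamma\,\lambda E\,G_{ah}}
  {s\,(H + \lambda E) + \rho c_p G_{ah} D - \lambda E\,(s+\gamma)},$$

where $G_{ah}$ combines the momentum conductance $G_{am} = u_*^2/u$ and the
quasi-laminar boundary-layer conductance $G_{bh} = (6.2\,u_*^{-0.67})^{-1}$
in series. The grouping of the inversion is likewise an adopted
interpretation of an ambiguously typeset source; the package pins it down
with a forward-model round trip: `penman_monteith_le()` is the exact forward
counterpart, and the property suite checks
`surface_conductance(forward(Gs)) == Gs` to $10^{-6}$ relative over
randomized physical inputs. Weeks where the inversion denominator is
non-positive (condensation, strong advection) are flagged `NA` rather than
clipped to zero: truncation would distort the state-space embeddings
downstream. The single W m$^{-2}$ to MJ m$^{-2}$ day$^{-1}$ conversion
(0.0864) lives in one internal constant.

## Drought indicators

The moisture coefficient is ET/PET with a weekly stress flag strictly below
0.6. The SPEI standardizes rolling sums of the climatic water balance
$P - PET$: sums are fit with a three-parameter log-logistic distribution via
unbiased probability-weighted moments and mapped through the standard normal
quantile. Two numerical choices matter here:

* **Calendar-week climatology.** Classical SPEI fits one distribution per
  calendar month. Five years of weekly data leave ~5 observations per
  calendar week, far too few, so the week-of-year climatology of the rolling
  sums is subtracted and the pooled anomalies are fit instead. A raw pooled
  fit is not an option: strongly seasonal sums are bimodal and sit outside
  the log-logistic family entirely.
* **Reflection for left skew.** The log-logistic is right-skewed. When the
  anomaly sample is left-skewed (typical when drought summers produce a long
  dry tail) the fit is applied to the mirrored sample and probabilities are
  back-transformed. The fit validates its own output (scale $>0$, shape
  $>1$, origin below the data) instead of silently returning a decreasing
  CDF.

Annual high/low classification applies six fixed thresholds literally
(stress high below 0.4; drought severe at SPEI $\le -1.5$; $G_{sw}$ high at
$\ge 0.2$ m s$^{-1}$; ET high at $\ge 3$ kg m$^{-2}$ day$^{-1}$; SWC decline
high below 82.5 %; EF high above 0.5). Summaries use April-September
(week bins 14-39) means, with growing-season minima for SWC and SPEI, since
the classification reflects summer behaviour and the aggregation window is
not otherwise prescribed.

## Empirical dynamic modelling

All EDM machinery is implemented from first principles on time-delay
embeddings $(x_t, x_{t-\tau}, \dots, x_{t-(E-1)\tau})$:

* **Simplex projection** forecasts with $E+1$ nearest neighbours and
  exponential weights $w_i = \exp(-d_i/d_{\min})$ (floor $10^{-6}$; exact
  duplicates share weight 1), strictly leave-one-out, ties broken by time
  index so results are deterministic. The embedding dimension is chosen by
  forecast skill over $E \in 1{:}10$.
* **S-maps** solve a weighted least-squares locally linear map at every
  week, weights $\exp(-\theta\, d(x_i, x_t)/\bar d_t)$, via SVD with a
  relative singular-value tolerance; singular weeks are flagged `NA`. At
  $\theta = 0$ every week reproduces the global OLS fit exactly (the fits
  use all rows, which is what makes this identity hold). The per-week
  coefficients are the time-varying interaction strengths
  (e.g. $\partial GPP/\partial SWC$).
* **CCM** reconstructs the *effect's* shadow manifold and cross-maps the
  *cause*; skill $\rho$ is the Pearson correlation between observed and
  cross-mapped cause values, averaged over 100 seeded libraries drawn with
  replacement per library size. The analytic standard error is
  $SE = \sqrt{(1-\rho^2)/(N-3)}$ with $N$ the library size. Convergence is
  declared when $\rho(L_{\max}) - \rho(L_{\min}) > 0.1$ and
  $\rho(L_{\max}) > 1.96\,SE$ — these two thresholds are package choices,
  not sourced values. The default cross-map horizon `tp = -1` reads "causes
  precede effects by one week" and is configurable.

## Attribution

`weekly_aggregate()` partitions each calendar year into 52 exact seven-day
bins anchored at January 1 (tail days fold into bin 52), so week counts are
analytic: five full years minus one omitted bin is exactly 259 retained
weeks, and the conventional cross-correlation degrees of freedom on that
series are $N - 2 = 257$ (the full-series convention, not the lag-shortened
pair count; confidence intervals still use the pair count at the best lag).

The GPP-SWC threshold estimator is entirely package-defined (the finding it
recovers was identified descriptively in the source): a continuous
two-segment piecewise-linear fit, exhaustive grid search at 0.5-point
resolution, an AIC guard against over-segmentation (knee counted as a
parameter), and a seeded pairs bootstrap for the confidence interval. Its
sampling window is weeks 10-48 (March-November): in the simulated world the
water-limited weeks fall in late summer and autumn while the moss canopy is
still active, and the narrower April-September classification window would
miss them.

Redundancy analysis is multivariate least squares of the standardized
responses on the standardized explanatory matrix followed by an SVD of the
fitted values, with correlation-style ("type 2") biplot scaling: site scores
have unit variance, response loadings carry the singular values, and
explanatory arrows are correlations with the site scores. Collinear columns
are dropped by the QR rank decision with a message. The test suite checks
the eigenvalues against both a brute-force eigendecomposition and
`vegan::rda()`.

## The synthetic bog: what it emulates and what it does not

`gen_bog_weekly()` simulates 52-week years (plus a discarded spin-up year)
of coupled meteorology, energy, water and carbon:

* seasonal temperature, radiation and wind; VPD peaking in late July
  (lagging the radiation peak, as observed in maritime climates);
* surface conductance
  $G_{sw} = g_{\max}\cdot \text{season} \cdot e^{-\sigma D} \cdot f(SWC)$,
  with $\sigma$ = `stomatal_sensitivity` (0.5 kPa$^{-1}$) and $f$ equal to 1
  at or above `swc_threshold` (82.5 %) and declining by `swc_sensitivity`
  (0.10) per percentage point below it — the saturating exponential form for
  the VPD term is a documented config choice;
* latent heat from the forward Penman-Monteith model
  ($A = 0.65\,SW_{in}$, $H = A - \lambda E$), so the micromet inversion
  recovers the prescribed conductance exactly;
* a soil-water bucket $S_t = S_{t-1} + \text{inflow}_t - a\,7\,ET_{t-L} -
  \text{leak}_t$ with $L$ = `et_swc_lag` (14 weeks): ET withdraws from the
  monitored layer with a pure delay (the hydraulic memory of the peat), and
  recharge is the sum of a constant capillary baseflow and
  infiltration-limited rain (excess rain runs off the saturated surface);
* GPP = saturating light response x VPD down-regulation x SWC limitation;
  Reco as a $Q_{10}$ function of temperature; additive seeded observation
  noise on every channel.

Drought years double dry-season VPD, brighten the sky by 25 %, halve
dry-season rain and cut recharge to a quarter (the water table falls, so
capillary supply fails). GPP peaks near 3 gC m$^{-2}$ day$^{-1}$ in wet
years, drought-year SWC bottoms out near 73 %, the growing-season moisture
coefficient sits near 0.45, and summer SPEI reaches about $-1.9$ in drought
years — the magnitudes a weekly bog record of this kind shows.

Three stylizations are deliberate and worth knowing about:

1. **The rain returns late.** The dry season is centred on week 45, later
   than the real maritime autumn, so that the 14-week lagged ET drawdown
   completes before winter recharge begins. In a seasonally forced world the
   lag scan measures a blend of the mechanistic delay and the climate phase;
   with an early rain return the blend, not the implanted delay, would set
   the peak. Exactness at the default lag is a property of this stated
   world; away from the default the scan tracks `et_swc_lag` within about
   two weeks, which is also the honest reading of such a scan on real data.
2. **Severe droughts.** The drought anomalies are stronger than the real
   site's, so that below-threshold weeks span a wide enough SWC range for
   the knee to be identifiable by regression at all.
3. **Seasonality is a confounder by construction.** Every seasonal channel
   cross-maps every other to some degree; the CO$_2$ channel is therefore
   generated as nearly season-free AR(1) noise so that the "no causal role"
   comparison in the tests is meaningful. A green CCM test on this world
   shows the machinery ranks implanted couplings above a non-coupled
   channel — it does not certify CCM against seasonal confounding in
   general, and `couple_gpp = FALSE` provides a null world in which GPP is
   exchangeable noise.

The generator attaches its ground truth (coupling map, thresholds, lag, the
affine SWC-WTD map calibrated so 82.5 % SWC corresponds exactly to a water
table 8 cm below the surface) as an attribute, so tests compare inferred
against implanted structure. The affine SWC-WTD link is a stated assumption:
only the paired thresholds are known, not the true functional relation.

## Numerical choices and degenerate inputs

* Distances are Euclidean; multivariate blocks should be standardized
  (z-score per column) before embedding, and the pipeline does so.
* Weight floor $10^{-6}$ in simplex/CCM avoids division by zero at
  duplicate states; equidistant neighbours break ties by time index.
* The segmented-regression AIC guard uses 4 vs 2 mean-model parameters;
  a pure linear relation yields a "no breakpoint" verdict.
* The knee estimator is bimodal under observation noise (an occasional seed
  latches onto a high-SWC artifact mode), so multi-seed summaries use the
  median.
* Constant series are rejected with explicit errors everywhere a
  correlation, fit or forecast would be undefined; missing inputs propagate
  as flagged `NA`, never silent zeros.

## Limitations

Half-hourly processes, snow, energy-balance closure error, and flux
partitioning are out of scope (the generator supplies GPP/Reco directly).
The SPEI scale (12 weeks) and the cross-map horizon are config parameters
whose source values are unstated. The Table-1-style $G_{sw} \ge 0.2$
m s$^{-1}$ threshold is never reached by the physically scaled synthetic
conductances ($\sim 10^{-2}$ m s$^{-1}$); the classifier is exercised with
constructed summaries at the boundaries instead.
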