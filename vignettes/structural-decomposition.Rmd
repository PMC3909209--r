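---
title: "Decomposing shelf copepod time series: model, forcing indices, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing shelf copepod time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfcope)
```

## The problem

Shelf-wide zooplankton surveys on the Northeast U.S. continental shelf sample
each sub-region only a handful of times per year, at slightly different dates
each year, with multi-year gaps in the south. Questions about decadal change
("is the population trending?") and phenology ("has the timing of the annual
peak moved?") require separating three things that the raw bi-monthly means
confound: a slowly varying population level, a recurrent within-year cycle,
and sampling noise. `shelfcope` implements that separation as a structural
time-series decomposition estimated in state-space form, together with the
physical covariates used to interpret it: an altimetry-style alongshore
transport index and a PCA-weighted Gulf Stream North Wall Index (GSNWI).

## The model

The bi-monthly abundance $y_t$ (ind m$^{-3}$; $t$ indexed in bi-monthly bins,
so one year is 6 steps) is decomposed as

$$y_t = \mu_t + \gamma_t + \epsilon_t, \qquad
  \mu_t = \phi\,\mu_{t-1} + \eta_t,$$

with $\eta_t \sim N(0, \sigma^2_\eta)$, $\epsilon_t \sim N(0,
\sigma^2_\epsilon)$ independent. The local trend $\mu_t$ is a first-order
autoregression with $\phi \in (0,1]$; $\phi = 1$ recovers a random walk
(available exactly via `model_spec(trend_form = "rw")`). The seasonal
component is a deterministic trigonometric cycle with a 12-month period — 6
bins, hence harmonics $j = 1, 2$ as full sine/cosine pairs plus the
cosine-only Nyquist term $j = 3$:

$$\gamma_t = \sum_{j=1}^{2}\left[a_j \cos\tfrac{2\pi j t}{6}
  + b_j \sin\tfrac{2\pi j t}{6}\right] + a_3 \cos(\pi t).$$

By construction $\gamma_t$ is exactly 6-periodic and sums to zero over any
year, so the decomposition is identified: the trend carries the level, the
seasonal carries the cycle shape. Because the seasonal is expressed relative
to the trend, fitted seasonal values are routinely negative; fits operate on
the raw abundance scale by default (a `scale = "log"` option exists for
robustness studies).

### Estimation

The model is cast in state-space form with state vector
$(\mu_t, a_1, b_1, a_2, b_2, a_3)$; the five seasonal states are constant
and enter through a time-varying observation row that evaluates the harmonic
basis at $t$ (`build_state_space()`). The trend initial value and the
seasonal coefficients are treated as diffuse. Diffuse handling uses state
augmentation: the Kalman filter (RcppArmadillo) propagates, alongside the
zero-initialized innovations, the linear impact of each diffuse component on
every innovation; the generalized-least-squares estimate of the diffuse
vector and the diffuse (marginal) likelihood fall out of the accumulated
cross-products. The six diffuse innovations are thereby excluded from the
likelihood, which equals the dense-matrix marginal form

$$\ell = -\tfrac{n-d}{2}\log 2\pi - \tfrac12\log|\Sigma|
  - \tfrac12\log|X^\top\Sigma^{-1}X|
  - \tfrac12 r^\top \Sigma^{-1} r$$

exactly ($d = 6$; $r$ the GLS residual) — the test suite asserts this
equivalence, and the agreement of the fixed-interval smoother with the GLS
projection of the trend, to better than $10^{-8}$ relative error on small
instances with missing values. One practical consequence: rescaling the data
and both SDs by $c$ shifts the likelihood by $-(n_\mathrm{obs}-d)\log c$,
the diffuse analogue of the usual $-n \log c$.

Missing bins skip the measurement update, so gap years and unsampled bins
are handled without imputation. `kalman_loglik()` requires at least 12
observed bins (the 6 diffuse states plus room for the variances);
`fit_structural()` requires 24 (four seasonal cycles).

Maximization is over three parameters — $\phi$ through a logistic transform,
the two variances on the log scale, bounded within $\pm$ roughly 13 natural
log units of the sample variance — by `nlminb` from 5 starts (one
moment-based, four randomized with fixed sub-seeds), relative tolerance
1e-10. Two refinements matter in practice:

* **Boundary probes.** Variance MLEs often sit at $\sigma^2 \to 0$ (e.g.,
  noiseless or very smooth series), where the profile is flat in
  $\log\sigma^2$ and quasi-Newton steps stall early. After the multi-start,
  each variance is probed at its lower bound and the re-optimized result is
  kept only if the likelihood strictly improves.
* **Convergence flag.** PORT reports "false convergence" at boundary optima
  even when they are genuine. A fit is declared converged when the optimizer
  reports success or when repeated re-polishing from the best point leaves
  the objective unchanged to $\max(10^{-6}, |\ell|\cdot 10^{-8})$; an
  unstable optimum is reported honestly as `converged = FALSE` and
  `annual_peaks()` refuses to use it.

An alternative reading of the decomposition — random-walk trend with AR(1)
*observation* error — is available as `model_spec(error_ar1 = TRUE)` (the
error becomes a proper AR(1) state with stationary initialization). It is
off by default; outputs are labelled by the variant used via the stored
`model_spec`.

### Degenerate inputs

For an exactly constant series every parameterization with both variances
near zero fits perfectly, so the trend/seasonal split is only weakly
identified (the fitted values are still exact); the tests check the
decomposition of that case at 1% of the series level. Ties in the annual
peak go to the earliest bin. Constant north-wall series (zero SD) are
rejected rather than standardized to 0/0.

## Binning conventions

* A sample's bi-monthly bin is `ceiling(month/2)`; bin 1 = Jan–Feb, bin 6 =
  Nov–Dec.
* "Complete surveys" are operationalized through the cruise table: all tows
  sharing a `cruise_id` form one survey, the survey midpoint is the mean of
  its first and last tow dates, and the whole cruise is assigned to the
  midpoint's bin.
* A bin's value is the unweighted arithmetic mean over the qualifying tows
  (flowmeter standardization to ind m$^{-3}$ is assumed already applied). A
  bin with no samples is missing, never zero.
* Sub-regions are rectangles with shipped defaults (GOM north of 42°N east
  of 70°W; GB 40.5–42°N east of 69°W; SNE 39–41°N, 69–72°W; MAB south of
  39°N west of 72°W); they are approximations, overridable via
  `region_spec()`, and the configured order is the tie-break for boundary
  points (first listed wins). Overlapping interiors are rejected at
  validation.
* Latitude bands are half-open 2° bins $[35+2k, 35+2k+2)$; the half-open
  convention resolves the ambiguity of inclusive labels like "35–36°N".
* Southern series (SNE, MAB by default) are split at the 1989–1991 survey
  gap into 1977–1988 and 1992–2009 fits; northern series are fit over the
  full span (this is configurable — whether the original analysis also split
  the north is not determinable, so the unsplit reading is the default).

## Forcing indices

**Alongshore transport.** On the 1/3° grid row nearest the path latitude
(default 39.3°N, configurable because 39°N is an equally defensible
reading), the first 6 ocean cells within 2° of the coast are selected, the
2 nearest the coast discarded against land contamination, and the weekly
mean northward component of the remaining 4 is the index ("alongshore" is
operationalized as the meridional component; positive = northward).
Bi-monthly means, and annual cumulative northward ($\sum \max(v,0)$) and
southward ($\sum \min(v,0)$) components, follow; cumulative sums operate on
bi-monthly means by default. The operator is linear in the field and errors
on missing path cells rather than silently filling.

**GSNWI.** The six monthly north-wall latitude series (79, 75, 72, 70, 67,
65°W) are standardized over the fitting span; the weights are the first
principal component loadings, sign-fixed so the mean loading is positive
(PC sign is arbitrary) and rescaled to sum to one; the index is the weighted
average. Standardization makes the index invariant to affine rescaling of
any input series.

**Associations.** All relationships are ordinary least squares with Pearson
r and a two-sided t-test on $n-2$ df — the simplest reading of
"regression analysis" — after complete-pair removal. The full design
(species × region-plus-entire × {velocity, GSNWI, temperature} at the
annual scale, plus velocity~GSNWI at bi-monthly and annual scales) is
returned unfiltered, with no multiple-testing correction, so users can apply
their own. The annual covariate is the annual mean of the bi-monthly series
(the cumulative components are available as an alternative). The "entire
region" response is the across-region mean of the annual peak values.

## The synthetic-data generator

`synthetic_truth()` fixes the world the tests run in:

* **Survey structure.** One cruise per bi-monthly period, 1977–2009, with 6
  stations per region per survey (uniform within the region rectangles),
  and no MAB/SNE samples in 1989–1991 — the southern gap.
* **Abundance.** Per species × region, a deterministic slow trend (a 22-year
  sinusoid of ±20% around regional levels of 55–490 ind m$^{-3}$, the order
  of magnitude of shelf copepod surveys) plus a single-harmonic seasonal
  cycle with a north–south amplitude gradient (C. finmarchicus larger in the
  north and peaking in May–Jun; Cen. typicus larger in the south, peaking in
  Nov–Dec), plus AR(1) bin-level noise ($\phi = 0.95$, $\sigma_\eta = 5$).
  The default truth moves the MAB Cen. typicus peak from bin 6 to bin 1
  after 1985, emulating a phenology shift.
* **Station noise.** Tow counts are right-skewed, so station values are
  lognormal multiplicative around the bin latent value, calibrated so the
  additive SD equals `sigma_eps` (30 by default), then truncated at zero.
  This is a deliberate stand-in — the observation-noise distribution of real
  tows is not known to the package — and a deliberate deviation from the
  pure Gaussian observation model the estimator assumes.
* **Physics.** Weekly velocities on the 1/3° grid are mean southward flow
  (−5 cm s$^{-1}$) plus a per-year anomaly (SD 2), a monthly GSNWI coupling
  (−1.5 cm s$^{-1}$ per index unit, injected at the monthly scale and then
  aggregated, mirroring how both series are later binned), and weekly white
  noise (SD 4). The north-wall series share one standardized AR(1) common
  signal (0.5° per unit) plus independent 0.3° noise; the same common signal
  drives the velocity coupling, so the generated GSNWI and transport are
  negatively associated by construction.

What the generator does *not* emulate: tides, eddies, mesoscale structure,
net-efficiency or day/night corrections, non-stationary seasonal amplitude,
or any real-data magnitudes beyond order of magnitude. Passing tests
therefore demonstrate that the estimators recover the statistical structure
they assume, not that real surveys satisfy those assumptions.

### Simulation-study sizes

The recovery experiment fits 200 series of length 198 at the default truth
($\phi = 0.95$, $\sigma_\eta = 5$, $\sigma_\epsilon = 30$, seasonal
amplitude 100) with 3 optimizer starts per fit — the simulated-likelihood
surface is unimodal enough that more starts change nothing — and summarises
the median absolute error of $\hat\phi$ (observed ≈ 0.03) and the median
relative error of the seasonal amplitude (≈ 3%). The null calibration runs
500 replicates of the GSNWI~velocity regression with the coupling set to
zero, on a narrow grid window around the transport path. Calibration is
checked at the annual scale, where the generator's annual velocities are
exchangeable across years and the OLS t-test is exact; at the bi-monthly
scale both series are autocorrelated and nominal OLS p-values are expected
to be anti-conservative (a known caveat for the real analysis too).

## Worked example

```{r example, eval = FALSE}
library(shelfcope)

truth <- synthetic_truth(seed = 1)
samples <- generate_abundance(truth)
series <- build_series(samples, "CFIN", "GOM", years = c(1977, 2009))
fit <- fit_structural(series, seed = 1)
fit
peaks <- annual_peaks(fit)
table(peaks$peak_bin)

grid <- generate_velocity_grid(truth)
transport <- to_bimonthly(path_velocity(grid))
gs <- gsnwi(generate_northwall(truth))
association_suite(peaks, transport, gs)
```

Or end to end, writing every stage to disk with a manifest:

```{r pipeline, eval = FALSE}
run_pipeline(default_config(seed = 1, outdir = "run1"), verbose = TRUE)
```

## Known limitations

* Single-series fits only: no multivariate or hierarchical coupling across
  regions, no stochastic-seasonal variant, no non-Gaussian observation
  families.
* The estimator assumes Gaussian observation noise on the raw scale while
  the generator (and reality) produce skewed, truncated values; the recovery
  experiments quantify the practical effect at the default truth only.
* OLS p-values on bi-monthly series ignore autocorrelation.
* Real EcoMon/AVISO/north-wall downloads are out of scope; the readers
  (`read_samples_csv()`, long-format velocity CSV, north-wall CSV) define
  the adapter surface for supplying real data.
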