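# shelfcope

Structural time-series analysis of Northeast U.S. continental-shelf copepod
populations (*Calanus finmarchicus*, *Centropages typicus*) and the physical
forcing used to interpret them.

Shelf-wide bongo surveys sample each sub-region — Gulf of Maine (GOM),
Georges Bank (GB), Southern New England (SNE), Mid-Atlantic Bight (MAB) — a
handful of times per year, with a 1989–1991 gap in the south. `shelfcope`
turns those station tables into bi-monthly regional abundance series and
separates each series into interpretable components:

```
y_t = mu_t + gamma_t + eps_t,        mu_t = phi * mu_(t-1) + eta_t
```

where `mu_t` is an autocorrelated local trend (`phi` in (0,1]; `phi = 1` is
a random walk), `gamma_t` a deterministic trigonometric seasonal with a
12-month period (6 bi-monthly steps: sine/cosine pairs at harmonics 1–2 plus
the Nyquist cosine), and `eta_t`, `eps_t` independent Gaussian errors.
Estimation is exact maximum likelihood via a Kalman filter with diffuse
initialization of the trend origin and the five seasonal coefficients
(profiled out by GLS inside the filter), full missing-data support, and a
fixed-interval smoother for the components. From the fitted series the
package extracts annual peak abundance and peak timing and cross-tabulates
peak bins by era to detect phenology shifts.

On the physical side it builds:

* an **alongshore transport index** — on the 1/3° velocity-grid row nearest
  39.3°N, the first 6 ocean cells within 2° of the coast are taken, the 2
  nearest the coast discarded, and the weekly mean northward component of
  the remaining 4 is aggregated to bi-monthly means and annual cumulative
  northward/southward components;
* a **Gulf Stream North Wall Index (GSNWI)** — the first-principal-component
  weighted average of the six standardized north-wall latitude series (79,
  75, 72, 70, 67, 65°W), weights rescaled to sum to one;
* an **association table** — OLS regressions of annual peak abundance on
  transport, GSNWI and regional temperature, plus velocity~GSNWI at
  bi-monthly and annual scales, returned unfiltered.

A synthetic-data module (`synthetic_truth()`, `generate_abundance()`,
`generate_velocity_grid()`, `generate_northwall()`) generates the whole
survey world with known ground truth — bi-monthly cruises, the southern gap,
north–south seasonal amplitude gradients, a controlled peak-timing shift,
and a negative GSNWI–velocity coupling — so every stage is verifiable at
desk scale.

## Worked example

```r
library(shelfcope)

truth   <- synthetic_truth(seed = 1)                      # ground-truth world
samples <- generate_abundance(truth)                      # 9072 station rows
series  <- build_series(samples, "CFIN", "GOM", years = c(1977, 2009))
fit     <- fit_structural(series, seed = 1)
fit
#> Structural time-series fit (full)
#>   series: CFIN / GOM
#>   phi = 0.9997  sigma2_eta = 28.956  sigma2_eps = 128.977
#>   loglik = -796.961 on 198 observed bins; converged: TRUE
#>   seasonal coefficients:
#>       a1       b1       a2       b2       a3
#> -198.964    0.141   -0.839   -0.327   -0.130
```

The GOM series has the full 198 bi-monthly points (33 years x 6 bins). The
trend is nearly a random walk (`phi` ≈ 1) with innovation variance ~29; the
first-harmonic cosine coefficient ≈ −199 places the seasonal peak in bin 3
(May–Jun) with amplitude ≈ 200 ind m⁻³ — the generator's GOM truth. Peak
timing is stable:

```r
table(annual_peaks(fit)$peak_bin)
#>  3
#> 33
```

every year peaks in May–Jun. The forcing side, and its association with the
north-wall index:

```r
grid      <- generate_velocity_grid(truth)
transport <- to_bimonthly(path_velocity(grid))
gs        <- gsnwi(generate_northwall(truth))
assoc     <- association_suite(annual_peaks(fit), transport, gs)
subset(assoc, response == "alongshore_velocity")
#>   covariate timescale   n slope      r  p_value
#> 1     gsnwi bimonthly 108 -2.10 -0.766 4.76e-22
#> 2     gsnwi    annual  18 -2.34 -0.761 2.45e-04
```

The alongshore flow is southward on average and more southward when the
north wall sits south (negative slope at both timescales — the generator's
coupling is −1.5 cm s⁻¹ per index unit, attenuated by noise).

The whole chain — simulate, bin, fit, peaks, forcing, associations — runs
from one config with on-disk outputs and a manifest:

```r
run_pipeline(default_config(seed = 1, outdir = "run1"), verbose = TRUE)
```

(`inst/scripts/run_pipeline.R` wraps this for the shell.)

## Scope notes

Real EcoMon / AVISO / north-wall downloads are out of scope; the CSV readers
define the adapter surface for real data. See the vignette
(`vignettes/structural-decomposition.Rmd`) for the model details, estimation
choices (diffuse augmentation, boundary probes, convergence policy), binning
conventions, generator design, and known limitations.
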