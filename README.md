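# crmacro

Consumer-resource models of microbiota macroecology: simulate, measure, and
fit the statistical regularities of species-abundance time series.

## The problem

Daily sampling of microbial communities (human gut, saliva, vagina, mouse
gut, plant-associated soil) yields relative-abundance time series with
striking shared statistics: each taxon's temporal variance scales as a
power of its mean (Taylor's law, variance $\propto \text{mean}^\beta$ with
$\beta \approx 1.5{-}2$), log abundance changes pool into roughly
exponential distributions, log abundances revert to taxon-specific means,
and the durations of presence and absence runs follow power laws with
exponential cutoffs. `crmacro` is for ecologists and modelers who want to
ask: *can plain resource competition, with randomly drawn metabolic
capabilities, quantitatively produce all of this — and which effective
parameters of competition does a given dataset imply?*

## The model

$N$ consumers compete for $M$ coarse-grained resources within each growth
cycle,

$$\frac{dX_i}{dt} = X_i \sum_j R_{ij} Y_j, \qquad
  \frac{dY_j}{dt} = -Y_j \sum_i R_{ij} X_i,$$

with consumption rates drawn once per community from a sparse random
ensemble: $R_{ij} \sim \mathrm{U}(0, R_{\max})$, zeroed with probability
$S$. Each sampling time runs a serial-dilution process (grow to depletion,
dilute by $D = 200$, replenish; seeded from an equal-abundance reservoir)
to an approximate ecological steady state. Between sampling times the
resource supplies follow a biased random walk
$Y_{j,0}(T) = |Y_{j,0}(T{-}1) - k (Y_{j,0}(T{-}1) - \bar{Y}_j) +
\sigma \bar{Y}_j \xi_j(T)|$, so all temporal variation is environmental.
Four free global parameters — $M$, $S$, $\sigma$, $k$ (with $N$ read off
the data) — are fit to four summary statistics (mean richness
$\bar\alpha$, Taylor exponent $\beta$, SD of log abundance changes
$\sigma_{\Delta l}$, mean restoring slope $\bar{s}$) by exhaustive grid
search; everything else the model reproduces is parameter-free. Global
susceptibilities $C(z, w)$ quantify which parameter dominates which
statistic. Comparison models (no-competition limits, Monod saturation, a
metabolic trade-off, converted and random generalized Lotka-Volterra, and
a non-interacting null) share the same statistics pipeline. See the
vignette `vignettes/consumer-resource-macroecology.Rmd` for the full
account.

## Worked example

```r
library(crmacro)

params <- cr_params(N = 50, M = 30, S = 0.1, sigma = 0.2, k = 0.8, T = 300)
series <- simulate_timeseries(params, seed = 1)
series
#> Relative-abundance time series: 50 taxa x 300 sampling times
#>   detection threshold 0.0001; 29.5% of entries present
#>   model variant: linear

summary_stats(series, pools = FALSE)
#> Macroecological summary statistics
#>   mean richness        alpha_bar = 14.7
#>   Taylor exponent      beta      = 1.46
#>   SD of log10 changes  sigma_dl  = 0.352
#>   mean restoring slope s_bar     = -0.883
```

For this instance of the best-fit human-gut ensemble the model produces
about 15 detectable families per day, Taylor scaling near $\beta = 1.5$,
abundance changes with $\sigma_{\Delta l} \approx 0.35$ decades, and a
mean restoring slope close to $-k$: resource-supply fluctuations with ~20%
amplitude and a strong restoring force reproduce the day-to-day statistics
of a human gut series. `mean(series$meta$n_dilutions)` is 5.0 for this
instance (the ensemble mean is close to 6) — each sampling interval
settles within a handful of dilution events, roughly 40 generations.

To fit data, build a scan and minimize the normalized error:

```r
scan <- scan_grid(params,
                  axes = list(M = c(10, 30, 100, 250),
                              S = c(0.1, 0.35, 0.65, 0.9),
                              sigma = c(0.05, 0.2, 0.35, 0.5),
                              k = c(0.1, 0.4, 0.7, 1.0)),
                  n_instances = 1, seed = 2)
fit <- best_fit(scan, summary_stats(series, pools = FALSE))
global_susceptibility(scan, "s_bar", "k")
```

A thin command-line wrapper with `simulate`, `stats`, `shuffle`,
`aggregate`, `scan`, and `fit` subcommands is installed at
`inst/cli/crmacro`.

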