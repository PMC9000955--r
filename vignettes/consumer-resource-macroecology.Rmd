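---
title: "Consumer-resource models of microbiota macroecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-resource models of microbiota macroecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmacro)
```

## The model

Longitudinal 16S or metagenomic surveys of microbial communities show
recurring statistical regularities: temporal variance scaling as a power of
mean abundance (Taylor's law), approximately exponential distributions of
log abundance changes, mean-reverting log abundances, and heavy-tailed
residence and return times of presence and absence. `crmacro` implements a
coarse-grained consumer-resource (CR) explanation of these patterns and the
machinery to fit it to data.

$N$ consumers compete for $M$ coarse-grained resources within a growth
cycle:

$$\frac{dX_i}{dt} = X_i \sum_{j=1}^{M} R_{ij} Y_j, \qquad
  \frac{dY_j}{dt} = -Y_j \sum_{i=1}^{N} R_{ij} X_i,$$

where $X_i$ is the abundance of consumer $i$, $Y_j$ the amount of resource
$j$, and $R_{ij}$ the consumption rate. Growth and consumption are coupled
one-to-one, so $\sum_i X_i + \sum_j Y_j$ is conserved within a cycle — the
central invariant our tests verify to $10^{-6}$ relative accuracy.

Rather than specifying $N \times M$ rates, the rates are drawn from a
statistical ensemble: $R_{ij}$ uniform on $[0, R_{\max}]$, then set to zero
with probability $S$, the *sparsity* of resource competition. Resource set
points $\bar{Y}_j$ are uniform on $[0, Y_{\max}]$. Because only relative
abundances at ecological steady state are analyzed, the absolute scales
$R_{\max}$ and $Y_{\max}$ drop out (a property we test by joint rescaling);
both default to 1.

### Serial dilution and the approximate ecological steady state

Each sampling time $T$ receives a resource supply $Y_{j,0}(T)$ and is run
as a serial-dilution experiment: a batch grows until every resource is
depleted, all consumers are diluted by $D = 200$, resources are replenished,
and the cycle repeats. The first cycle of every sampling interval is seeded
from a reservoir: all $N$ consumers at equal abundance with total
$\sum_j Y_{j,0} / (D - 1)$. This inoculum makes the serial-dilution fixed
point self-consistent — a surviving consumer's within-cycle growth ratio is
exactly $D$ at the fixed point — and its relative size is exposed as the
`reservoir` option because community composition does depend on the
reservoir's existence and scale.

The interval ends at an *approximate* ecological steady state: when every
consumer's growth ratio changes by less than `steady_frac` $\times D$
(default 5%) between successive cycles. Exact steady state (every consumer
extinct or growing by exactly $D$) can take hundreds of cycles because of
slow paths to extinction; the 5% criterion ends intervals after about 6
dilution events, i.e. roughly $6 \log_2 200 \approx 46$ doublings, at the
default parameters. We count *dilution events* (cycles minus one, since the
first cycle is seeded rather than diluted) and accumulate generations as
$\log_2$ of the community growth ratio over the dilution-initiated cycles.
Relative abundances $x_i(T)$ are read from the final pre-dilution state.

### Fluctuating resource supplies

All temporal variation enters through the supplies, which follow a biased
random walk around the set points:

$$Y_{j,0}(T) = \left| Y_{j,0}(T-1) - k\,(Y_{j,0}(T-1) - \bar{Y}_j)
  + \sigma \bar{Y}_j \xi_j(T) \right|,$$

with independent standard-normal $\xi_j(T)$. $\sigma$ sets the fluctuation
magnitude (as a fraction of the set point) and $k \in [0, 1]$ the restoring
force: $k = 1$ is memoryless fluctuation about $\bar{Y}_j$, $k = 0$ an
unbiased random walk. The absolute value enforces positivity and is applied
once per step, matching the literal update rule rather than a multi-fold
reflecting boundary. The chain's initial condition is not part of the model
definition; we start at $\bar{Y}$ and discard a 50-step burn-in so recorded
supplies are stationary (for $k$ not extremely small).

The five global parameters are therefore $N$, $M$, $S$, $\sigma$, $k$; $N$
is estimated from data as the number of taxa ever observed above the
detection threshold, leaving four free parameters.

## Statistics

All statistics apply a detection threshold of $10^{-4}$ relative abundance:
entries below it count as absences. `summary_stats()` computes:

* **Richness** $\alpha(T)$: taxa present at each sampling time.
* **Taylor's law**: OLS slope $\beta$ of $\log_{10}$ temporal variance on
  $\log_{10}$ temporal mean across taxa. Below-detection abundances count
  as 0 in the moments by default; a `mask_absent` mode restricting moments
  to presence times is provided, because the pooling rule is a genuine
  convention choice and it shifts $\beta$.
* **Abundance changes** $\Delta l = \log_{10} x(T+1)/x(T)$ pooled over taxa
  and times, restricted to pairs with both endpoints present. We report the
  pool's standard deviation $\sigma_{\Delta l}$, and separately a Laplace
  (two-sided exponential) maximum-likelihood scale — the mean absolute
  deviation from the median — for the fitted reference curve.
* **Restoring slopes** $s_i$: per-taxon OLS slope of $\Delta l$ on
  $\log_{10} x$, requiring at least 10 presence pairs. With memoryless
  supplies ($k = 1$), $s_i \to -1$; generally $-\bar{s}$ tracks $k$.
* **Residence and return times**: lengths of maximal presence/absence runs.
  Only interior runs — bounded by a transition on both sides — are pooled;
  boundary-censored runs are dropped rather than double-counting the
  finite-window correction that the exponential cutoff in the fitted law
  already absorbs. Interval distributions are fit by discrete maximum
  likelihood to $P(t) \propto t^{\nu} e^{-t/\tau}$ (binned least squares is
  deliberately avoided at the small samples typical of single series).
* **Prevalence, rank abundance, pairwise correlations** (Pearson, over
  shared-presence times, pairs with at least 10 shared times).

Simulated and loaded experimental tables flow through the identical code
path, so model-data comparisons are like for like.

## Fitting and susceptibilities

Fitting is an exhaustive grid scan, not gradient-based optimization: four
statistics ($\bar\alpha$, $\beta$, $\sigma_{\Delta l}$, $\bar{s}$) against
four parameters ($M$, $S$, $\sigma$, $k$). The fit error sums
$|z_{\text{model}} - z_{\text{data}}|$ over the four statistics, each
normalized by the SD of that statistic across the whole scan table — the
same normalization used by the susceptibilities, so one scan serves both
purposes. Estimation bounds extend along each axis through the best point,
piecewise-linearly interpolated, until the error exceeds the minimum by 5%
of the scan-mean error.

The global susceptibility $C(z, w)$ is the endpoint change in $z$ as $w$
goes from its smallest to largest scanned value, averaged over all
combinations of the other parameters, normalized by the scan-wide SD of
$z$; for the resource axis, $w = N/M$, so its largest value corresponds to
the smallest $M$. We use endpoint differences rather than a regression
across levels — the simplest reading consistent with the $\pm 3$ bound that
the normalization implies. A local variant fixes the other parameters at
their best-fit values instead of averaging. Note that $|C|$ depends mildly
on the grid design: with 4 evenly spaced levels per axis the level SD is
about 1.17 times that of a 9-10-level axis, deflating $|C|$ by roughly 15%
relative to a dense scan; the package's coarse-scan defaults (4 levels per
axis, spanning $M \in [10, 250]$, $S \in [0.1, 0.9]$,
$\sigma \in [0.05, 0.5]$, $k \in [0.1, 1]$) reproduce the dense-scan
couplings up to that factor.

## Comparison models

* **Trade-off variant**: row $i$ of the consumption matrix is rescaled so
  its rate sum equals a capacity resampled from the original growth rates
  $\sum_j R_{ij} \bar{Y}_j$, removing the correlation between growth rate
  and resource-set size while preserving fitness variation. Capacities are
  resampled *with* replacement (the alternative is unspecified in the
  underlying construction; with replacement keeps instances i.i.d.).
* **Saturation kinetics**: every uptake term gains a Monod factor
  $Y_j / (Y_s + Y_j)$, with a single saturation constant
  $Y_s = \overline{\bar{Y}_j} / 3$ shared across resources. A per-resource
  $Y_s = Y_{j,0}/3$ reading exists but conflicts with sharing a single
  constant; the mean-based reading honors both clauses.
* **No-competition limits**: disjoint resource sets per consumer. With one
  unique resource each, steady-state abundance tracks a single supply and
  $\beta = 2$ follows directly from the supply noise; with large equal
  disjoint sets and uniform set points, the ratio of between-consumer
  covariances gives $\beta = 3/2$ analytically
  ($\mathrm{Cov}(\bar Y^2, \bar Y)\,\bar m / (\overline{\bar Y^2}\,
  \mathrm{Var}\,\bar m) = 3/2$ for uniform $\bar Y$), which the simulations
  reproduce. Resources assigned to no consumer are inert and are excluded
  from the simulated environment; correspondingly the depletion criterion
  in the pipeline treats a resource consumed by nobody ($dY_j/dt \equiv 0$)
  as settled, which also covers sparse ensembles where a zero consumption
  column arises by chance.
* **Lotka-Volterra correspondence**: near-uniform consumption rates map the
  CR model onto a normalized gLV model with $r_i = 2 \sum_j R_{ij} Y_{j,0}$
  and interactions of magnitude
  $\frac{1}{R_{\max}} \sum_k R_{ik} R_{jk} Y_{k,0}$. The interaction matrix
  is assigned the negative sign: the replicator-form dynamics add
  $+\sum_j A_{ij} X_j$, and the coefficients describe competition, so
  negativity and the printed magnitude formula are reconciled by
  $A = -|A|$. Supply fluctuations propagate into $r$ and $A$ across
  sampling times. Each sampling time integrates from equal abundances for a
  fixed duration calibrated so the 10th-90th percentile spread of
  $\log_{10}$ abundance matches the CR steady state on a calibration
  instance (the calibration rule is a package choice; the duration is the
  only free quantity in the correspondence). A moment-matched *random* gLV
  ensemble (normal draws with the converted ensemble's means and variances,
  symmetrized, forced negative) is provided as the contrast case.
* **Non-interacting null**: each taxon redrawn independently at each time
  from a normal with its empirical mean and variance, negative draws
  clipped to zero (the truncation rule is unspecified in the construction;
  clipping treats them as absences). The null preserves marginal moments
  but its pairwise-correlation pool is sharply peaked at zero, unlike the
  CR model's.

## Numerical choices

The batch integrator is an adaptive Dormand-Prince 5(4) pair (relative
tolerance $10^{-8}$, absolute $10^{-10}$) implemented in C++; the dynamics
are non-stiff (monotone resource depletion), and the contract is the
conservation bound, not a particular method. `deSolve`'s `lsoda` serves as
an independent cross-check in the test suite and integrates the gLV
replicator equations. Each resource is clamped to exactly zero once it
falls below $10^{-7}$ times the largest initial supply; without the clamp a
depleted resource keeps decaying exponentially and pins the step size far
below the time scale of the remaining dynamics. A batch ends when every
consumable resource is clamped. Consumer abundances are floored at
$10^{-300}$ when growth ratios are formed, so numerically extinct consumers
cannot produce 0/0 or block convergence.

## What the synthetic benchmarks do and do not show

The generator's defaults are the study conditions: best-fit human-gut
ensemble $(N, M, S, \sigma, k) = (50, 30, 0.1, 0.2, 0.8)$, $D = 200$, 5%
steady-state threshold, $10^{-4}$ detection, and $T = 300$ sampling times
(the order of a year of daily sampling). Replicate counts and problem sizes
used by the test suite and the acceptance script are chosen for desk-scale
reproduction: 20 instances at full length for the headline Taylor exponent;
a 4-level-per-axis scan with 1 instance and $T = 60$ per grid point for
susceptibilities; 2 instances and $T = 150{-}200$ for the shuffle-refit.
Synthetic series share the simulator's idealizations — equally spaced
sampling, no measurement noise, no compositional read-count noise, no true
immigration or extinction, i.i.d. consumption ensembles without phylogenetic
structure. Passing tests therefore demonstrate internal consistency of the
model, statistics, and fitting machinery at the stated conditions, not that
real communities satisfy the model's assumptions.

## Known limitations

* Richness-style statistics assume the detection threshold is meaningful on
  relative abundances; count tables are renormalized on read, and
  sequencing depth is not modeled.
* The no-drift property of the supply walk fails as $k \to 0$ with large
  $\sigma$ (reflection becomes frequent and inflates the mean); the scan
  grids start at $k = 0.1$.
* Power-law-cutoff fits are reported as degenerate when all intervals are
  equal; confidence intervals beyond OLS standard errors are out of scope.
* Irregular sampling gaps and unclassified-taxon handling beyond
  pool-or-drop are out of scope.
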