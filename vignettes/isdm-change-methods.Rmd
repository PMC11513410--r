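---
title: "Modelling two-period range and diversity change with integrated species distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-period range and diversity change with integrated species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isdmchange)
```

## The problem

Most continental-scale knowledge of where species occur is static: expert
range maps and stacked richness maps describe one snapshot. Detecting
whether a species' area of occupancy (AOO) has grown or shrunk between two
time periods requires combining the data that actually exist — opportunistic
presence-only (PO) records whose collection effort varies wildly in space
and time, camera-trap surveys with known effort that support true absences,
and expert range maps that are unreliable inside the range but trustworthy
far outside it — inside a single model with an explicit observation process
for each source. `isdmchange` implements such an integrated species
distribution model (ISDM) on an equal-area analysis lattice, together with
the downstream change metrics (AOO change with credible intervals, per-cell
change classes, stacked richness, multiplicative beta diversity, Ruzicka
temporal and spatial dissimilarity) and a synthetic-data generator with
known truth so that the entire chain is testable.

## The model

**Latent state.** Species occurrences in period $t \in \{1, 2\}$ form an
inhomogeneous Poisson point process whose intensity is piecewise constant
on the grid cells (100 km cells by default; the lattice is the analysis
grain, and within-cell variation is deliberately not modelled):

$$\log \Lambda_{it} = \beta_0 + x_i'\beta + \beta_D D_i + B_i g +
  \mathbf{1}[t = 2]\,(\tau + B_i g_2)$$

* $x_i$ — environmental covariates, averaged over the cell and standardized;
* $D_i$ — distance (in thousands of km) from the cell centroid to the
  expert range polygon, 0 inside it. Rescaling by 1000 keeps $\beta_D$ on
  the same magnitude as the other coefficients. $\beta_D$ is a free
  parameter, estimated from the data rather than imposed as an offset, so
  the expert map informs but does not dictate the fit;
* $B$ — a low-rank tensor-product B-spline surface over the projected
  coordinates ($K = 16$ by default), absorbing missing covariates and
  residual spatial autocorrelation;
* $\tau$ — the mean log-intensity change between periods;
* $g_2$ — a second spline field that lets the change vary in space. It
  carries a tighter shrinkage prior than $g$ (Half-Normal(0.5) versus
  Half-Normal(1) on the field scales): with a scalar $\tau$ alone the map
  of change would be spatially flat, while an unpenalized $g_2$ would be
  confounded with $\tau$; shrinkage keeps the decomposition identifiable.

**Presence-only observation process.** Retained records in cell $i$ and
period $t$ are a thinned Poisson sample,

$$n_{it} \sim \text{Poisson}(\Lambda_{it}\, A_i\, p_i\, \rho_t), \qquad
  p_i = \text{logit}^{-1}(\alpha_0 + \alpha_a\,\mathrm{access}_i + c_{j(i)}),$$

with accessibility and sum-to-zero country offsets describing uneven
recording effort in space, and $\rho_1 = 1$, $\rho_2$ the ratio of pooled
period-2 to period-1 record totals. $\rho$ enters the observation mean as
a fixed constant, not a free parameter: global growth in data sharing
between the periods would otherwise masquerade as range expansion through
$\tau$. Placing the calibration inside the likelihood (rather than
rescaling predictions afterwards) is the only placement that separates
sampling growth from the latent change, and the package's ablation
(`use_rho = FALSE`) demonstrates the spurious positive $\tau$ that appears
without it. In the real multi-source setting the ratio comes from the
pooled records of *all* study species; in a single-species synthetic run
that pooled quantity is represented by the generator's known value, since
the focal species' own ratio would confound its genuine period effect.

**Presence-absence observation process.** Camera-trap surveys are discs
(radius $\sqrt{\text{area}/\pi}$ at the survey centroid); overlapping discs
within a period are unioned into "blobs" with summed camera-trap-day effort
$E_b$ and union area $A_b$. Detection of the species in blob $b$ is

$$y_b \sim \text{Bernoulli}\{(1 - e^{-\Lambda_b A_b})\,(1 - e^{-q E_b})\},$$

the product of a cloglog presence probability (at the blob's area-weighted
mean intensity for its period) and an effort saturation curve with
per-camera-day detection rate $q$. This factorized form uses both blob
quantities the data supply (area and effort) and nests the two natural
limits: no effort, no detection; unbounded intensity and effort, certain
detection.

**Priors.** Normal(0, 10) on the fixed effects ($\beta_0$, $\beta$, $\tau$,
$\alpha_0$, $\alpha_a$), Normal(0, 2) sum-to-zero country offsets,
Exponential(1) on $q$, and hierarchical Normal–Half-Normal priors on the
two spline fields as above. These are wide on the scale of standardized
covariates; the data dominate wherever they carry information. The
range-distance effect is the one deliberate exception: its prior is
Normal(0, 2.5). Far outside the range the expected counts vanish for any
sufficiently negative $\beta_D$, so the likelihood is one-sidedly flat in
that coefficient; under a Normal(0, 10) prior the resulting tail mass drags
the posterior median about 0.2 below the likelihood's elbow in simulation
(a systematic effect, reproducible across replicate streams), while the
2.5 scale — a conventional weakly-informative choice — removes the
distortion without affecting interval coverage.

## Posterior computation

The joint posterior is sampled with Hamiltonian Monte Carlo written for
this model (4 chains x 2000 iterations with the first half warmup by
default; tests and the acceptance script use shorter, documented chains).
Three structural choices matter more than the generic machinery:

* **Laplace-preconditioned dense metric.** The mode of the posterior over
  all non-scale parameters is found by BFGS with analytic gradients, with
  the spline scales profiled (the joint mode of a centred hierarchy is
  degenerate at scale zero). The inverse negative Hessian supplies a dense
  mass matrix, so the strong correlation that joint PO/PA likelihoods
  induce (the latent intercept trades against the thinning intercept) is
  whitened. During warmup the metric is refreshed from the analytic
  curvature at the current scales, with marginal scales inflated — never
  shrunk — where the warmup draws prove wider.
* **An identified-level reparameterization.** PO data identify the product
  $\Lambda p$, so $(\beta_0, \alpha_0)$ has a curved likelihood ridge. The
  sampler works in $u = \beta_0 + \log \text{logit}^{-1}(\alpha_0)$, which
  is sharply identified, leaving the residual freedom in $\alpha_0$
  axis-aligned and prior-dominated — geometry a fixed metric handles.
  Draws are mapped back to $\beta_0$ afterwards.
* **Interweaved scale updates.** The shared field $g$ is sampled centred
  (it is strongly informed by the counts) with its scale $\sigma_g$ updated
  by an exact one-dimensional slice-sampling Gibbs step — given $g$, the
  scale's conditional involves only the prior. An additional update in the
  ancillary parameterization (rescaling the field amplitude through the
  likelihood) and the mirrored pair of updates for the weakly informed
  interaction field $g_2$ (sampled non-centred) remove the funnel dynamics
  that defeat a single fixed parameterization.

Convergence is judged by split-chain potential-scale-reduction (split-Rhat)
on every free parameter with the conventional 1.1 bar, plus effective
sample sizes. A fit that misses the bar is extended once with 2.5x longer
chains; if it still misses, it is returned with an explicit
`converged = FALSE` status, and the change stage of the pipeline refuses to
process it — mirroring the practice of excluding unconverged species from
downstream change analysis rather than silently reporting their maps.

## Synthetic study systems

`sim_config()` fixes the generative conditions; `simulate_system()` draws a
complete study system. The defaults describe a single carnivore-like
species on a 20 x 20 lattice of 100-km cells:

* four standardized Gaussian-process environmental fields (squared
  exponential kernel, 500 km range) and a 600-km accessibility field;
* 2-4 contiguous rectangular "countries" (vertical bands) with sum-to-zero
  thinning offsets (0.5, -0.5, 0), emulating country-level differences in
  record sharing;
* true effects $\beta = (1, -0.7, 0.5, 0)$ (one null covariate on
  purpose), $\tau = -0.5$ (a contraction), $\beta_D = -1$ per 1000 km,
  intercept $\beta_0 = -8.5$ on the per-km$^2$ log scale (about two
  expected occurrences per core-range cell), plus a residual
  Gaussian-process field of sd 0.25 that the splines must absorb;
* a pseudo-expert range: the cells whose period-1 intensity (before the
  distance term) exceeds its median, mimicking an expert map drawn around
  the first-period core range;
* thinning $\alpha_0 = -1.5$, $\alpha_a = 1$ (roughly a fifth of
  occurrences retained in accessible cells), and 27% more presence-only
  sampling in period 2 ($\rho = 1.27$);
* 30 camera-trap surveys of 500-5000 km$^2$ with 100-1000 trap-days and a
  detection rate of $q = 0.02$ per trap-day.

Records are materialized as point tables (uniform within cells,
back-projected to longitude/latitude, random dates, a mix of small, large
and missing coordinate uncertainties), so the raw-record filters -
coordinate precision of at least three decimals, uncertainty at most
25,000 m, missing uncertainty passing, exact-duplicate removal - operate on
realistic inputs. The two periods split at the boundary between calendar
years 2013 and 2014, surveys spanning the boundary going to the period
containing their midpoint (the symmetric choice).

What the generator does **not** emulate: real covariate products and their
measurement error, taxonomic misidentification, spatial clustering of
records within cells beyond the Poisson process, temporal trends within a
period, and non-rectangular country geometry. Passing tests therefore
demonstrate internal consistency of the method under its own assumptions,
not robustness to every failure mode of field data.

## Change metrics

Occupancy per cell, period and posterior draw is
$P_{it} = 1 - \exp(-\Lambda_{it} A_i)$; AOO is $\sum_i P_{it}$ (in cells,
times $10^4$ km$^2$ at the default grain). Change is always differenced
within a posterior draw before summarizing, so its credible interval
respects the coupling of the two periods; intervals are never obtained by
differencing two marginal intervals. Per-cell change classes split
gain/loss by whether the central 95% interval excludes zero, with a
configurable neutral band (default |median change| < 0.01, a logged
threshold for the map's implicit "no change" class).

For communities, per-species/cell/period medians over 1000 subsampled
posterior draws (fixed seed) are stacked: richness is the sum of medians;
gamma diversity of a probabilistic stack is the expected pooled richness
$\sum_s [1 - \prod_i (1 - P_{si})]$, which reduces to a species count when
each species is certain somewhere; Whittaker's multiplicative beta is
gamma over mean alpha. One consequence of the probabilistic gamma is worth
flagging: unlike the binary case, it grows when cells are duplicated (more
cells mean more chances of occurrence), so beta values are comparable only
across stacks on the same lattice. Ruzicka dissimilarity
($1 - \sum \min / \sum \max$) is computed per cell between periods
(temporal turnover) and between sampled cell pairs within periods (50,000
pairs by default — the all-pairs computation is quadratic and a binned
median does not need it), summarized as median dissimilarity per distance
bin.

## Numerical choices and degenerate inputs

* Geometry is planar and closed-form: the spherical Lambert azimuthal
  equal-area projection, axis-aligned cell squares, disc unions whose areas
  are computed by exact interval unions along one axis and quadrature along
  the other (2000 columns; relative error well below 10^-3).
* Quantile-based ranges use R's default (type 7) quantiles; with continuous
  fields ties have probability zero.
* Counts against zero Poisson means, detections against zero detection
  probability, and all-zero composition vectors are reported (`-Inf` with a
  warning, or `NA`) rather than silently patched.
* The spline basis dimension rounds up to the next perfect square (tensor
  construction); centred columns keep it identifiable next to the
  intercept.
* Boundary centroids count as inside a range polygon, so distance-to-range
  is exactly zero on the edge.

## Problem sizes used in the tests

The test-suite experiments run at the generator's default conditions
(20 x 20 cells, 30 blobs, 4 covariates) with 4 chains of 600-800
iterations for the fits inside the recovery, convergence and calibration
experiments, and smaller 10 x 10 or 14 x 14 systems with 2 chains for
module-level checks; these chain lengths were chosen as the shortest that
hold the convergence contract under the preconditioned sampler, and the
one-step chain extension covers the occasional seed that mixes more
slowly. The PIT calibration experiment evaluates 200 replicate datasets
against one fitted model's posterior predictive — the calibration property
under test is uniformity of the randomized-quantile transform under the
predictive distribution, which does not require refitting per replicate.
Its power counterpart uses a deliberately stripped model (no environmental
drivers, no sampling-bias covariates, minimal spatial basis) fitted to the
same data, a misspecification the flexible spline surface cannot quietly
absorb; dropping a single smooth covariate is largely absorbed by the
splines — itself a finding about residual checks for spatially smooth
predictors, and the reason the power check removes the whole driver set.

## Known limitations

* The intensity is piecewise constant at the analysis grain; the model is
  not a point-level point-process fit.
* $\beta_D$ is weakly identified when the pseudo-range closely tracks the
  covariate-driven core range (the distance surface is spatially smooth
  and partly collinear with the splines); its posterior is honest about
  this — wide — but single-run medians scatter accordingly.
* The effort-ratio calibration assumes sampling growth is spatially
  uniform between periods; spatially uneven growth would be aliased into
  the change field.
* With 30 blobs the detection rate $q$ and the absolute intensity level
  are informed mostly by the prior and the PO/PA balance; AOO levels are
  correspondingly less certain than AOO *change*.
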