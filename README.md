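# isdmchange

Integrated species distribution models (ISDMs) for estimating **two-period
range and diversity change** from heterogeneous evidence: opportunistic
presence-only records, camera-trap presence–absence surveys with known
effort, and expert range maps.

## Who this is for

Macroecologists and conservation scientists who want to ask, at a
continental analysis grain, *has this species' area of occupancy grown or
shrunk between two time periods, where, and with what certainty?* — and,
for a set of species, *how have richness and compositional turnover
changed?* — when the only data available are biased occurrence archives,
scattered camera-trap surveys and a static expert map.

## The model

The latent state is an inhomogeneous Poisson point process with piecewise
constant intensity on an equal-area lattice (Lambert azimuthal equal-area
projection, 100 × 100 km cells by default):

```
log Λ_it = β0 + x_i'β + βD·D_i + B_i·g + 1[t = 2]·(τ + B_i·g2)
```

with environmental covariates `x_i`, distance to the expert range `D_i`
(zero inside it; `βD` estimated, not imposed), a low-rank spatial spline
surface `B g`, a period effect `τ` and a shrunken spatially varying change
field `B g2`. Two observation processes connect the latent state to data:

* presence-only counts are a thinned Poisson sample,
  `n_it ~ Poisson(Λ_it · A_i · p_i · ρ_t)`, with logistic thinning in
  accessibility and country, and a fixed effort-ratio calibration `ρ_2`
  (period-2 over period-1 pooled record totals) that stops global growth
  in recording effort from masquerading as range expansion;
* camera-trap blobs (unions of overlapping survey discs) contribute
  `y_b ~ Bernoulli{(1 − e^(−Λ_b·A_b)) · (1 − e^(−q·E_b))}`, presence times
  effort-dependent detection with per-trap-day rate `q`.

The joint posterior is sampled with a Laplace-preconditioned Hamiltonian
Monte Carlo sampler built for this model (details and the reparameterizations
that make it mix are in the methods vignette,
`vignettes/isdm-change-methods.Rmd`). Convergence is certified by
split-Rhat < 1.1 on every free parameter; unconverged fits are flagged and
refused by the change stage.

From the posterior, the package derives occupancy surfaces
`P_it = 1 − exp(−Λ_it·A_i)`, the area of occupancy `A_t = Σ_i P_it` (so
14.6 cells at the 100-km grain is 146,000 km²), its change `ΔA` with 95%
credible intervals computed within posterior draws, per-cell change classes
(certain/uncertain gain/loss split by whether the interval excludes zero),
stacked species richness from 1000 posterior samples per species,
Whittaker's multiplicative beta diversity `β = γ / ᾱ` with `γ` the expected
pooled richness, and Růžička dissimilarity `1 − Σmin/Σmax` between periods
(temporal turnover per cell) and between cell pairs (distance decay).

A synthetic-data module generates complete study systems with known truth —
autocorrelated covariate fields, thinned presence-only records with more
sampling in the second period, merged survey blobs with effort-dependent
detections, and a pseudo-expert range — so every stage, and parameter
recovery end to end, is testable.

## Worked example

```r
library(isdmchange)

cfg  <- sim_config(seed = 1)              # 20 x 20 grid, known truth
sys  <- simulate_system(cfg)
data <- assemble_isdm_data(sys$grid, sys$po$counts, sys$pa$blobs,
                           effort_ratio = cfg$effort_ratio_true,
                           species = cfg$species)
fit  <- fit_isdm(data, model_spec(chains = 4, iter = 800, warmup = 300,
                                  seed = 99))
fit
#> <isdm_fit: 4 chains x 500 draws, 46 parameters>
#>   max Rhat = 1.050 (converged), min ESS = 130, mean accept = 0.94
#>   PA fit: AUC = 0.930, Tjur R2 = 0.434

surf <- occupancy_probability(fit)
area_of_occupancy(surf)
#> <change_summary: dA median -34.5 cells (-345479 km2), 95% CI [-56.5, -20.9] cells>
```

The species was simulated with a period effect of `τ = −0.5`, a true
contraction of −38.3 cells on this realization: the posterior change
interval brackets the truth, and the printed fit line shows the
convergence verdict and the discrimination of the camera-trap detections. `summary(fit)` tabulates the
posterior of each effect next to its Rhat and effective sample size;
`classify_change(area_of_occupancy(surf))` labels each cell for mapping.

For a staged, file-based run (manifests, seeds, per-stage artifacts):

```r
cfg <- pipeline_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)   # simulate > prepare > covariates > fit > diagnose > change
```

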