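# Shared experiment machinery for the acceptance-level checks. Fits are
# memoized so several tests can interrogate the same posterior.

.acc_env <- new.env(parent = emptyenv())

# The default synthetic study system (the generator's stated conditions:
# 20 x 20 cells of 100 km, 4 covariates, 30 blobs) and its model fit with
# 4 chains. Chain length is reduced relative to the production default;
# the one-step extension guards the convergence contract.
default_fit <- function() {
  if (is.null(.acc_env$default_fit)) {
    cfg <- sim_config(seed = 1)
    sys <- simulate_system(cfg)
    data <- assemble_isdm_data(sys$grid, sys$po$counts, sys$pa$blobs,
                               effort_ratio = cfg$effort_ratio_true,
                               species = cfg$species)
    .acc_env$default_sys <- sys
    .acc_env$default_fit <- fit_isdm(
      data, model_spec(chains = 4, iter = 800, warmup = 300, seed = 99))
  }
  .acc_env$default_fit
}

default_sys <- function() {
  default_fit()
  .acc_env$default_sys
}

# One parameter-recovery replicate at the default conditions.
recovery_replicate <- function(seed) {
  cfg <- sim_config(seed = seed)
  sys <- simulate_system(cfg)
  data <- assemble_isdm_data(sys$grid, sys$po$counts, sys$pa$blobs,
                             effort_ratio = cfg$effort_ratio_true,
                             species = cfg$species)
  fit <- fit_isdm(data, model_spec(chains = 4, iter = 600, warmup = 250,
                                   seed = 5000 + seed), retries = 0)
  truth <- c(beta1 = cfg$beta[1], beta2 = cfg$beta[2], beta3 = cfg$beta[3],
             beta4 = cfg$beta[4], tau = cfg$tau, betaD = cfg$beta_dist)
  su <- summary(fit, pars = names(truth))
  list(truth = truth, median = stats::setNames(su$median, su$parameter),
       lower = su$q2.5, upper = su$q97.5, converged = fit$converged)
}

# Randomized-quantile PIT of counts against given Poisson means.
conditional_pit_ks <- function(counts, mu, seed) {
  u <- with_seed_local(seed, {
    v <- stats::runif(length(counts))
    stats::ppois(counts - 1, mu) + v * stats::dpois(counts, mu)
  })
  suppressWarnings(stats::ks.test(u, "punif"))$p.value
}
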