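# Fitting tests use a deliberately small lattice (10 x 10 cells, 12 blobs)
# and short chains so the whole file runs in about a minute.

fit_small <- function(seed_fit = 101, ...) {
  data <- small_isdm_data(small_system(seed = 42))
  fit_isdm(data, model_spec(K = 9, chains = 2, iter = 400, warmup = 150,
                            target_accept = 0.9, seed = seed_fit), ...)
}

test_that("fits are reproducible given the spec seed", {
  f1 <- fit_small()
  f2 <- fit_small()
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$rhat, f2$rhat)
  f3 <- fit_small(seed_fit = 102)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the fit object carries diagnostics for every free parameter", {
  f <- fit_small()
  expect_s3_class(f, "isdm_fit")
  expect_equal(length(f$rhat), length(f$par_names))
  expect_true(all(is.finite(f$rhat)))
  expect_true(is.logical(f$converged))
  s <- summary(f)
  expect_true(all(c("median", "q2.5", "q97.5", "rhat", "ess") %in% names(s)))
  # posterior intensities are positive for every draw and cell
  lam <- posterior_intensity(f, 1)
  expect_true(all(lam > 0))
  expect_equal(dim(lam), c(nrow(f$draws), 100))
  # occupancy stays in [0, 1] for every draw
  surf <- occupancy_probability(f)
  expect_true(all(surf$P$t1 >= 0 & surf$P$t1 <= 1))
  expect_true(all(surf$P$t2 >= 0 & surf$P$t2 <= 1))
})

test_that("posterior predictive PO draws have plausible totals", {
  f <- fit_small()
  pred <- posterior_predict_po(f, n_draws = 200, seed = 9)
  obs_tot <- sum(f$data$po_counts)
  pred_tot <- rowSums(pred$t1) + rowSums(pred$t2)
  # the observed total sits inside the central predictive interval
  expect_gt(obs_tot, quantile(pred_tot, 0.005))
  expect_lt(obs_tot, quantile(pred_tot, 0.995))
  # deterministic given the seed
  pred2 <- posterior_predict_po(f, n_draws = 200, seed = 9)
  expect_identical(pred$t1, pred2$t1)
})

test_that("PA metrics discriminate detections from absences on synthetic data", {
  f <- fit_small()
  if (!is.null(f$pa_metrics)) {
    expect_gt(f$pa_metrics["auc"], 0.5)
    expect_true(abs(f$pa_metrics["tjur_r2"]) <= 1)
  }
  pib <- posterior_pa_prob(f)
  expect_true(all(pib >= 0 & pib <= 1))
})

test_that("posterior means agree with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  sys <- small_system(8, 8, n_blobs = 8, seed = 3)
  data <- small_isdm_data(sys)
  spec <- model_spec(K = 4, chains = 2, iter = 2500, warmup = 750,
                     target_accept = 0.9, seed = 7)
  fit <- fit_isdm(data, spec, retries = 0)
  B <- spline_basis(data$grid$cells[, c("x", "y")], spec$K)
  Bs <- sweep(B, 2, pmax(apply(B, 2, sd), 1e-12), "/")
  model_str <- "
  model {
    beta0 ~ dnorm(0, 0.01); tau ~ dnorm(0, 0.01); betaD ~ dnorm(0, 0.16)
    alpha0 ~ dnorm(0, 0.01); alphaA ~ dnorm(0, 0.01)
    for (k in 1:kc) { beta[k] ~ dnorm(0, 0.01) }
    sg ~ dnorm(0, 1) T(0,)
    sg2 ~ dnorm(0, 4) T(0,)
    for (k in 1:K) { g[k] ~ dnorm(0, 1/(sg*sg)); g2[k] ~ dnorm(0, 1/(sg2*sg2)) }
    for (j in 1:J) { craw[j] ~ dnorm(0, 0.25) }
    for (j in 1:J) { cc[j] <- craw[j] - mean(craw) }
    q ~ dexp(1)
    for (i in 1:N) {
      logit(p[i]) <- alpha0 + alphaA * access[i] + cc[country[i]]
      eta1[i] <- beta0 + inprod(X[i,], beta) + betaD * D[i] + inprod(B[i,], g)
      eta2[i] <- eta1[i] + tau + inprod(B[i,], g2)
      lam1[i] <- exp(eta1[i]); lam2[i] <- exp(eta2[i])
      n1[i] ~ dpois(lam1[i] * A[i] * p[i])
      n2[i] ~ dpois(lam2[i] * A[i] * p[i] * rho)
    }
    for (b in 1:Nb) {
      lamb[b] <- inprod(W[b,], lam1) * (2 - per[b]) +
                 inprod(W[b,], lam2) * (per[b] - 1)
      pib[b] <- (1 - exp(-lamb[b] * Ab[b])) * (1 - exp(-q * Eb[b]))
      y[b] ~ dbern(max(1e-12, min(1 - 1e-12, pib[b])))
    }
  }"
  jd <- list(X = data$X, B = Bs, D = data$D, access = data$access,
             country = data$country, A = data$area,
             n1 = data$po_counts[, 1], n2 = data$po_counts[, 2],
             K = ncol(Bs), kc = ncol(data$X), J = max(data$country),
             N = nrow(data$X), Nb = length(data$blob_y), W = data$blob_W,
             Ab = data$blob_area, Eb = data$blob_effort,
             per = data$blob_period, y = data$blob_y,
             rho = data$effort_ratio)
  jm <- rjags::jags.model(
    textConnection(model_str), data = jd, n.chains = 2, n.adapt = 1000,
    quiet = TRUE,
    inits = list(
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)))
  js <- rjags::coda.samples(jm, c("beta", "tau", "betaD"), n.iter = 4000)
  jsum <- summary(js)$statistics
  ours <- summary(fit)
  for (nm in c("beta1", "beta2", "beta3", "beta4", "tau", "betaD")) {
    jnm <- switch(nm, beta1 = "beta[1]", beta2 = "beta[2]",
                  beta3 = "beta[3]", beta4 = "beta[4]", nm)
    o <- ours[ours$parameter == nm, ]
    # agreement within Monte-Carlo error plus a sixth of the posterior sd
    # (both chains are finite; the check is on the distribution, not on
    # exact numerics)
    tol <- 3 * sqrt(jsum[jnm, "Time-series SE"]^2 + (o$sd / sqrt(o$ess))^2) +
      0.15 * jsum[jnm, "SD"]
    expect_lt(abs(o$mean - jsum[jnm, "Mean"]), max(tol, 0.1))
    expect_equal(o$sd, unname(jsum[jnm, "SD"]), tolerance = 0.5)
  }
})

test_that("dropping the effort-ratio term shifts the period effect as expected", {
  # identical latent state across periods, rho = 1.27 of extra sampling: a
  # model without the calibration reads the sampling growth as tau > 0
  cfg <- sim_config(grid_nx = 10, grid_ny = 10, tau = 0, n_blobs = 12,
                    seed = 55)
  sys <- simulate_system(cfg)
  data <- assemble_isdm_data(sys$grid, sys$po$counts, sys$pa$blobs,
                             effort_ratio = cfg$effort_ratio_true,
                             species = cfg$species)
  spec <- model_spec(K = 9, chains = 2, iter = 500, warmup = 200,
                     target_accept = 0.9, seed = 31)
  tau_with <- median(fit_isdm(data, spec, retries = 0)$draws[, "tau"])
  tau_without <- median(fit_isdm(data, spec, use_rho = FALSE,
                                 retries = 0)$draws[, "tau"])
  expect_gt(tau_without, tau_with)
})
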