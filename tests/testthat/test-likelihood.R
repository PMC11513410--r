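test_that("the spline basis is deterministic, centred and complete enough", {
  set.seed(3)
  coords <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
  B1 <- spline_basis(coords, 16)
  B2 <- spline_basis(coords, 16)
  expect_identical(B1, B2)
  expect_equal(ncol(B1), 16)
  expect_true(all(abs(colMeans(B1)) < 1e-12))
  # a constant is exactly representable by [1, B]
  fit_const <- lm.fit(cbind(1, B1), rep(2.5, 100))
  expect_lt(max(abs(fit_const$residuals)), 1e-9)
  # a linear surface z = x + y is reproduced when K >= 16
  z <- coords[, 1] + coords[, 2]
  fit_lin <- lm.fit(cbind(1, B1), z)
  expect_lt(max(abs(fit_lin$residuals)), 1e-6)
  expect_error(spline_basis(coords, 3), "at least 4")
  # K rounds up to the next perfect square
  expect_equal(ncol(spline_basis(coords, 10)), 16)
  # evaluation at the original coordinates reproduces the basis
  expect_equal(spline_basis_eval(B1, coords), unclass(B1)[, ],
               ignore_attr = TRUE)
})

test_that("log intensity follows its closed forms and monotonicity", {
  n <- 20
  set.seed(5)
  X <- matrix(rnorm(n * 2), n); B <- matrix(rnorm(n * 4), n)
  D <- runif(n)
  p0 <- list(beta0 = 0, beta = c(0, 0), tau = 0, betaD = 0,
             g = rep(0, 4), g2 = rep(0, 4))
  expect_equal(log_intensity(p0, X, D, B, 1), rep(1, n))
  p1 <- p0; p1$beta0 <- log(2)
  expect_equal(log_intensity(p1, X, D, B, 2), rep(2, n))
  # negative distance effect lowers intensity wherever D > 0
  p2 <- p0; p2$betaD <- -1
  lam <- log_intensity(p2, X, D, B, 1)
  expect_true(all(lam[D > 0] < 1))
  expect_equal(lam[D == 0], rep(1, sum(D == 0)))
  p_bad <- p0; p_bad$beta0 <- NaN
  expect_error(log_intensity(p_bad, X, D, B, 1), "non-finite")
})

test_that("presence-only log likelihood matches Poisson identities", {
  n <- matrix(c(0L, 1L), 1, 2)
  lam <- matrix(c(0, 1), 1, 2)
  # n = 0 with mu = 0 contributes log(1) = 0; n = 1 with mu = 1 gives -1
  expect_equal(po_loglik(n, lam, area = 1, p = c(1, 1), rho = 1), -1)
  # doubling rho changes the log likelihood by n log 2 - mu per cell
  n2 <- matrix(rpois(20, 2), 10, 2)
  lam2 <- matrix(runif(20, 0.5, 2), 10, 2)
  p <- runif(10, 0.2, 0.8)
  ll1 <- po_loglik(n2, lam2, 1, p, rho = 1)
  ll2 <- po_loglik(n2, lam2, 1, p, rho = 2)
  mu2 <- lam2[, 2] * p
  expect_equal(ll2 - ll1, sum(n2[, 2]) * log(2) - sum(mu2), tolerance = 1e-9)
  # a zero mean facing a positive count is flagged as impossible
  expect_warning(ll0 <- po_loglik(matrix(c(1L, 0L), 1), matrix(0, 1, 2),
                                  1, c(0.5, 0.5), 1), "-Inf")
  expect_identical(ll0, -Inf)
})

test_that("presence-absence likelihood factorizes presence and detection", {
  # Lambda*A = ln 2 and q*E = ln 2: success probability 0.5 * 0.5
  ll1 <- pa_loglik(1, lambda_b = log(2), area_b = 1, effort_b = log(2), q = 1)
  expect_equal(exp(ll1), 0.25)
  ll0 <- pa_loglik(0, log(2), 1, log(2), 1)
  expect_equal(exp(ll0), 0.75)
  # no effort: pi = 0, absence contributes log(1) = 0
  expect_equal(pa_loglik(0, 5, 10, 0, 1), 0)
  expect_warning(llm <- pa_loglik(1, 5, 10, 0, 1), "-Inf")
  expect_identical(llm, -Inf)
  # pi is non-decreasing in each argument
  base <- pa_loglik(1, 1, 1, 1, 0.5)
  expect_gte(pa_loglik(1, 2, 1, 1, 0.5), base)
  expect_gte(pa_loglik(1, 1, 2, 1, 0.5), base)
  expect_gte(pa_loglik(1, 1, 1, 2, 0.5), base)
  expect_gte(pa_loglik(1, 1, 1, 1, 0.9), base)
})

test_that("thinning probability uses the logistic link with country offsets", {
  p <- thinning_probability(0, 1, access = c(0, 1), country_effects = c(1, -1),
                            country = c(1, 2))
  expect_equal(p, plogis(c(1, 0)))
  expect_equal(thinning_probability(-40, 0, 0, numeric(0), integer(0)),
               plogis(-40))
})

test_that("the joint model gradient matches finite differences", {
  sys <- small_system(8, 8, n_blobs = 8, seed = 3)
  data <- small_isdm_data(sys)
  spec <- model_spec(K = 9, chains = 2, iter = 300, warmup = 100)
  B <- spline_basis(data$grid$cells[, c("x", "y")], spec$K)
  Bs <- sweep(B, 2, pmax(apply(B, 2, sd), 1e-12), "/")
  lg <- isdmchange:::make_lp_grad(data, spec, Bs)
  lay <- attr(lg, "layout")
  set.seed(42)
  theta <- rnorm(lay$n, 0, 0.3)
  theta[lay$idx$beta0] <- -9  # keep detection probabilities off saturation
  an <- lg(theta)$grad
  fd <- vapply(seq_len(lay$n), function(j) {
    h <- 1e-6
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (lg(tp)$lp - lg(tm)$lp) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(an - fd) / pmax(1, abs(fd))), 1e-5)
})

test_that("with no presence-absence blobs the joint reduces to the thinned-Poisson model", {
  sys <- small_system(8, 8, n_blobs = 8, seed = 3)
  data <- small_isdm_data(sys)
  # strip the PA component
  data0 <- data
  data0$blob_y <- integer(0); data0$blob_period <- integer(0)
  data0$blob_W <- matrix(0, 0, nrow(data$grid$cells))
  data0$blob_area <- numeric(0); data0$blob_effort <- numeric(0)
  spec <- model_spec(K = 4, chains = 2, iter = 300, warmup = 100)
  B <- spline_basis(data$grid$cells[, c("x", "y")], spec$K)
  Bs <- sweep(B, 2, pmax(apply(B, 2, sd), 1e-12), "/")
  lg0 <- isdmchange:::make_lp_grad(data0, spec, Bs)
  lay <- attr(lg0, "layout")
  set.seed(9)
  th1 <- rnorm(lay$n, 0, 0.2); th1[lay$idx$beta0] <- -9
  th2 <- th1; th2[lay$idx$beta] <- th2[lay$idx$beta] + 0.3
  # the lp difference between two states that differ only in beta equals
  # the po_loglik difference plus the beta prior difference
  unpack <- function(th) {
    a0 <- th[lay$idx$alpha0]
    list(beta0 = th[lay$idx$beta0] - plogis(a0, log.p = TRUE),
         beta = th[lay$idx$beta], tau = th[lay$idx$tau],
         betaD = th[lay$idx$betaD], g = th[lay$idx$g],
         g2 = exp(th[lay$idx$log_sigma_g2]) * th[lay$idx$g2],
         alpha0 = a0, alphaA = th[lay$idx$alpha_access],
         craw = th[lay$idx$craw])
  }
  po_part <- function(th) {
    pp <- unpack(th)
    lam1 <- log_intensity(pp[c("beta0", "beta", "tau", "betaD", "g", "g2")],
                          data0$X, data0$D, Bs, 1)
    lam2 <- log_intensity(pp[c("beta0", "beta", "tau", "betaD", "g", "g2")],
                          data0$X, data0$D, Bs, 2)
    cfull <- c(pp$craw, -sum(pp$craw))
    p <- thinning_probability(pp$alpha0, pp$alphaA, data0$access,
                              cfull, data0$country)
    po_loglik(data0$po_counts, cbind(lam1, lam2), data0$area, p,
              rho = data0$effort_ratio)
  }
  prior_beta <- function(th) -sum(th[lay$idx$beta]^2) / (2 * spec$scale_fixed^2)
  d_lp <- lg0(th2)$lp - lg0(th1)$lp
  d_ref <- (po_part(th2) + prior_beta(th2)) - (po_part(th1) + prior_beta(th1))
  expect_equal(d_lp, d_ref, tolerance = 1e-8)
})
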