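# Hamiltonian Monte Carlo over a Laplace-preconditioned metric.
#
# Static-trajectory HMC with a jittered number of leapfrog steps and dual
# averaging of the step size towards a target acceptance rate. The mass
# matrix is either a fixed dense metric (the inverse of a posterior
# covariance estimate, typically from a Laplace approximation at the mode)
# or an identity/diagonal metric adapted in expanding warmup windows.
# Deliberately minimal: the posteriors fitted here are smooth,
# moderate-dimensional GLM-type posteriors for which this is ample.

# momentum/kinetic helpers for a metric given by Sigma (= inverse mass).
make_metric <- function(d, Sigma = NULL) {
  if (is.null(Sigma)) {
    inv_mass <- rep(1, d)
    list(
      type = "diag",
      sample_p = function() stats::rnorm(d) / sqrt(inv_mass),
      kinetic = function(p) 0.5 * sum(inv_mass * p^2),
      velocity = function(p) inv_mass * p,
      set_diag = function(v) inv_mass <<- v,
      get_diag = function() inv_mass
    )
  } else {
    U <- chol(Sigma)  # Sigma = U'U; mass = Sigma^-1; p ~ N(0, mass)
    list(
      type = "dense",
      sample_p = function() backsolve(U, stats::rnorm(d)),
      kinetic = function(p) { w <- U %*% p; 0.5 * sum(w^2) },
      velocity = function(p) drop(crossprod(U, U %*% p))
    )
  }
}

leapfrog <- function(theta, p, eps, L, lp_grad, metric) {
  gr <- lp_grad(theta)
  if (!is.finite(gr$lp)) return(NULL)
  g <- gr$grad
  for (l in seq_len(L)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * metric$velocity(p)
    gr <- lp_grad(theta)
    if (!is.finite(gr$lp) || any(!is.finite(gr$grad))) return(NULL)
    g <- gr$grad
    p <- p + 0.5 * eps * g
  }
  list(theta = theta, p = p, lp = gr$lp)
}

find_initial_eps <- function(theta, lp_grad, metric, eps = 0.1) {
  lp0 <- lp_grad(theta)$lp
  accept_of <- function(eps) {
    p <- metric$sample_p()
    st <- leapfrog(theta, p, eps, 1L, lp_grad, metric)
    if (is.null(st)) return(0)
    exp(min(0, st$lp - metric$kinetic(st$p) - (lp0 - metric$kinetic(p))))
  }
  a <- accept_of(eps)
  dir <- if (a > 0.5) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^dir
    a <- accept_of(eps)
    if ((dir == 1 && a < 0.5) || (dir == -1 && a > 0.5)) break
  }
  max(eps, 1e-6)
}

#' Sample one HMC chain
#'
#' @param lp_grad function of the parameter vector returning
#'   `list(lp = <log posterior>, grad = <gradient vector>)`; `lp = -Inf`
#'   marks an excluded region.
#' @param init initial parameter vector.
#' @param n_iter total iterations (including warmup).
#' @param n_warmup warmup iterations (discarded; used to adapt the step
#'   size, and the mass matrix when no `Sigma` is supplied).
#' @param seed integer seed (chain-specific).
#' @param target_accept dual-averaging target acceptance rate.
#' @param L_range inclusive range of leapfrog steps per iteration (jittered
#'   uniformly).
#' @param Sigma optional dense posterior covariance estimate; when given,
#'   the fixed metric `Sigma^-1` is used (Laplace preconditioning) and only
#'   the step size is adapted.
#' @param active optional index vector of coordinates updated by HMC; the
#'   rest are left to `gibbs`.
#' @param gibbs optional function mapping the full parameter vector to an
#'   updated one (conditional updates of the non-`active` coordinates),
#'   applied once per iteration after the HMC step.
#' @param metric_refresh optional function of the full parameter vector
#'   returning an updated dense covariance for the active block; called at
#'   one and two thirds of warmup (dense metric only), after which the step
#'   size is re-adapted.
#' @return List with `draws` (kept iterations x parameters),
#'   `accept_rate`, `eps` and `n_divergent`.
#' @export
hmc_chain <- function(lp_grad, init, n_iter = 2000, n_warmup = n_iter %/% 2,
                      seed = 1, target_accept = 0.8, L_range = c(8, 15),
                      Sigma = NULL, active = NULL, gibbs = NULL,
                      metric_refresh = NULL) {
  stopifnot(n_warmup < n_iter, n_warmup >= 20)
  if (is.null(active)) active <- seq_along(init)
  d <- length(active)
  with_seed_local(seed, {
    theta_full <- init
    lp_grad_full <- lp_grad
    lp_grad <- function(th_act) {
      th <- theta_full
      th[active] <- th_act
      r <- lp_grad_full(th)
      list(lp = r$lp, grad = r$grad[active])
    }
    theta <- init[active]
    metric <- make_metric(d, if (is.null(Sigma)) NULL else
      Sigma[active, active, drop = FALSE])
    eps <- find_initial_eps(theta, lp_grad, metric,
                            eps = if (is.null(Sigma)) 0.1 else 0.5)
    mu_da <- log(10 * eps); log_eps_bar <- log(eps); H_bar <- 0
    gamma_da <- 0.05; t0 <- 10; kappa <- 0.75; da_count <- 0
    reset_da <- function() {
      mu_da <<- log(10 * eps); log_eps_bar <<- log(eps)
      H_bar <<- 0; da_count <<- 0
    }
    # diag-adaptation windows (only without a fixed dense metric)
    adapt_mass <- is.null(Sigma)
    n_fast1 <- max(10L, floor(0.15 * n_warmup))
    n_fast2 <- max(10L, floor(0.10 * n_warmup))
    slow_span <- n_warmup - n_fast1 - n_fast2
    w <- max(10L, floor(slow_span / 7))
    window_ends <- integer(0); pos <- n_fast1
    while (pos < n_fast1 + slow_span) {
      pos <- min(pos + w, n_fast1 + slow_span)
      window_ends <- c(window_ends, pos)
      w <- w * 2
    }
    window_buf <- matrix(NA_real_, 0, d)
    refresh_at <- if (!is.null(Sigma) && !is.null(metric_refresh)) {
      unique(pmax(20L, floor(n_warmup * c(0.2, 0.4, 0.6, 0.8))))
    } else {
      integer(0)
    }
    draws <- matrix(NA_real_, n_iter - n_warmup, length(init))
    n_acc <- 0; n_div <- 0; n_post <- 0
    for (it in seq_len(n_iter)) {
      L <- sample(L_range[1]:L_range[2], 1)
      p0 <- metric$sample_p()
      lp0 <- lp_grad(theta)$lp
      H0 <- -lp0 + metric$kinetic(p0)
      st <- leapfrog(theta, p0, eps, L, lp_grad, metric)
      if (is.null(st)) {
        a_prob <- 0; n_div <- n_div + 1
      } else {
        dH <- H0 - (-st$lp + metric$kinetic(st$p))
        a_prob <- if (is.finite(dH)) exp(min(0, dH)) else 0
        if (stats::runif(1) < a_prob) {
          theta <- st$theta
          if (it > n_warmup) n_acc <- n_acc + 1
        }
      }
      if (it <= n_warmup) {
        da_count <- da_count + 1
        frac <- 1 / (da_count + t0)
        H_bar <- (1 - frac) * H_bar + frac * (target_accept - a_prob)
        log_eps <- mu_da - sqrt(da_count) / gamma_da * H_bar
        wt <- da_count^(-kappa)
        log_eps_bar <- wt * log_eps + (1 - wt) * log_eps_bar
        eps <- exp(log_eps)
        if (adapt_mass && it > n_fast1 && it <= n_warmup - n_fast2) {
          window_buf <- rbind(window_buf, theta)
          if (it %in% window_ends && nrow(window_buf) >= 10) {
            v <- apply(window_buf, 2, stats::var)
            n_w <- nrow(window_buf)
            metric$set_diag((n_w / (n_w + 5)) * v + (5 / (n_w + 5)) * 1e-3)
            window_buf <- matrix(NA_real_, 0, d)
            eps <- exp(log_eps_bar)
            reset_da()
          }
        }
        if (length(refresh_at)) window_buf <- rbind(window_buf, theta)
        if (it %in% refresh_at) {
          S_new <- metric_refresh(`[<-`(theta_full, active, theta))
          if (!is.null(S_new)) {
            if (nrow(window_buf) >= 40) {
              # keep the analytic correlation structure but inflate the
              # marginal scales where the warmup draws prove wider (heavy
              # prior-dominated directions); never shrink on window noise
              v_emp <- apply(window_buf, 2, stats::var)
              s <- sqrt(pmax(v_emp / diag(S_new), 1))
              s <- pmin(s, 10)
              S_new <- S_new * tcrossprod(s)
            }
            window_buf <- matrix(NA_real_, 0, d)
            metric <- make_metric(d, S_new)
            eps <- exp(log_eps_bar)
            reset_da()
          }
        }
        if (it == n_warmup) eps <- exp(log_eps_bar)
      }
      theta_full[active] <- theta
      if (!is.null(gibbs)) {
        theta_full <- gibbs(theta_full)
        theta <- theta_full[active]
      }
      if (it > n_warmup) {
        n_post <- n_post + 1
        draws[n_post, ] <- theta_full
      }
    }
    list(draws = draws, accept_rate = n_acc / (n_iter - n_warmup),
         eps = eps, n_divergent = n_div)
  })
}

# Posterior mode and Laplace covariance for preconditioning. Returns the
# mode and a positive-definite covariance estimate (inverse negative
# Hessian of the log posterior, with a ridge fallback).
laplace_approx <- function(lp_grad, init, maxit = 500) {
  opt <- stats::optim(init, fn = function(t) -lp_grad(t)$lp,
                      gr = function(t) -lp_grad(t)$grad,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  mode <- opt$par
  d <- length(mode)
  h <- 1e-4 * pmax(abs(mode), 1)
  H <- matrix(NA_real_, d, d)
  for (j in seq_len(d)) {
    tp <- mode; tp[j] <- tp[j] + h[j]
    tm <- mode; tm[j] <- tm[j] - h[j]
    H[, j] <- (lp_grad(tp)$grad - lp_grad(tm)$grad) / (2 * h[j])
  }
  H <- (H + t(H)) / 2
  Sigma <- hessian_to_cov(H)
  list(mode = mode, Sigma = Sigma, H = H, value = -opt$value,
       convergence = opt$convergence)
}

# Invert a negative Hessian into a positive-definite covariance, flooring
# eigenvalues when the curvature estimate is not quite definite.
hessian_to_cov <- function(H) {
  Sigma <- tryCatch(solve(-H), error = function(e) NULL)
  ok <- !is.null(Sigma) && all(is.finite(Sigma)) &&
    all(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!ok) {
    ev <- eigen(-H, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-6 * max(abs(ev$values), 1))
    Sigma <- ev$vectors %*% (t(ev$vectors) / vals)
  }
  Sigma
}
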