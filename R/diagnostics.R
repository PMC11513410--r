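# Convergence diagnostics and goodness-of-fit measures.

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half and the Gelman-Rubin statistic is computed on
#' the resulting half-chains, so slow within-chain drift also inflates the
#' diagnostic. Values near 1 indicate agreement; the conventional
#' convergence bar here is 1.1.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths
#'   preferred; trailing draws are dropped to equalize), or a matrix with
#'   one column per chain. At least 2 chains of at least 4 draws.
#' @return Scalar Rhat (`NA` with a warning when the within-chain variance
#'   is zero, where the statistic is undefined).
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  stopifnot(is.list(chains), length(chains) >= 2)
  n <- min(lengths(chains))
  if (n < 4) stop("need at least 4 draws per chain")
  half <- n %/% 2
  splits <- list()
  for (ch in chains) {
    ch <- ch[seq_len(2 * half)]
    splits[[length(splits) + 1]] <- ch[seq_len(half)]
    splits[[length(splits) + 1]] <- ch[half + seq_len(half)]
  }
  m <- length(splits)
  means <- vapply(splits, mean, numeric(1))
  vars <- vapply(splits, stats::var, numeric(1))
  W <- mean(vars)
  if (W == 0 || !is.finite(W)) {
    warning("zero within-chain variance: Rhat undefined")
    return(NA_real_)
  }
  Bv <- half * stats::var(means)
  var_plus <- (half - 1) / half * W + Bv / half
  sqrt(var_plus / W)
}

# Effective sample size over multiple chains (Geyer initial-positive
# truncation of the pooled autocorrelation, Stan-style).
ess_basic <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  n <- min(lengths(chains)); m <- length(chains)
  chains <- lapply(chains, function(ch) ch[seq_len(n)])
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0 || !is.finite(W)) return(NA_real_)
  Bv <- if (m > 1) n * stats::var(vapply(chains, mean, numeric(1))) else 0
  var_plus <- (n - 1) / n * W + Bv / n
  acfs <- lapply(chains, function(ch) {
    stats::acf(ch, lag.max = n - 2, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  max_lag <- n - 2
  rho <- vapply(seq_len(max_lag + 1), function(l) {
    mean_acov <- mean(vapply(acfs, function(a) a[l], numeric(1))) * W
    1 - (W - mean_acov) / var_plus
  }, numeric(1))
  # Geyer: sum consecutive pairs while positive
  tau <- -1
  l <- 1
  while (l + 1 <= length(rho)) {
    pair <- rho[l] + rho[l + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    l <- l + 2
  }
  tau <- max(tau, 1 / (m * n))
  min(m * n / tau, m * n)
}

#' Discrimination measures for presence-absence fits
#'
#' AUC is the probability that a randomly chosen presence receives a higher
#' fitted probability than a randomly chosen absence (ties count one half);
#' Tjur's R-squared is the mean fitted probability at presences minus the
#' mean at absences.
#'
#' @param y observed 0/1 outcomes (both classes must occur).
#' @param pi fitted success probabilities.
#' @return Named vector `c(auc, tjur_r2)`.
#' @export
evaluate_pa <- function(y, pi) {
  stopifnot(length(y) == length(pi), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both presences and absences are required")
  r <- rank(pi, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(auc = auc, tjur_r2 = mean(pi[y == 1]) - mean(pi[y == 0]))
}

#' Randomized-quantile (PIT) residuals for the presence-only counts
#'
#' For each observed count, the probability integral transform under its
#' posterior predictive distribution, randomized within the discrete mass
#' at the observed value. Under a well-specified model the residuals are
#' Uniform(0, 1); a Kolmogorov-Smirnov test against uniformity summarizes
#' calibration.
#'
#' @param observed integer vector (or cells x 2 matrix) of observed counts.
#' @param predictive matrix of posterior predictive counts with one column
#'   per observation (draws x observations), at least 100 draws; when
#'   `observed` is a matrix, a list of two such matrices (`t1`, `t2`).
#' @param seed integer seed for the randomization.
#' @return List of class `pit_result` with `residuals`, `ks_stat`,
#'   `p_value`.
#' @export
pit_residuals <- function(observed, predictive, seed = 1) {
  if (is.matrix(observed) && ncol(observed) == 2) {
    stopifnot(is.list(predictive), length(predictive) >= 2)
    observed <- c(observed[, 1], observed[, 2])
    predictive <- cbind(predictive[[1]], predictive[[2]])
  }
  stopifnot(is.matrix(predictive), ncol(predictive) == length(observed))
  if (nrow(predictive) < 100) {
    stop("at least 100 posterior predictive draws are required")
  }
  u <- with_seed_local(seed, {
    v <- stats::runif(length(observed))
    vapply(seq_along(observed), function(i) {
      Fn <- mean(predictive[, i] <= observed[i])
      Fn1 <- mean(predictive[, i] <= observed[i] - 1)
      Fn1 + v[i] * (Fn - Fn1)
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  structure(list(residuals = u, ks_stat = unname(ks$statistic),
                 p_value = unname(ks$p.value)),
            class = "pit_result")
}

#' @export
print.pit_result <- function(x, ...) {
  cat(sprintf("<pit_result: KS = %.4f, p = %.4f over %d residuals>\n",
              x$ks_stat, x$p_value, length(x$residuals)))
  invisible(x)
}
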