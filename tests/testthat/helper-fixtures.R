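# Shared fixtures and independent oracles used across tests.

# A small study system with model-ready data, memoized per configuration.
.fixture_env <- new.env(parent = emptyenv())

small_system <- function(nx = 10, ny = 10, n_blobs = 12, seed = 42, ...) {
  key <- paste("sys", nx, ny, n_blobs, seed, ..., sep = "_")
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(grid_nx = nx, grid_ny = ny, n_blobs = n_blobs,
                      seed = seed, ...)
    .fixture_env[[key]] <- simulate_system(cfg)
  }
  .fixture_env[[key]]
}

small_isdm_data <- function(sys = small_system()) {
  assemble_isdm_data(sys$grid, sys$po$counts, sys$pa$blobs,
                     effort_ratio = sys$config$effort_ratio_true,
                     species = sys$config$species)
}

# ---- independent brute-force oracles -----------------------------------

oracle_ruzicka <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + min(x[i], y[i])
    den <- den + max(x[i], y[i])
  }
  1 - num / den
}

oracle_whittaker <- function(P) {
  alpha <- numeric(ncol(P))
  for (i in seq_len(ncol(P))) alpha[i] <- sum(P[, i])
  gamma <- 0
  for (s in seq_len(nrow(P))) {
    pr_absent <- 1
    for (i in seq_len(ncol(P))) pr_absent <- pr_absent * (1 - P[s, i])
    gamma <- gamma + 1 - pr_absent
  }
  c(gamma = gamma, alpha_bar = mean(alpha), beta = gamma / mean(alpha))
}

oracle_auc <- function(y, pi) {
  pos <- pi[y == 1]; neg <- pi[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

oracle_tjur <- function(y, pi) mean(pi[y == 1]) - mean(pi[y == 0])

# Split-Rhat straight from the Gelman-Rubin formula.
oracle_split_rhat <- function(chains) {
  n <- min(lengths(chains))
  half <- n %/% 2
  halves <- list()
  for (ch in chains) {
    halves <- c(halves, list(ch[1:half]), list(ch[(half + 1):(2 * half)]))
  }
  m <- length(halves)
  means <- sapply(halves, mean)
  W <- mean(sapply(halves, var))
  B <- half * var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Moran's I with a row-standardized inverse-distance weight matrix, via ape.
morans_i <- function(values, x, y) {
  w <- 1 / (as.matrix(stats::dist(cbind(x, y))) + diag(length(x)))
  diag(w) <- 0
  ape::Moran.I(values, w)$observed
}
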