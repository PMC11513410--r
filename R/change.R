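# From posterior intensities to range- and diversity-change summaries.

#' Occupancy probability surfaces from intensity draws
#'
#' Converts per-cell intensity draws into occupancy probabilities through
#' the cloglog relation `P = 1 - exp(-Lambda * A)`.
#'
#' @param lambda list with matrices `t1` and `t2` (draws x cells) of
#'   intensity draws, or an `isdm_fit` (whose intensities are computed).
#' @param area per-cell areas in km^2 (taken from the fit's grid when
#'   `lambda` is a fit).
#' @return An object of class `occupancy_surface`: list with draw matrices
#'   `P` (`t1`, `t2`), per-cell `median` (cells x 2), `area` and
#'   `cell_area_km2`.
#' @export
occupancy_probability <- function(lambda, area = NULL) {
  if (inherits(lambda, "isdm_fit")) {
    area <- lambda$data$grid$cells$area_km2
    lambda <- list(t1 = posterior_intensity(lambda, 1),
                   t2 = posterior_intensity(lambda, 2))
  }
  stopifnot(is.list(lambda), all(c("t1", "t2") %in% names(lambda)),
            !is.null(area))
  if (ncol(lambda$t1) != ncol(lambda$t2)) stop("mismatched cell sets")
  if (ncol(lambda$t1) != length(area)) stop("area does not match cells")
  if (any(lambda$t1 < 0) || any(lambda$t2 < 0)) stop("negative intensity")
  P <- list(t1 = 1 - exp(-sweep(lambda$t1, 2, area, "*")),
            t2 = 1 - exp(-sweep(lambda$t2, 2, area, "*")))
  med <- cbind(t1 = apply(P$t1, 2, stats::median),
               t2 = apply(P$t2, 2, stats::median))
  structure(list(P = P, median = med, area = area,
                 cell_area_km2 = unique(area)[1]),
            class = "occupancy_surface")
}

#' @export
print.occupancy_surface <- function(x, ...) {
  cat(sprintf("<occupancy_surface: %d cells x %d draws; mean median P %.3f | %.3f>\n",
              ncol(x$P$t1), nrow(x$P$t1),
              mean(x$median[, 1]), mean(x$median[, 2])))
  invisible(x)
}

#' Area of occupancy and its temporal change
#'
#' Per posterior draw, the area of occupancy in a period is the sum of the
#' occupancy probabilities over cells (in cells; times the cell area for
#' km^2); the change is the within-draw difference `A_t2 - A_t1`, so the
#' credible interval of the change respects the posterior coupling of the
#' two periods.
#'
#' @param surface an [occupancy_probability()] result.
#' @param prob credible-interval mass (default 0.95).
#' @return An object of class `change_summary`: draws of `A_t1`, `A_t2`,
#'   `dA` (cells), a `summary` data.frame (median and interval, in cells
#'   and km^2), per-cell `dP` draws and their median/interval.
#' @export
area_of_occupancy <- function(surface, prob = 0.95) {
  stopifnot(inherits(surface, "occupancy_surface"))
  a <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  A1 <- rowSums(surface$P$t1)
  A2 <- rowSums(surface$P$t2)
  dA <- A2 - A1
  cell_km2 <- surface$cell_area_km2
  qs <- function(v) c(median = stats::median(v), stats::quantile(v, a))
  s <- rbind(A_t1 = qs(A1), A_t2 = qs(A2), dA = qs(dA))
  summary <- data.frame(
    quantity = rownames(s),
    median_cells = s[, 1], lower_cells = s[, 2], upper_cells = s[, 3],
    median_km2 = s[, 1] * cell_km2, lower_km2 = s[, 2] * cell_km2,
    upper_km2 = s[, 3] * cell_km2, row.names = NULL)
  dP <- surface$P$t2 - surface$P$t1
  structure(list(A_t1 = A1, A_t2 = A2, dA = dA, summary = summary,
                 dP = dP,
                 dP_median = apply(dP, 2, stats::median),
                 dP_lower = apply(dP, 2, stats::quantile, a[1]),
                 dP_upper = apply(dP, 2, stats::quantile, a[2]),
                 cell_area_km2 = cell_km2, prob = prob),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  s <- x$summary[x$summary$quantity == "dA", ]
  cat(sprintf(
    "<change_summary: dA median %.1f cells (%.0f km2), %d%% CI [%.1f, %.1f] cells>\n",
    s$median_cells, s$median_km2, round(100 * x$prob),
    s$lower_cells, s$upper_cells))
  invisible(x)
}

#' Classify per-cell occupancy change by sign and certainty
#'
#' The sign comes from the posterior median change; a change is "certain"
#' when the central credible interval excludes zero; cells whose absolute
#' median change is below `eps` are "no change".
#'
#' @param change a [area_of_occupancy()] result, or a draws x cells matrix
#'   of per-cell occupancy changes.
#' @param eps neutral-band half width on the median change (default 0.01).
#' @param prob interval mass (default 0.95).
#' @return Factor with levels `certain loss`, `uncertain loss`, `no change`,
#'   `uncertain gain`, `certain gain`.
#' @export
classify_change <- function(change, eps = 0.01, prob = 0.95) {
  if (inherits(change, "change_summary")) {
    med <- change$dP_median; lo <- change$dP_lower; hi <- change$dP_upper
  } else {
    stopifnot(is.matrix(change))
    if (nrow(change) < 100) stop("need at least 100 draws per cell")
    a <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
    med <- apply(change, 2, stats::median)
    lo <- apply(change, 2, stats::quantile, a[1])
    hi <- apply(change, 2, stats::quantile, a[2])
  }
  lab <- ifelse(abs(med) < eps, "no change",
         ifelse(med > 0 & lo > 0, "certain gain",
         ifelse(med > 0, "uncertain gain",
         ifelse(hi < 0, "certain loss", "uncertain loss"))))
  factor(lab, levels = c("certain loss", "uncertain loss", "no change",
                         "uncertain gain", "certain gain"))
}

#' Stacked species richness per cell and period
#'
#' Subsamples (with a fixed seed) up to `n_samples` posterior draws per
#' species, takes the per-species/cell/period median occupancy over them,
#' and sums the medians over species. When fewer draws are available, all
#' are used with a warning.
#'
#' @param surfaces named list of [occupancy_probability()] surfaces sharing
#'   one grid (one per species).
#' @param n_samples posterior draws per species to use (default 1000).
#' @param seed integer seed for the subsample.
#' @return List of class `richness_summary` with `median_P` (list of
#'   species x cells matrices `t1`, `t2`), `SR` (cells x 2) and `dSR`.
#' @export
stack_richness <- function(surfaces, n_samples = 1000, seed = 1) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1,
            all(vapply(surfaces, inherits, logical(1), "occupancy_surface")))
  ncells <- vapply(surfaces, function(s) ncol(s$P$t1), integer(1))
  if (length(unique(ncells)) != 1) stop("species must share the grid")
  # one subsample of draws per species, shared by both periods so the
  # within-draw coupling of the two surfaces is preserved
  takes <- lapply(seq_along(surfaces), function(s) {
    n_av <- nrow(surfaces[[s]]$P$t1)
    if (n_av < n_samples) {
      warning(sprintf("species %d: only %d draws available (< %d); using all",
                      s, n_av, n_samples))
      seq_len(n_av)
    } else {
      with_seed_local(derive_seed(seed, s), sample(n_av, n_samples))
    }
  })
  med <- list(t1 = NULL, t2 = NULL)
  for (t in c("t1", "t2")) {
    M <- t(vapply(seq_along(surfaces), function(s) {
      P <- surfaces[[s]]$P[[t]]
      apply(P[takes[[s]], , drop = FALSE], 2, stats::median)
    }, numeric(ncells[1])))
    rownames(M) <- names(surfaces) %||% paste0("sp", seq_along(surfaces))
    med[[t]] <- M
  }
  SR <- cbind(t1 = colSums(med$t1), t2 = colSums(med$t2))
  structure(list(median_P = med, SR = SR, dSR = SR[, 2] - SR[, 1]),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("<richness_summary: %d species x %d cells; mean SR %.2f -> %.2f>\n",
              nrow(x$median_P$t1), ncol(x$median_P$t1),
              mean(x$SR[, 1]), mean(x$SR[, 2])))
  invisible(x)
}

#' Whittaker multiplicative beta diversity of a probabilistic stack
#'
#' Local (alpha) diversity in a cell is the expected richness
#' `sum_s P_si`; gamma is the expected pooled richness
#' `sum_s [1 - prod_i (1 - P_si)]` (the probability each species occurs
#' somewhere); beta is their ratio `gamma / mean(alpha)`.
#'
#' @param P species x cells matrix of occupancy probabilities in `[0, 1]`.
#' @return Named vector `c(gamma, alpha_bar, beta)` (`beta = NA` with a
#'   warning when the mean alpha is zero).
#' @export
whittaker_beta <- function(P) {
  P <- as.matrix(P)
  stopifnot(all(P >= 0 & P <= 1))
  alpha <- colSums(P)
  abar <- mean(alpha)
  gamma <- sum(1 - apply(1 - P, 1, prod))
  if (abar == 0) {
    warning("mean alpha diversity is zero: beta undefined")
    return(c(gamma = gamma, alpha_bar = 0, beta = NA_real_))
  }
  c(gamma = gamma, alpha_bar = abar, beta = gamma / abar)
}

#' Ruzicka dissimilarity between two non-negative vectors
#'
#' The quantitative Jaccard-family index
#' `1 - sum(min(x, y)) / sum(max(x, y))`, in `[0, 1]`.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return Scalar dissimilarity (`NA` with a warning when both vectors are
#'   all zero, where the index is undefined).
#' @export
#' @examples
#' ruzicka(c(0.2, 0.5, 0), c(0.4, 0.1, 0))  # 1 - 0.3/0.9
ruzicka <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  smax <- sum(pmax(x, y))
  if (smax == 0) {
    warning("both vectors are all-zero: Ruzicka dissimilarity undefined")
    return(NA_real_)
  }
  1 - sum(pmin(x, y)) / smax
}

#' Per-cell temporal Ruzicka dissimilarity between two periods
#'
#' @param P1,P2 species x cells occupancy matrices for the two periods
#'   (same species, same cells).
#' @return Numeric vector of per-cell dissimilarities (`NA` where both
#'   period compositions are zero).
#' @export
temporal_dissimilarity_map <- function(P1, P2) {
  P1 <- as.matrix(P1); P2 <- as.matrix(P2)
  stopifnot(all(dim(P1) == dim(P2)))
  vapply(seq_len(ncol(P1)), function(i) {
    suppressWarnings(ruzicka(P1[, i], P2[, i]))
  }, numeric(1))
}

#' Distance decay of spatial Ruzicka dissimilarity
#'
#' Samples `n_pairs` unordered cell pairs (with a fixed seed), computes the
#' pairwise Ruzicka dissimilarity of the species-composition vectors within
#' each period and the centroid distance of the pair, and summarizes the
#' median dissimilarity per distance bin and period.
#'
#' @param stacks list with species x cells matrices `t1`, `t2`.
#' @param centroids two-column matrix of cell centroids (km).
#' @param n_pairs number of sampled pairs (default 50000, capped at the
#'   number of distinct pairs).
#' @param bins number of equal-width distance bins, or a vector of breaks.
#' @param seed integer seed.
#' @return data.frame with `bin_mid`, `period`, `median_dissim`, `n`;
#'   empty bins are retained with `NA` medians.
#' @export
spatial_distance_decay <- function(stacks, centroids, n_pairs = 50000,
                                   bins = 10, seed = 1) {
  stopifnot(is.list(stacks), all(c("t1", "t2") %in% names(stacks)))
  centroids <- as.matrix(centroids)
  n <- ncol(stacks$t1)
  stopifnot(n >= 2, nrow(centroids) == n)
  total_pairs <- n * (n - 1) / 2
  n_pairs <- min(n_pairs, total_pairs)
  pr <- with_seed_local(seed, {
    i <- sample(n, n_pairs, replace = TRUE)
    j <- sample(n - 1, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    cbind(i, j)
  })
  d <- sqrt((centroids[pr[, 1], 1] - centroids[pr[, 2], 1])^2 +
              (centroids[pr[, 1], 2] - centroids[pr[, 2], 2])^2)
  breaks <- if (length(bins) == 1) {
    seq(0, max(d) * (1 + 1e-9), length.out = bins + 1)
  } else {
    bins
  }
  bin <- cut(d, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- list()
  for (t in c("t1", "t2")) {
    P <- stacks[[t]]
    diss <- vapply(seq_len(n_pairs), function(r) {
      suppressWarnings(ruzicka(P[, pr[r, 1]], P[, pr[r, 2]]))
    }, numeric(1))
    med <- tapply(diss, bin, stats::median, na.rm = TRUE)
    cnt <- tapply(diss, bin, length)
    out[[t]] <- data.frame(bin_mid = mids, period = t,
                           median_dissim = as.numeric(med),
                           n = ifelse(is.na(cnt), 0L, as.integer(cnt)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$n == 0)) message("spatial_distance_decay: empty bins flagged (n = 0)")
  res
}
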