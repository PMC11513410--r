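# Latent-state and observation-process likelihood components.
#
# Latent state: log Lambda_{it} = beta0 + x_i'beta + betaD D_i + B_i g
#                                 + 1[t=2] (tau + B_i g2)
# PO process:  n_{it} ~ Poisson(Lambda_{it} A_i p_{i} rho_t), with thinning
#              p_i = logit^-1(alpha0 + alpha_a access_i + c_{j(i)}) and
#              rho_1 = 1, rho_2 the fixed effort ratio.
# PA process:  y_b ~ Bernoulli{(1 - e^{-Lambda_b A_b})(1 - e^{-q E_b})}.

#' Low-rank 2-D spatial spline basis
#'
#' Tensor-product cubic B-spline basis over the projected coordinates, with
#' `ceiling(sqrt(K))` marginal basis functions per axis (so the number of
#' columns is the smallest perfect square at or above `K`). Columns are
#' centred, so the smooth field is identifiable alongside an intercept.
#'
#' @param coords two-column matrix or data.frame of projected `x`, `y` (km).
#' @param K requested basis dimension (at least 4); rounded up to a square.
#' @return Numeric matrix (points x K') with centred columns and attributes
#'   `knots_per_axis` and the marginal boundary knots (for evaluation at new
#'   points via [spline_basis_eval()]).
#' @export
spline_basis <- function(coords, K) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (!is.numeric(K) || K < 4) stop("K must be at least 4")
  m <- ceiling(sqrt(K))
  if (m^2 > nrow(coords)) stop("K exceeds the number of points")
  deg <- min(3L, m - 1L)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  Bx <- splines::bs(coords[, 1], df = m, degree = deg, intercept = TRUE,
                    Boundary.knots = rx)
  By <- splines::bs(coords[, 2], df = m, degree = deg, intercept = TRUE,
                    Boundary.knots = ry)
  B <- matrix(NA_real_, nrow(coords), m * m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B[, (i - 1) * m + j] <- Bx[, i] * By[, j]
  }
  ctr <- colMeans(B)
  B <- sweep(B, 2, ctr)
  colnames(B) <- paste0("s", seq_len(ncol(B)))
  structure(B, knots_per_axis = m, range_x = rx, range_y = ry, center = ctr)
}

#' Evaluate a fitted spline basis at new coordinates
#'
#' @param basis a matrix returned by [spline_basis()].
#' @param coords new projected coordinates.
#' @return Basis matrix at the new points, using the same knots/centring.
#' @export
spline_basis_eval <- function(basis, coords) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  m <- attr(basis, "knots_per_axis")
  deg <- min(3L, m - 1L)
  Bx <- splines::bs(coords[, 1], df = m, degree = deg, intercept = TRUE,
                    Boundary.knots = attr(basis, "range_x"))
  By <- splines::bs(coords[, 2], df = m, degree = deg, intercept = TRUE,
                    Boundary.knots = attr(basis, "range_y"))
  B <- matrix(NA_real_, nrow(coords), m * m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B[, (i - 1) * m + j] <- Bx[, i] * By[, j]
  }
  sweep(B, 2, attr(basis, "center"))
}

#' Latent intensity from parameters
#'
#' @param params list with `beta0`, `beta`, `tau`, `betaD`, `g`, `g2`.
#' @param X covariate matrix (cells x k).
#' @param D distance-to-range vector (per 1000 km).
#' @param B spatial spline basis (cells x K).
#' @param period 1 or 2.
#' @return Vector of intensities `Lambda` (per km^2).
#' @export
log_intensity <- function(params, X, D, B, period) {
  stopifnot(period %in% c(1, 2))
  eta <- params$beta0 + drop(X %*% params$beta) + params$betaD * D +
    drop(B %*% params$g)
  if (period == 2) eta <- eta + params$tau + drop(B %*% params$g2)
  if (any(!is.finite(eta))) {
    stop("non-finite log intensity at cell(s) ",
         paste(utils::head(which(!is.finite(eta)), 5), collapse = ", "))
  }
  exp(eta)
}

#' Presence-only thinning probability
#'
#' @param alpha0,alpha_access thinning coefficients.
#' @param access per-cell accessibility covariate.
#' @param country_effects per-country offsets (sum to zero).
#' @param country per-cell country index.
#' @return Per-cell retention probability in (0, 1).
#' @export
thinning_probability <- function(alpha0, alpha_access, access,
                                 country_effects, country) {
  ce <- if (length(country_effects)) country_effects[country] else 0
  stats::plogis(alpha0 + alpha_access * access + ce)
}

#' Presence-only (thinned Poisson) log likelihood
#'
#' @param n cells x 2 matrix of observed counts.
#' @param lambda cells x 2 matrix of intensities.
#' @param area per-cell area (km^2).
#' @param p per-cell thinning probability (or cells x 2 matrix).
#' @param rho period-2 effort ratio (rho_1 = 1).
#' @return Scalar log likelihood (`-Inf` when a zero mean meets a positive
#'   count, with a warning).
#' @export
po_loglik <- function(n, lambda, area, p, rho) {
  n <- as.matrix(n); lambda <- as.matrix(lambda)
  stopifnot(all(dim(n) == dim(lambda)), ncol(n) == 2, all(n >= 0),
            rho > 0, all(p >= 0 & p <= 1))
  if (!is.matrix(p)) p <- matrix(p, nrow(n), 2)
  mu <- lambda * area * p
  mu[, 2] <- mu[, 2] * rho
  if (any(mu == 0 & n > 0)) {
    warning("zero Poisson mean with positive count: log likelihood is -Inf")
    return(-Inf)
  }
  sum(stats::dpois(n, mu, log = TRUE))
}

#' Presence-absence (occupancy-detection) log likelihood
#'
#' Success probability factorizes as presence times detection,
#' `pi_b = (1 - exp(-Lambda_b A_b)) * (1 - exp(-q E_b))`.
#'
#' @param y 0/1 detection flags per blob.
#' @param lambda_b per-blob mean intensity (area-weighted over cells).
#' @param area_b blob areas (km^2).
#' @param effort_b blob efforts (camera-trap days).
#' @param q per-camera-trap-day detection rate (> 0).
#' @return Scalar log likelihood (`-Inf` when `pi = 0` meets `y = 1`, with a
#'   warning).
#' @export
pa_loglik <- function(y, lambda_b, area_b, effort_b, q) {
  stopifnot(all(y %in% c(0, 1)), all(area_b >= 0), all(effort_b >= 0), q > 0)
  p_pres <- -expm1(-lambda_b * area_b)
  p_det <- -expm1(-q * effort_b)
  pi <- p_pres * p_det
  if (any(pi == 0 & y == 1)) {
    warning("zero detection probability with observed detection: -Inf")
    return(-Inf)
  }
  sum(ifelse(y == 1, log(pi), log1p(-pi)))
}
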