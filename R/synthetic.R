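# Synthetic study systems with known truth.
#
# A simulated system mirrors the structure of a two-period continental
# analysis: an equal-area grid with smooth environmental covariates, a
# latent log-linear intensity with a period effect and a residual spatial
# field, presence-only records thinned by accessibility and country,
# presence-absence camera-trap blobs with effort-dependent detection, and a
# pseudo-expert range derived from the period-1 truth. All generators are
# deterministic given the seed they are handed.

#' Configuration of a synthetic study system
#'
#' Collects every generative parameter of the simulated two-period system.
#' Defaults describe a single carnivore-like species on a 20 x 20 lattice of
#' 100-km cells: a latent intensity around 2 expected occurrences per cell
#' inside the core range, a mild range contraction between periods
#' (`tau = -0.5`), suppression of intensity far outside the expert range
#' (`beta_dist`, per 1000 km of distance), presence-only thinning that keeps
#' roughly a fifth of occurrences in accessible cells, 27% more
#' presence-only sampling in the second period (`effort_ratio_true = 1.27`),
#' and 30 camera-trap surveys of 500-5000 km^2 with 100-1000 trap-days of
#' effort.
#'
#' @param grid_nx,grid_ny lattice dimensions (cells).
#' @param cell_size_km cell side (km).
#' @param n_covariates number of environmental covariate fields.
#' @param beta0 intercept of the log intensity (occurrences per km^2).
#' @param beta covariate effects (recycled/truncated to `n_covariates`).
#' @param tau period-2 offset on the log intensity.
#' @param beta_dist effect of distance to the pseudo-expert range, per
#'   1000 km (negative values suppress intensity outside the range).
#' @param sigma_resid,resid_length_scale sd and range (km) of the residual
#'   spatial field on the log intensity.
#' @param cov_length_scale,access_length_scale autocorrelation range (km) of
#'   the covariate and accessibility fields.
#' @param alpha0,alpha_access thinning coefficients on the logit scale.
#' @param n_countries number of contiguous rectangular "countries" (2-4).
#' @param country_effects per-country thinning offsets, sum to zero.
#' @param detection_rate per-camera-trap-day detection rate `q`.
#' @param effort_ratio_true true ratio of period-2 to period-1 presence-only
#'   sampling effort (rho).
#' @param n_blobs number of camera-trap surveys.
#' @param survey_area_range survey footprint area interval (km^2).
#' @param effort_range camera-trap-day effort interval.
#' @param range_threshold intensity quantile defining the pseudo-expert
#'   range (cells above it are "inside").
#' @param period1_years,period2_years calendar years of the two periods.
#' @param species species label used in generated record tables.
#' @param seed integer seed governing all generators.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_nx = 20, grid_ny = 20, cell_size_km = 100,
                       n_covariates = 4,
                       beta0 = -8.5,
                       beta = c(1.0, -0.7, 0.5, 0.0),
                       tau = -0.5,
                       beta_dist = -1.0,
                       sigma_resid = 0.25, resid_length_scale = 400,
                       cov_length_scale = 500, access_length_scale = 600,
                       alpha0 = -1.5, alpha_access = 1.0,
                       n_countries = 3,
                       country_effects = c(0.5, -0.5, 0),
                       detection_rate = 0.02,
                       effort_ratio_true = 1.27,
                       n_blobs = 30,
                       survey_area_range = c(500, 5000),
                       effort_range = c(100, 1000),
                       range_threshold = 0.5,
                       period1_years = 2000:2013,
                       period2_years = 2014:2021,
                       species = "species_A",
                       seed = 1) {
  beta <- rep_len(beta, n_covariates)
  country_effects <- rep_len(country_effects, n_countries)
  country_effects <- country_effects - mean(country_effects)
  cfg <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              cell_size_km = cell_size_km, n_covariates = as.integer(n_covariates),
              beta0 = beta0, beta = beta, tau = tau, beta_dist = beta_dist,
              sigma_resid = sigma_resid, resid_length_scale = resid_length_scale,
              cov_length_scale = cov_length_scale,
              access_length_scale = access_length_scale,
              alpha0 = alpha0, alpha_access = alpha_access,
              n_countries = as.integer(n_countries),
              country_effects = country_effects,
              detection_rate = detection_rate,
              effort_ratio_true = effort_ratio_true,
              n_blobs = as.integer(n_blobs),
              survey_area_range = survey_area_range,
              effort_range = effort_range,
              range_threshold = range_threshold,
              period1_years = period1_years, period2_years = period2_years,
              species = species, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$grid_nx >= 1, cfg$grid_ny >= 1, cfg$n_covariates >= 1,
            cfg$n_blobs >= 1, cfg$n_countries >= 1)
  if (cfg$cell_size_km <= 0) stop("cell_size_km must be positive")
  if (cfg$range_threshold <= 0 || cfg$range_threshold >= 1) {
    stop("range_threshold must lie strictly between 0 and 1")
  }
  if (cfg$effort_ratio_true <= 0) stop("effort_ratio_true must be positive")
  if (cfg$detection_rate <= 0) stop("detection_rate must be positive")
  if (diff(cfg$survey_area_range) < 0 || cfg$survey_area_range[1] <= 0) {
    stop("invalid survey_area_range")
  }
  if (diff(cfg$effort_range) < 0 || cfg$effort_range[1] < 0) {
    stop("invalid effort_range")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %dx%d grid of %g km, %d covariates, seed %d>\n",
              x$grid_nx, x$grid_ny, x$cell_size_km, x$n_covariates, x$seed))
  cat(sprintf("  beta0 %.2f | beta %s | tau %.2f | beta_dist %.2f\n",
              x$beta0, paste(sprintf("%.2f", x$beta), collapse = " "),
              x$tau, x$beta_dist))
  cat(sprintf("  thinning alpha0 %.2f alpha_access %.2f | rho %.2f | q %.3f | %d blobs\n",
              x$alpha0, x$alpha_access, x$effort_ratio_true,
              x$detection_rate, x$n_blobs))
  invisible(x)
}

#' Simulate spatially autocorrelated covariate fields
#'
#' Draws `n_fields` independent Gaussian-process realizations (squared
#' exponential kernel with range `length_scale`) at the cell centroids and
#' standardizes each to mean 0, sd 1.
#'
#' @param grid an [build_grid()] lattice.
#' @param n_fields number of fields.
#' @param length_scale kernel range (km), positive.
#' @param seed integer seed.
#' @return A numeric matrix (cells x fields) with columns `cov1`, `cov2`, ...
#' @export
simulate_covariates <- function(grid, n_fields, length_scale, seed) {
  stopifnot(inherits(grid, "ea_grid"))
  if (!is.numeric(n_fields) || n_fields < 1) stop("n_fields must be >= 1")
  if (!is.numeric(length_scale) || length_scale <= 0) {
    stop("length_scale must be positive")
  }
  n_fields <- as.integer(n_fields)
  flds <- with_seed_local(seed, {
    vapply(seq_len(n_fields), function(k) {
      gp_field(grid$cells$x, grid$cells$y, length_scale)
    }, numeric(nrow(grid$cells)))
  })
  flds <- matrix(flds, nrow = nrow(grid$cells))
  # smooth fields have few effective degrees of freedom, so independent
  # draws can be strongly sample-correlated by chance; orthogonalize so the
  # fields are exactly uncorrelated over the lattice (linear combinations
  # of smooth fields stay smooth), then standardize
  if (n_fields > 1 && nrow(flds) > n_fields) {
    flds <- qr.Q(qr(sweep(flds, 2, colMeans(flds))))
  }
  flds <- apply(flds, 2, function(f) as.numeric(scale(f)))
  colnames(flds) <- paste0("cov", seq_len(n_fields))
  flds
}

# Split the lattice into contiguous rectangular "countries" (vertical bands
# of columns), mimicking country-level differences in record sharing.
assign_countries <- function(grid, n_countries) {
  stopifnot(inherits(grid, "ea_grid"), n_countries >= 1)
  breaks <- round(seq(0, grid$nx, length.out = n_countries + 1))
  findInterval(grid$cells$col, breaks[-(n_countries + 1)],
               rightmost.closed = TRUE)
}

#' Attach synthetic covariates, accessibility and countries to a grid
#'
#' Convenience wrapper used by [simulate_system()]: simulates environmental
#' fields and an accessibility field, assigns country bands, and binds them
#' to `grid$cells`.
#'
#' @param grid an `ea_grid`.
#' @param config a [sim_config()].
#' @return The grid with `cov*`, `access` and `country` columns attached.
#' @export
attach_synthetic_covariates <- function(grid, config) {
  stopifnot(inherits(grid, "ea_grid"), inherits(config, "sim_config"))
  covs <- simulate_covariates(grid, config$n_covariates,
                              config$cov_length_scale,
                              derive_seed(config$seed, 1))
  access <- with_seed_local(derive_seed(config$seed, 2), {
    as.numeric(scale(gp_field(grid$cells$x, grid$cells$y,
                              config$access_length_scale)))
  })
  grid$cells <- cbind(grid$cells, as.data.frame(covs))
  grid$cells$access <- access
  grid$cells$country <- assign_countries(grid, config$n_countries)
  grid
}

#' Simulate the latent truth of a study system
#'
#' Builds the true per-cell, per-period intensity
#' \deqn{\Lambda_{it} = \exp(\beta_0 + x_i'\beta + \tau 1[t=2] +
#'   \beta_D D_i + s_i)}
#' with a smooth Gaussian-process residual field \eqn{s}, the pseudo-expert
#' range (cells whose period-1 intensity, computed before the
#' distance-to-range term, exceeds the `range_threshold` quantile) and the
#' distance covariate \eqn{D_i} it induces (0 inside the range), and the true
#' occupancy probabilities \eqn{P_{it} = 1 - \exp(-\Lambda_{it} A_i)}.
#'
#' @param grid an `ea_grid` with covariate columns `cov*` attached.
#' @param config a [sim_config()].
#' @return An object of class `truth_bundle`: list with `grid` (with
#'   `dist_range_km` attached), `lambda` (cells x 2 matrix of intensities
#'   per km^2), `occupancy` (cells x 2), `range_polygon` (a [rect_union()]),
#'   `range_cells` (cell ids) and `config`.
#' @export
simulate_truth <- function(grid, config) {
  stopifnot(inherits(grid, "ea_grid"), inherits(config, "sim_config"))
  covnames <- paste0("cov", seq_len(config$n_covariates))
  if (!all(covnames %in% names(grid$cells))) {
    stop("covariates must be attached to the grid before simulate_truth ",
         "(missing: ", paste(setdiff(covnames, names(grid$cells)),
                             collapse = ", "), ")")
  }
  X <- as.matrix(grid$cells[covnames])
  s <- if (config$sigma_resid > 0) {
    with_seed_local(derive_seed(config$seed, 3), {
      f <- gp_field(grid$cells$x, grid$cells$y, config$resid_length_scale)
      config$sigma_resid * as.numeric(scale(f))
    })
  } else {
    rep(0, nrow(grid$cells))
  }
  eta_base <- config$beta0 + drop(X %*% config$beta) + s
  # Pseudo-expert range from the period-1 intensity before the distance
  # term enters (the range map is information about the truth, not a cause
  # of it; the distance effect then shapes the final intensity).
  lam1_pre <- exp(eta_base)
  thr <- stats::quantile(lam1_pre, config$range_threshold, names = FALSE)
  range_cells <- grid$cells$cell_id[lam1_pre > thr]
  if (length(range_cells) == 0) {
    # degenerate (constant or heavily tied) intensity: fall back to >=
    range_cells <- grid$cells$cell_id[lam1_pre >= thr]
  }
  if (length(range_cells) == 0) stop("range_threshold leaves no range cells")
  poly <- cells_to_polygon(grid, range_cells)
  D_km <- dist_to_rect_union(grid$cells$x, grid$cells$y, poly)
  grid$cells$dist_range_km <- D_km
  eta1 <- eta_base + config$beta_dist * D_km / 1000
  lambda <- cbind(t1 = exp(eta1), t2 = exp(eta1 + config$tau))
  occupancy <- 1 - exp(-lambda * grid$cells$area_km2)
  structure(list(grid = grid, lambda = lambda, occupancy = occupancy,
                 range_polygon = poly, range_cells = range_cells,
                 config = config),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("<truth_bundle: %d cells, range of %d cells, mean occupancy %.3f / %.3f>\n",
              nrow(x$grid$cells), length(x$range_cells),
              mean(x$occupancy[, 1]), mean(x$occupancy[, 2])))
  invisible(x)
}

# True presence-only thinning probability per cell.
thinning_prob_true <- function(truth) {
  cfg <- truth$config
  stats::plogis(cfg$alpha0 + cfg$alpha_access * truth$grid$cells$access +
                  cfg$country_effects[truth$grid$cells$country])
}

#' Simulate presence-only observations
#'
#' Thinned-Poisson counts per cell and period,
#' \eqn{n_{it} \sim Pois(\Lambda_{it} A_i p_i \rho_t)} with
#' \eqn{p_i = logit^{-1}(\alpha_0 + \alpha_a \, access_i + c_{j(i)})},
#' \eqn{\rho_1 = 1} and \eqn{\rho_2} the true effort ratio. Each count is
#' also expanded into a point-record table (uniform locations within the
#' cell, back-projected to lon/lat; random dates within the period; small
#' coordinate uncertainties) so that the raw-record preprocessing stages can
#' be exercised on synthetic data.
#'
#' @param truth a [simulate_truth()] bundle.
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @param seed integer seed; defaults to a stream derived from the config.
#' @return List with `counts` (cells x 2 integer matrix), `records` (a
#'   data.frame with `species`, `lon`, `lat`, `date`, `uncertainty_m`) and
#'   `thinning_prob` (the true per-cell retention probability).
#' @export
simulate_po <- function(truth, config = truth$config,
                        seed = derive_seed(config$seed, 4)) {
  stopifnot(inherits(truth, "truth_bundle"))
  grid <- truth$grid
  p <- thinning_prob_true(truth)
  A <- grid$cells$area_km2
  rho <- c(1, config$effort_ratio_true)
  if (any(truth$lambda < 0)) stop("negative intensity in truth")
  with_seed_local(seed, {
    counts <- cbind(
      t1 = stats::rpois(nrow(grid$cells), truth$lambda[, 1] * A * p * rho[1]),
      t2 = stats::rpois(nrow(grid$cells), truth$lambda[, 2] * A * p * rho[2])
    )
    recs <- list()
    half <- grid$cell_size_km / 2
    for (t in 1:2) {
      n <- counts[, t]
      idx <- rep(seq_along(n), n)
      if (length(idx) == 0) next
      px <- grid$cells$x[idx] + stats::runif(length(idx), -half, half)
      py <- grid$cells$y[idx] + stats::runif(length(idx), -half, half)
      ll <- laea_inverse(px, py, lon0 = grid$lon0, lat0 = grid$lat0)
      yrs <- if (t == 1) config$period1_years else config$period2_years
      dates <- as.Date(sprintf(
        "%d-%02d-%02d",
        sample(yrs, length(idx), replace = TRUE),
        sample(1:12, length(idx), replace = TRUE),
        sample(1:28, length(idx), replace = TRUE)))
      unc <- ifelse(stats::runif(length(idx)) < 0.1, NA_real_,
                    round(stats::rexp(length(idx), rate = 1 / 3000)))
      recs[[t]] <- data.frame(species = config$species,
                              lon = ll$lon, lat = ll$lat,
                              date = dates, uncertainty_m = unc)
    }
    records <- if (length(recs)) do.call(rbind, recs) else
      data.frame(species = character(), lon = numeric(), lat = numeric(),
                 date = as.Date(character()), uncertainty_m = numeric())
    rownames(records) <- NULL
    list(counts = counts, records = records, thinning_prob = p)
  })
}

#' Simulate camera-trap surveys and their detections
#'
#' Places `n_blobs` circular survey footprints at random cells, assigns
#' areas and camera-trap-day efforts, merges overlapping footprints within a
#' period into blobs (via [build_blobs()]), and draws one detection flag per
#' blob, \eqn{y_b \sim Bern\{(1 - e^{-\Lambda_b A_b})(1 - e^{-q E_b})\}},
#' where \eqn{\Lambda_b} is the area-weighted mean true intensity over the
#' blob for its period. When a blob is detected, one of its member surveys
#' is marked as the detecting survey so that blob-level flags can be
#' reconstructed from the survey table by [generate_absences()].
#'
#' @inheritParams simulate_po
#' @return List with `surveys` (data.frame: `survey_id`, `x`, `y`,
#'   `area_km2`, `effort_days`, `start_date`, `end_date`, `species`,
#'   `detected`), `blobs` (a `survey_blobs` object with `y` filled in) and
#'   `detect_prob` (per-blob true detection probability).
#' @export
simulate_surveys <- function(truth, config = truth$config,
                             seed = derive_seed(config$seed, 5)) {
  stopifnot(inherits(truth, "truth_bundle"))
  grid <- truth$grid
  with_seed_local(seed, {
    n <- config$n_blobs
    cell <- sample(nrow(grid$cells), n, replace = TRUE)
    half <- grid$cell_size_km / 2
    sx <- grid$cells$x[cell] + stats::runif(n, -half, half)
    sy <- grid$cells$y[cell] + stats::runif(n, -half, half)
    area <- stats::runif(n, config$survey_area_range[1],
                         config$survey_area_range[2])
    effort <- stats::runif(n, config$effort_range[1], config$effort_range[2])
    period <- sample(1:2, n, replace = TRUE)
    yrs1 <- range(config$period1_years); yrs2 <- range(config$period2_years)
    start_year <- ifelse(period == 1,
                         sample(seq(yrs1[1], yrs1[2]), n, replace = TRUE),
                         sample(seq(yrs2[1], yrs2[2]), n, replace = TRUE))
    surveys <- data.frame(
      survey_id = seq_len(n), x = sx, y = sy, area_km2 = area,
      effort_days = effort,
      start_date = as.Date(sprintf("%d-01-15", start_year)),
      end_date = as.Date(sprintf("%d-11-15", start_year)),
      species = config$species, detected = 0L
    )
    blobs <- build_blobs(surveys,
                         period_split_year = max(config$period1_years))
    q <- config$detection_rate
    pdet <- numeric(length(blobs$blobs))
    for (b in seq_along(blobs$blobs)) {
      bl <- blobs$blobs[[b]]
      w <- disc_union_cell_overlap(bl$discs$x, bl$discs$y, bl$discs$r,
                                   grid$cells$x, grid$cells$y,
                                   grid$cell_size_km)
      if (sum(w) <= 0) stop("blob overlaps no grid cells")
      lam_b <- sum(w * truth$lambda[, bl$period]) / sum(w)
      p_pres <- 1 - exp(-lam_b * bl$area_km2)
      p_det <- 1 - exp(-q * bl$effort_days)
      pdet[b] <- p_pres * p_det
      y <- stats::rbinom(1, 1, pdet[b])
      blobs$blobs[[b]]$y <- y
      if (y == 1) {
        pick <- bl$survey_ids[sample.int(length(bl$survey_ids), 1)]
        surveys$detected[surveys$survey_id == pick] <- 1L
      }
    }
    list(surveys = surveys, blobs = blobs, detect_prob = pdet)
  })
}

#' Simulate a complete study system
#'
#' One call producing everything a full pipeline run needs: grid +
#' covariates, latent truth, presence-only counts and records, and surveyed
#' blobs with detections.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_system` with elements `config`, `grid`,
#'   `truth`, `po` and `pa`.
#' @export
simulate_system <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- build_grid(extent_km = c(0, config$grid_nx * config$cell_size_km,
                                   0, config$grid_ny * config$cell_size_km),
                     cell_size_km = config$cell_size_km)
  grid <- attach_synthetic_covariates(grid, config)
  truth <- simulate_truth(grid, config)
  po <- simulate_po(truth)
  pa <- simulate_surveys(truth)
  structure(list(config = config, grid = truth$grid, truth = truth,
                 po = po, pa = pa),
            class = "sim_system")
}

#' @export
print.sim_system <- function(x, ...) {
  cat(sprintf("<sim_system: %d cells, %d PO records (%d | %d), %d blobs>\n",
              nrow(x$grid$cells), sum(x$po$counts),
              sum(x$po$counts[, 1]), sum(x$po$counts[, 2]),
              length(x$pa$blobs$blobs)))
  invisible(x)
}
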