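# Staged pipeline driver: simulate -> prepare -> covariates -> fit ->
# diagnose -> change, with per-stage file artifacts and manifests.

#' Configure a pipeline run
#'
#' @param out_dir directory receiving stage outputs (created if needed).
#' @param sim a [sim_config()] for the simulate stage.
#' @param model a [model_spec()] for the fit stage.
#' @param min_decimals,max_uncertainty_m presence-only filter settings.
#' @param screen_k,screen_r_max covariate screening settings.
#' @param eps_change neutral-band width for change classification.
#' @param n_predictive posterior predictive draws for diagnostics.
#' @param seed global seed recorded in every manifest and used to derive
#'   stage seeds.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), model = model_spec(),
                            min_decimals = 3, max_uncertainty_m = 25000,
                            screen_k = 4, screen_r_max = 0.6,
                            eps_change = 0.01, n_predictive = 500,
                            seed = 1) {
  stopifnot(inherits(sim, "sim_config"), inherits(model, "model_spec"))
  structure(list(out_dir = out_dir, sim = sim, model = model,
                 min_decimals = min_decimals,
                 max_uncertainty_m = max_uncertainty_m,
                 screen_k = screen_k, screen_r_max = screen_r_max,
                 eps_change = eps_change, n_predictive = n_predictive,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate", "prepare", "covariates", "fit",
                     "diagnose", "change")

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

stage_manifest_path <- function(config, stage) {
  file.path(stage_dir(config, stage), "manifest.json")
}

write_stage_manifest <- function(config, stage, inputs, outputs) {
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("isdmchange")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config_echo(config),
    input_checksums = checksums,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, stage_manifest_path(config, stage),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

config_echo <- function(config) {
  list(sim = unclass(config$sim), model = unclass(config$model),
       min_decimals = config$min_decimals,
       max_uncertainty_m = config$max_uncertainty_m,
       screen_k = config$screen_k, screen_r_max = config$screen_r_max,
       eps_change = config$eps_change, seed = config$seed)
}

require_stage <- function(config, stage) {
  if (!file.exists(stage_manifest_path(config, stage))) {
    stop("missing upstream artifacts: run stage '", stage, "' first")
  }
}

wcsv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

read_grid_artifact <- function(config) {
  cells <- utils::read.csv(file.path(stage_dir(config, "simulate"),
                                     "grid_cells.csv"))
  size <- config$sim$cell_size_km
  structure(list(cells = cells,
                 nx = max(cells$col), ny = max(cells$row),
                 cell_size_km = size,
                 origin = c(min(cells$x) - size / 2, min(cells$y) - size / 2),
                 lon0 = -73.125, lat0 = 0),
            class = "ea_grid")
}

read_blobs_artifact <- function(config) {
  surveys <- utils::read.csv(file.path(stage_dir(config, "simulate"),
                                       "surveys.csv"))
  surveys$start_date <- as.Date(surveys$start_date)
  surveys$end_date <- as.Date(surveys$end_date)
  blobs <- build_blobs(surveys,
                       period_split_year = max(config$sim$period1_years))
  detections <- surveys[surveys$detected == 1, c("survey_id", "species")]
  generate_absences(blobs, detections, species = config$sim$species)
}

stage_simulate <- function(config) {
  dir.create(stage_dir(config, "simulate"), recursive = TRUE,
             showWarnings = FALSE)
  system <- simulate_system(config$sim)
  d <- stage_dir(config, "simulate")
  truth_df <- data.frame(cell_id = system$grid$cells$cell_id,
                         lambda_t1 = system$truth$lambda[, 1],
                         lambda_t2 = system$truth$lambda[, 2],
                         occupancy_t1 = system$truth$occupancy[, 1],
                         occupancy_t2 = system$truth$occupancy[, 2],
                         in_range = system$grid$cells$cell_id %in%
                           system$truth$range_cells)
  files <- file.path(d, c("grid_cells.csv", "po_records.csv", "surveys.csv",
                          "truth.csv"))
  wcsv(system$grid$cells, files[1])
  wcsv(system$po$records, files[2])
  wcsv(system$pa$surveys, files[3])
  wcsv(truth_df, files[4])
  write_stage_manifest(config, "simulate", character(0), files)
  invisible(system)
}

stage_prepare <- function(config) {
  require_stage(config, "simulate")
  dir.create(stage_dir(config, "prepare"), recursive = TRUE,
             showWarnings = FALSE)
  sd_ <- stage_dir(config, "simulate")
  records <- utils::read.csv(file.path(sd_, "po_records.csv"))
  records$date <- as.Date(records$date)
  grid <- read_grid_artifact(config)
  split_year <- max(config$sim$period1_years)
  filtered <- filter_po(records, min_decimals = config$min_decimals,
                        max_uncertainty_m = config$max_uncertainty_m,
                        quiet = TRUE)
  dedup <- deduplicate_po(filtered)
  counts <- grid_po_counts(dedup, grid, period_split_year = split_year)
  rho <- effort_ratio(dedup, period_split_year = split_year)
  blobs <- read_blobs_artifact(config)
  pa_table <- attr(blobs, "pa_table")
  d <- stage_dir(config, "prepare")
  files <- file.path(d, c("po_counts.csv", "pa_table.csv", "prepare.json"))
  wcsv(data.frame(cell_id = grid$cells$cell_id, n_t1 = counts[, 1],
                  n_t2 = counts[, 2]), files[1])
  wcsv(pa_table, files[2])
  jsonlite::write_json(
    list(effort_ratio = rho,
         n_records_raw = nrow(records),
         n_records_filtered = nrow(filtered),
         n_records_dedup = nrow(dedup),
         removed = as.list(attr(filtered, "removed")),
         period_split_year = split_year),
    files[3], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_stage_manifest(config, "prepare",
                       file.path(sd_, c("po_records.csv", "surveys.csv")),
                       files)
  invisible(list(counts = counts, rho = rho, blobs = blobs))
}

stage_covariates <- function(config) {
  require_stage(config, "simulate")
  require_stage(config, "prepare")
  dir.create(stage_dir(config, "covariates"), recursive = TRUE,
             showWarnings = FALSE)
  grid <- read_grid_artifact(config)
  blobs <- read_blobs_artifact(config)
  covnames <- grep("^cov", names(grid$cells), value = TRUE)
  X <- as.matrix(grid$cells[covnames])
  # blob-level covariate averages via area-weighted cell overlap
  pa_table <- attr(blobs, "pa_table")
  bx <- t(vapply(blobs$blobs, function(b) {
    w <- disc_union_cell_overlap(b$discs$x, b$discs$y, b$discs$r,
                                 grid$cells$x, grid$cells$y,
                                 grid$cell_size_km)
    drop(crossprod(X, w / sum(w)))
  }, numeric(length(covnames))))
  colnames(bx) <- covnames
  screen_tab <- cbind(data.frame(y = pa_table$y), as.data.frame(bx))
  k <- min(config$screen_k, length(covnames))
  sc <- screen_covariates(screen_tab, covnames, k = k,
                          r_max = config$screen_r_max,
                          seed = derive_seed(config$seed, 11),
                          cor_data = grid$cells[covnames])
  d <- stage_dir(config, "covariates")
  files <- file.path(d, c("screening.json", "blob_covariates.csv"))
  jsonlite::write_json(list(selected = sc$selected,
                            importance = sc$importance,
                            r_max = sc$r_max),
                       files[1], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  wcsv(cbind(blob_id = pa_table$blob_id, as.data.frame(bx)), files[2])
  write_stage_manifest(config, "covariates",
                       file.path(stage_dir(config, "simulate"),
                                 c("grid_cells.csv", "surveys.csv")),
                       files)
  invisible(sc)
}

assemble_from_artifacts <- function(config) {
  grid <- read_grid_artifact(config)
  counts_df <- utils::read.csv(file.path(stage_dir(config, "prepare"),
                                         "po_counts.csv"))
  counts <- cbind(t1 = counts_df$n_t1, t2 = counts_df$n_t2)
  prep <- jsonlite::read_json(file.path(stage_dir(config, "prepare"),
                                        "prepare.json"), simplifyVector = TRUE)
  screening <- jsonlite::read_json(file.path(stage_dir(config, "covariates"),
                                             "screening.json"),
                                   simplifyVector = TRUE)
  blobs <- read_blobs_artifact(config)
  assemble_isdm_data(grid, counts, blobs, effort_ratio = prep$effort_ratio,
                     covariates = screening$selected,
                     species = config$sim$species)
}

stage_fit <- function(config) {
  for (s in c("simulate", "prepare", "covariates")) require_stage(config, s)
  dir.create(stage_dir(config, "fit"), recursive = TRUE, showWarnings = FALSE)
  data <- assemble_from_artifacts(config)
  spec <- config$model
  spec$seed <- as.integer(derive_seed(config$seed, 21) %% .Machine$integer.max)
  fit <- fit_isdm(data, spec)
  d <- stage_dir(config, "fit")
  tidy <- do.call(rbind, lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    data.frame(chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  files <- file.path(d, c("draws.csv", "fit_summary.csv", "fit.json"))
  wcsv(tidy, files[1])
  wcsv(summary(fit), files[2])
  jsonlite::write_json(
    list(converged = fit$converged, max_rhat = max(fit$rhat),
         min_ess = min(fit$ess), accept_rate = mean(fit$accept_rate),
         n_divergent = sum(fit$n_divergent), seed = spec$seed,
         rhat = as.list(fit$rhat)),
    files[3], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_stage_manifest(config, "fit",
                       file.path(stage_dir(config, "prepare"),
                                 c("po_counts.csv", "pa_table.csv")),
                       files)
  invisible(fit)
}

# Rebuild an isdm_fit from the tidy draws artifact (stages are file-based;
# the reconstruction is exact because the basis and data are deterministic).
fit_from_artifacts <- function(config) {
  data <- assemble_from_artifacts(config)
  spec <- config$model
  spec$seed <- as.integer(derive_seed(config$seed, 21) %% .Machine$integer.max)
  tidy <- utils::read.csv(file.path(stage_dir(config, "fit"), "draws.csv"))
  B <- spline_basis(data$grid$cells[, c("x", "y")], spec$K)
  bsd <- pmax(apply(B, 2, stats::sd), 1e-12)
  lay <- param_layout(ncol(data$X), ncol(B),
                      max(1L, max(data$country)))
  chains <- lapply(sort(unique(tidy$chain)), function(ch) {
    sub <- tidy[tidy$chain == ch, ]
    m <- do.call(cbind, lapply(lay$names, function(p) {
      sub$value[sub$parameter == p][order(sub$draw[sub$parameter == p])]
    }))
    colnames(m) <- lay$names
    m
  })
  rh <- vapply(seq_len(lay$n), function(j) {
    rhat(lapply(chains, function(m) m[, j]))
  }, numeric(1))
  names(rh) <- lay$names
  fitj <- jsonlite::read_json(file.path(stage_dir(config, "fit"), "fit.json"),
                              simplifyVector = TRUE)
  structure(list(chains = chains, draws = do.call(rbind, chains),
                 par_names = lay$names, layout = lay, rhat = rh,
                 ess = rep(NA_real_, lay$n), converged = fitj$converged,
                 accept_rate = fitj$accept_rate, n_divergent = fitj$n_divergent,
                 basis = B, basis_sd = bsd, use_rho = TRUE,
                 spec = spec, data = data),
            class = "isdm_fit")
}

stage_diagnose <- function(config) {
  require_stage(config, "fit")
  dir.create(stage_dir(config, "diagnose"), recursive = TRUE,
             showWarnings = FALSE)
  fit <- fit_from_artifacts(config)
  pam <- tryCatch(evaluate_pa(fit$data$blob_y,
                              colMeans(posterior_pa_prob(fit))),
                  error = function(e) c(auc = NA_real_, tjur_r2 = NA_real_))
  pred <- posterior_predict_po(fit, n_draws = config$n_predictive,
                               seed = derive_seed(config$seed, 31))
  pit <- pit_residuals(fit$data$po_counts, pred,
                       seed = derive_seed(config$seed, 32))
  d <- stage_dir(config, "diagnose")
  files <- file.path(d, "diagnostics.json")
  jsonlite::write_json(
    list(converged = fit$converged, max_rhat = max(fit$rhat),
         auc = unname(pam["auc"]), tjur_r2 = unname(pam["tjur_r2"]),
         pit_ks = pit$ks_stat, pit_p = pit$p_value),
    files, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_stage_manifest(config, "diagnose",
                       file.path(stage_dir(config, "fit"), "draws.csv"),
                       files)
  invisible(list(pa = pam, pit = pit, converged = fit$converged))
}

stage_change <- function(config) {
  require_stage(config, "fit")
  require_stage(config, "diagnose")
  diag <- jsonlite::read_json(file.path(stage_dir(config, "diagnose"),
                                        "diagnostics.json"),
                              simplifyVector = TRUE)
  if (!isTRUE(diag$converged)) {
    stop("model status is 'not converged': species excluded from change analysis")
  }
  dir.create(stage_dir(config, "change"), recursive = TRUE,
             showWarnings = FALSE)
  fit <- fit_from_artifacts(config)
  surface <- occupancy_probability(fit)
  aoo <- area_of_occupancy(surface)
  classes <- classify_change(aoo, eps = config$eps_change)
  d <- stage_dir(config, "change")
  files <- file.path(d, c("change_cells.csv", "change_summary.json"))
  wcsv(data.frame(cell_id = fit$data$grid$cells$cell_id,
                  P_t1 = surface$median[, 1], P_t2 = surface$median[, 2],
                  dP_median = aoo$dP_median, dP_lower = aoo$dP_lower,
                  dP_upper = aoo$dP_upper, class = as.character(classes)),
       files[1])
  jsonlite::write_json(
    list(summary = aoo$summary,
         class_counts = as.list(table(classes)),
         eps_change = config$eps_change),
    files[2], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_stage_manifest(config, "change",
                       file.path(stage_dir(config, "fit"), "draws.csv"),
                       files)
  invisible(list(surface = surface, aoo = aoo, classes = classes))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic system with known truth), `prepare`
#' (filter/deduplicate/grid the presence-only records, build survey blobs
#' with absences, effort ratio), `covariates` (blob covariate averages and
#' tree-based screening), `fit` (the integrated model), `diagnose`
#' (convergence, AUC/Tjur, PIT residuals) and `change` (occupancy, area of
#' occupancy and change classes; refuses fits flagged "not converged").
#' Each stage writes its artifacts plus a manifest (config echo, seed,
#' input checksums) under `out_dir/<stage>/`. Re-running a stage with
#' identical inputs and config reproduces identical outputs.
#'
#' @param stage one of `r paste0('\x60', pipeline_stages, '\x60', collapse = ", ")`.
#' @param config a [pipeline_config()].
#' @return The stage's in-memory result, invisibly.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, pipeline_stages)
  switch(stage,
         simulate = stage_simulate(config),
         prepare = stage_prepare(config),
         covariates = stage_covariates(config),
         fit = stage_fit(config),
         diagnose = stage_diagnose(config),
         change = stage_change(config))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  res <- lapply(pipeline_stages, run_stage, config = config)
  names(res) <- pipeline_stages
  invisible(res)
}
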