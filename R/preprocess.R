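# From raw records and survey tables to model-ready inputs.

count_decimals_chr <- function(s) {
  s <- sub(",", ".", trimws(s), fixed = TRUE)
  has <- grepl("\\.", s)
  n <- integer(length(s))
  n[has] <- nchar(sub("^-?[0-9]*\\.", "", s[has]))
  n
}

# Does a coordinate carry at least `min_decimals` decimal places?
# Textual input: decimals are counted as written (trailing zeros count).
# Numeric input: passes when some digit at or beyond position `min_decimals`
# is non-zero, i.e. value * 10^(min_decimals - 1) is not an integer.
has_min_decimals <- function(value, text = NULL, min_decimals = 3) {
  if (!is.null(text) && is.character(text)) {
    return(count_decimals_chr(text) >= min_decimals)
  }
  scaled <- value * 10^(min_decimals - 1)
  abs(scaled - round(scaled)) > 1e-9 * pmax(1, abs(scaled))
}

#' Filter presence-only records by coordinate precision and uncertainty
#'
#' Keeps records whose latitude AND longitude carry at least `min_decimals`
#' decimal places and whose coordinate uncertainty is missing or at most
#' `max_uncertainty_m` metres (a missing uncertainty cannot assert an
#' excessive one, so it passes). Records with unparseable coordinates are
#' dropped and logged, never fatal. The returned data.frame carries a
#' `removed` attribute with per-rule counts.
#'
#' @param records data.frame with `lon`, `lat` (numeric or character),
#'   optional `uncertainty_m`, and any other columns.
#' @param min_decimals minimum decimal places on each coordinate.
#' @param max_uncertainty_m maximum coordinate uncertainty in metres.
#' @param quiet suppress the per-rule log message.
#' @return The filtered data.frame (coordinates coerced to numeric), with
#'   attribute `removed = c(unparseable, precision, uncertainty)`.
#' @export
filter_po <- function(records, min_decimals = 3, max_uncertainty_m = 25000,
                      quiet = FALSE) {
  stopifnot(is.data.frame(records), all(c("lon", "lat") %in% names(records)))
  lon_txt <- if (is.character(records$lon)) records$lon else NULL
  lat_txt <- if (is.character(records$lat)) records$lat else NULL
  lon <- suppressWarnings(as.numeric(sub(",", ".", records$lon, fixed = TRUE)))
  lat <- suppressWarnings(as.numeric(sub(",", ".", records$lat, fixed = TRUE)))
  parseable <- is.finite(lon) & is.finite(lat) &
    abs(lat) <= 90 & abs(lon) <= 180
  prec_ok <- has_min_decimals(lon, lon_txt, min_decimals) &
    has_min_decimals(lat, lat_txt, min_decimals)
  unc <- if ("uncertainty_m" %in% names(records)) {
    suppressWarnings(as.numeric(records$uncertainty_m))
  } else {
    rep(NA_real_, nrow(records))
  }
  unc_ok <- is.na(unc) | unc <= max_uncertainty_m
  keep <- parseable & prec_ok & unc_ok
  removed <- c(unparseable = sum(!parseable),
               precision = sum(parseable & !prec_ok),
               uncertainty = sum(parseable & prec_ok & !unc_ok))
  if (!quiet && sum(removed) > 0) {
    message(sprintf(
      "filter_po: removed %d records (%d unparseable, %d low precision, %d high uncertainty)",
      sum(removed), removed[1], removed[2], removed[3]))
  }
  out <- records[keep, , drop = FALSE]
  out$lon <- lon[keep]
  out$lat <- lat[keep]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Deduplicate presence-only records
#'
#' One record per unique (species, date, lat, lon) tuple; two observations
#' of the same species at the same location on different dates are
#' independent records and both survive. The result is sorted by the tuple,
#' so it does not depend on the input order.
#'
#' @param records data.frame with `species`, `date`, `lat`, `lon`.
#' @return Deduplicated, deterministically ordered data.frame.
#' @export
deduplicate_po <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("species", "date", "lat", "lon") %in% names(records)))
  if (nrow(records) == 0) return(records)
  o <- order(records$species, records$date, records$lat, records$lon)
  records <- records[o, , drop = FALSE]
  key <- paste(records$species, records$date,
               format(records$lat, digits = 15),
               format(records$lon, digits = 15), sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

record_year <- function(date) {
  as.integer(format(as.Date(date), "%Y"))
}

#' Grid presence-only records into per-cell, per-period counts
#'
#' Projects record coordinates into the grid's plane, assigns each record to
#' a cell and a period (period 1: year <= `period_split_year`; period 2:
#' later years), and tallies counts. Records outside the gridded extent or
#' outside the analysis year window are excluded and reported via
#' attributes `n_outside_extent` and `n_outside_window`.
#'
#' @param records deduplicated records with `lon`, `lat`, `date`.
#' @param grid an `ea_grid`.
#' @param period_split_year last calendar year of period 1.
#' @param year_window inclusive year range of the analysis.
#' @return Integer matrix (cells x 2, columns `t1`, `t2`), with exclusion
#'   counts as attributes.
#' @export
grid_po_counts <- function(records, grid, period_split_year,
                           year_window = c(period_split_year - 13,
                                           period_split_year + 8)) {
  stopifnot(inherits(grid, "ea_grid"))
  n_cells <- nrow(grid$cells)
  counts <- matrix(0L, n_cells, 2, dimnames = list(NULL, c("t1", "t2")))
  if (nrow(records) == 0) {
    attr(counts, "n_outside_extent") <- 0L
    attr(counts, "n_outside_window") <- 0L
    return(counts)
  }
  yr <- record_year(records$date)
  in_window <- !is.na(yr) & yr >= year_window[1] & yr <= year_window[2]
  pr <- laea_project(records$lon, records$lat,
                     lon0 = grid$lon0, lat0 = grid$lat0)
  cell <- grid_cell_index(grid, pr$x, pr$y)
  in_extent <- !is.na(cell)
  keep <- in_window & in_extent
  period <- ifelse(yr <= period_split_year, 1L, 2L)
  for (t in 1:2) {
    tab <- table(factor(cell[keep & period == t], levels = seq_len(n_cells)))
    counts[, t] <- counts[, t] + as.integer(tab)
  }
  attr(counts, "n_outside_extent") <- sum(in_window & !in_extent)
  attr(counts, "n_outside_window") <- sum(!in_window)
  counts
}

survey_period <- function(start_date, end_date, period_split_year) {
  mid <- as.Date(start_date) + floor((as.Date(end_date) - as.Date(start_date)) / 2)
  ifelse(record_year(mid) <= period_split_year, 1L, 2L)
}

#' Merge camera-trap surveys into per-period blobs
#'
#' Each survey becomes a disc of radius `sqrt(area / pi)` at its centroid;
#' overlapping discs within a period are unioned into "blobs". A blob's area
#' is the area of the union, its effort the sum of member efforts, and its
#' time span the union of member spans. Surveys spanning the period boundary
#' are assigned to the period containing their midpoint. Surveys with
#' missing effort are rejected with a log message; non-positive survey areas
#' are an error.
#'
#' @param surveys data.frame with projected centroids `x`, `y` (km) or
#'   `lon`, `lat` columns, `area_km2`, `effort_days`, `start_date`,
#'   `end_date`; any `survey_id` column is preserved (else row numbers).
#' @param period_split_year last calendar year of period 1.
#' @param lon0,lat0 projection centre used when only `lon`/`lat` given.
#' @return An object of class `survey_blobs`: list of blobs (each with
#'   `blob_id`, `period`, member `discs` and `survey_ids`, union `area_km2`,
#'   summed `effort_days`, `start_date`, `end_date`, detection flags `y`
#'   once attached) plus the split year.
#' @export
build_blobs <- function(surveys, period_split_year, lon0 = -73.125, lat0 = 0) {
  stopifnot(is.data.frame(surveys))
  if (!all(c("x", "y") %in% names(surveys))) {
    stopifnot(all(c("lon", "lat") %in% names(surveys)))
    pr <- laea_project(surveys$lon, surveys$lat, lon0 = lon0, lat0 = lat0)
    surveys$x <- pr$x; surveys$y <- pr$y
  }
  need <- c("area_km2", "effort_days", "start_date", "end_date")
  stopifnot(all(need %in% names(surveys)))
  if (!"survey_id" %in% names(surveys)) surveys$survey_id <- seq_len(nrow(surveys))
  if (any(!is.finite(surveys$area_km2) | surveys$area_km2 <= 0)) {
    stop("surveys with non-positive area")
  }
  missing_e <- !is.finite(suppressWarnings(as.numeric(surveys$effort_days)))
  if (any(missing_e)) {
    message(sprintf("build_blobs: rejected %d survey(s) with missing effort",
                    sum(missing_e)))
    surveys <- surveys[!missing_e, , drop = FALSE]
  }
  if (nrow(surveys) == 0) {
    return(structure(list(blobs = list(),
                          period_split_year = period_split_year),
                     class = "survey_blobs"))
  }
  surveys$radius_km <- sqrt(surveys$area_km2 / pi)
  surveys$period <- survey_period(surveys$start_date, surveys$end_date,
                                  period_split_year)
  blobs <- list()
  for (t in 1:2) {
    s <- surveys[surveys$period == t, , drop = FALSE]
    if (nrow(s) == 0) next
    # union-find over pairwise disc overlaps
    parent <- seq_len(nrow(s))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(s))) for (j in seq_len(i - 1L)) {
      if (sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2) <
          s$radius_km[i] + s$radius_km[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    comp <- vapply(seq_len(nrow(s)), find, integer(1))
    for (g in unique(comp)) {
      m <- s[comp == g, , drop = FALSE]
      m <- m[order(m$survey_id), , drop = FALSE]
      blobs[[length(blobs) + 1]] <- list(
        period = t,
        discs = data.frame(x = m$x, y = m$y, r = m$radius_km),
        survey_ids = m$survey_id,
        area_km2 = disc_union_area(m$x, m$y, m$radius_km),
        effort_days = sum(m$effort_days),
        start_date = min(as.Date(m$start_date)),
        end_date = max(as.Date(m$end_date)),
        y = NA_integer_
      )
    }
  }
  # deterministic order regardless of input permutation
  o <- order(vapply(blobs, `[[`, integer(1), "period"),
             vapply(blobs, function(b) min(b$discs$x), numeric(1)),
             vapply(blobs, function(b) min(b$discs$y), numeric(1)))
  blobs <- blobs[o]
  for (i in seq_along(blobs)) blobs[[i]]$blob_id <- i
  structure(list(blobs = blobs, period_split_year = period_split_year),
            class = "survey_blobs")
}

#' @export
print.survey_blobs <- function(x, ...) {
  per <- vapply(x$blobs, `[[`, integer(1), "period")
  cat(sprintf("<survey_blobs: %d blobs (%d in period 1, %d in period 2)>\n",
              length(x$blobs), sum(per == 1), sum(per == 2)))
  invisible(x)
}

#' Attach per-species detection flags (and hence absences) to blobs
#'
#' A blob detects a species when any of its member surveys did; otherwise
#' the blob contributes an absence for that species.
#'
#' @param blobs a [build_blobs()] result.
#' @param detections data.frame of detection events with `survey_id` and
#'   `species` columns.
#' @param species character vector of study species; every species occurring
#'   in `detections` must be listed.
#' @return `blobs` with each blob's `y` set to a named 0/1 vector over
#'   `species`, plus a tidy `pa_table` attribute (blob_id, period, area,
#'   effort, species, y).
#' @export
generate_absences <- function(blobs, detections, species) {
  stopifnot(inherits(blobs, "survey_blobs"))
  stopifnot(is.data.frame(detections) || is.null(detections))
  if (!is.null(detections) && nrow(detections) > 0) {
    unknown <- setdiff(unique(detections$species), species)
    if (length(unknown)) {
      stop("detections for species not in the species list: ",
           paste(unknown, collapse = ", "))
    }
  }
  rows <- list()
  for (i in seq_along(blobs$blobs)) {
    b <- blobs$blobs[[i]]
    y <- stats::setNames(integer(length(species)), species)
    if (!is.null(detections) && nrow(detections) > 0) {
      det <- detections$species[detections$survey_id %in% b$survey_ids]
      y[unique(det)] <- 1L
    }
    blobs$blobs[[i]]$y <- y
    rows[[i]] <- data.frame(blob_id = b$blob_id, period = b$period,
                            area_km2 = b$area_km2,
                            effort_days = b$effort_days,
                            species = species, y = as.integer(y),
                            row.names = NULL)
  }
  attr(blobs, "pa_table") <- if (length(rows)) do.call(rbind, rows) else
    data.frame(blob_id = integer(), period = integer(), area_km2 = numeric(),
               effort_days = numeric(), species = character(), y = integer())
  blobs
}

#' Presence-only sampling-effort ratio between periods
#'
#' The ratio of period-2 to period-1 record totals pooled over all study
#' species. It calibrates the period-2 presence-only observation process so
#' that growth in recording effort is not mistaken for range expansion.
#'
#' @param x either a length-2 numeric vector of pooled record totals
#'   `c(period1, period2)`, or a records data.frame with a `date` column.
#' @param period_split_year required when `x` is a data.frame.
#' @return The scalar ratio `rho`.
#' @export
#' @examples
#' effort_ratio(c(100, 127))  # 1.27
effort_ratio <- function(x, period_split_year = NULL) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(period_split_year), "date" %in% names(x))
    yr <- record_year(x$date)
    x <- c(sum(yr <= period_split_year, na.rm = TRUE),
           sum(yr > period_split_year, na.rm = TRUE))
  }
  stopifnot(is.numeric(x), length(x) == 2)
  if (x[1] <= 0) stop("no period-1 records: effort ratio undefined")
  unname(x[2] / x[1])
}

#' Assemble aligned model inputs
#'
#' Binds the gridded presence-only counts, the surveyed blobs (with
#' detection flags for one focal species), the blob-to-cell overlap weights
#' and blob covariate averages, and the effort ratio into the single
#' container the model fitter consumes. The grid must already carry the
#' covariate columns, `access`, `country` and `dist_range_km`.
#'
#' @param grid an `ea_grid` with covariates attached.
#' @param po_counts cells x 2 count matrix from [grid_po_counts()].
#' @param blobs a `survey_blobs` with `y` attached (for the focal species a
#'   scalar, or a named vector from which `species` selects the flag).
#' @param effort_ratio scalar rho.
#' @param covariates character vector of covariate column names to model.
#' @param species focal species name (used when blob `y` is a named vector).
#' @return An object of class `isdm_data`.
#' @export
assemble_isdm_data <- function(grid, po_counts, blobs, effort_ratio,
                               covariates = grep("^cov", names(grid$cells),
                                                 value = TRUE),
                               species = NULL) {
  stopifnot(inherits(grid, "ea_grid"), inherits(blobs, "survey_blobs"))
  need <- c(covariates, "access", "country", "dist_range_km")
  missing_cols <- setdiff(need, names(grid$cells))
  if (length(missing_cols)) {
    stop("grid lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  n_cells <- nrow(grid$cells)
  stopifnot(nrow(po_counts) == n_cells, ncol(po_counts) == 2,
            all(po_counts >= 0))
  if (effort_ratio <= 0) stop("effort_ratio must be positive")
  nb <- length(blobs$blobs)
  W <- matrix(0, nb, n_cells)
  blob_area <- blob_effort <- numeric(nb)
  blob_period <- integer(nb)
  blob_y <- integer(nb)
  for (b in seq_len(nb)) {
    bl <- blobs$blobs[[b]]
    w <- disc_union_cell_overlap(bl$discs$x, bl$discs$y, bl$discs$r,
                                 grid$cells$x, grid$cells$y,
                                 grid$cell_size_km)
    if (sum(w) <= 0) stop("blob ", b, " overlaps no grid cells")
    W[b, ] <- w / sum(w)
    blob_area[b] <- bl$area_km2
    blob_effort[b] <- bl$effort_days
    blob_period[b] <- bl$period
    yb <- bl$y
    if (length(yb) > 1 || !is.null(names(yb))) {
      stopifnot(!is.null(species), species %in% names(yb))
      yb <- yb[[species]]
    }
    blob_y[b] <- as.integer(yb)
  }
  X <- as.matrix(grid$cells[covariates])
  structure(list(
    grid = grid,
    covariates = covariates,
    X = X,
    D = grid$cells$dist_range_km / 1000,  # per 1000 km in the predictor
    access = grid$cells$access,
    country = as.integer(grid$cells$country),
    area = grid$cells$area_km2,
    po_counts = po_counts,
    blobs = blobs,
    blob_W = W,
    blob_X = W %*% X,
    blob_area = blob_area,
    blob_effort = blob_effort,
    blob_period = blob_period,
    blob_y = blob_y,
    effort_ratio = effort_ratio,
    species = species %||% "species"
  ), class = "isdm_data")
}

#' @export
print.isdm_data <- function(x, ...) {
  cat(sprintf("<isdm_data: %d cells, PO counts %d | %d, %d blobs (%d det.), rho = %.3f>\n",
              nrow(x$grid$cells), sum(x$po_counts[, 1]), sum(x$po_counts[, 2]),
              length(x$blob_y), sum(x$blob_y), x$effort_ratio))
  invisible(x)
}
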