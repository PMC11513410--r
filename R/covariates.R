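# Environmental, thinning and range-distance covariates.

#' A stack of aligned raster layers
#'
#' Minimal in-memory raster container used by [zonal_average()]: named
#' layers on a common regular lattice in the projected plane. Each layer is
#' a matrix indexed `[iy, ix]` with row 1 at `ymin` (south) and column 1 at
#' `xmin` (west).
#'
#' @param layers named list of equally sized numeric matrices.
#' @param xmin,ymin lower-left corner of the lattice (km).
#' @param res_km raster cell size (km).
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, xmin, ymin, res_km) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)),
            res_km > 0)
  dims <- lapply(layers, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    stop("all layers must share extent and resolution")
  }
  structure(list(layers = layers, xmin = xmin, ymin = ymin, res_km = res_km,
                 ny = nrow(layers[[1]]), nx = ncol(layers[[1]])),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack: %d layer(s) [%s], %d x %d cells of %g km>\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$nx, x$ny, x$res_km))
  invisible(x)
}

# Overlap area between one raster cell rectangle and a unit that is either
# a rectangle (grid cell) or a union of discs (blob).
unit_raster_overlap <- function(unit, rect) {
  if (unit$type == "rect") {
    w <- max(0, min(unit$xmax, rect[2]) - max(unit$xmin, rect[1]))
    h <- max(0, min(unit$ymax, rect[4]) - max(unit$ymin, rect[3]))
    w * h
  } else {
    disc_union_area(unit$x, unit$y, unit$r, clip = rect, n_steps = 120L)
  }
}

zonal_average_unit <- function(stack, unit) {
  # raster index window covering the unit's bbox
  bb <- if (unit$type == "rect") {
    c(unit$xmin, unit$xmax, unit$ymin, unit$ymax)
  } else {
    c(min(unit$x - unit$r), max(unit$x + unit$r),
      min(unit$y - unit$r), max(unit$y + unit$r))
  }
  ix <- max(1, floor((bb[1] - stack$xmin) / stack$res_km) + 1):
    min(stack$nx, ceiling((bb[2] - stack$xmin) / stack$res_km))
  iy <- max(1, floor((bb[3] - stack$ymin) / stack$res_km) + 1):
    min(stack$ny, ceiling((bb[4] - stack$ymin) / stack$res_km))
  if (length(ix) == 0 || length(iy) == 0 || ix[1] > rev(ix)[1] ||
      iy[1] > rev(iy)[1]) {
    return(list(values = rep(NA_real_, length(stack$layers)), missing = 1))
  }
  cells <- expand.grid(ix = ix, iy = iy)
  w <- vapply(seq_len(nrow(cells)), function(r) {
    rect <- c(stack$xmin + (cells$ix[r] - 1) * stack$res_km,
              stack$xmin + cells$ix[r] * stack$res_km,
              stack$ymin + (cells$iy[r] - 1) * stack$res_km,
              stack$ymin + cells$iy[r] * stack$res_km)
    unit_raster_overlap(unit, rect)
  }, numeric(1))
  vals <- vapply(stack$layers, function(L) {
    v <- L[cbind(cells$iy, cells$ix)]
    ok <- w > 0 & !is.na(v)
    if (!any(ok)) NA_real_ else sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
  miss <- vapply(stack$layers, function(L) {
    v <- L[cbind(cells$iy, cells$ix)]
    if (sum(w) == 0) 1 else sum(w[is.na(v)]) / sum(w)
  }, numeric(1))
  list(values = vals, missing = max(miss))
}

#' Area-weighted zonal averages of raster layers
#'
#' Averages every layer of a [covariate_stack()] over each unit (grid cells
#' of an `ea_grid`, or the blobs of a `survey_blobs`), weighting raster
#' cells by their overlap area with the unit. Raster cells with missing
#' values are excluded from the weights; a unit with no data at all gets
#' `NA` and is flagged.
#'
#' @param stack a `covariate_stack`.
#' @param units an `ea_grid` or a `survey_blobs` object.
#' @return A data.frame keyed by `cell_id` or `blob_id` with one column per
#'   layer and a `missing_frac` column.
#' @export
zonal_average <- function(stack, units) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (inherits(units, "ea_grid")) {
    h <- units$cell_size_km / 2
    ulist <- lapply(seq_len(nrow(units$cells)), function(i) {
      list(type = "rect",
           xmin = units$cells$x[i] - h, xmax = units$cells$x[i] + h,
           ymin = units$cells$y[i] - h, ymax = units$cells$y[i] + h)
    })
    ids <- data.frame(cell_id = units$cells$cell_id)
  } else if (inherits(units, "survey_blobs")) {
    ulist <- lapply(units$blobs, function(b) {
      list(type = "discs", x = b$discs$x, y = b$discs$y, r = b$discs$r)
    })
    ids <- data.frame(blob_id = vapply(units$blobs, `[[`, integer(1),
                                       "blob_id"))
  } else {
    stop("units must be an ea_grid or survey_blobs")
  }
  res <- lapply(ulist, function(u) zonal_average_unit(stack, u))
  vals <- do.call(rbind, lapply(res, `[[`, "values"))
  colnames(vals) <- names(stack$layers)
  out <- cbind(ids, as.data.frame(vals),
               missing_frac = vapply(res, `[[`, numeric(1), "missing"))
  flagged <- which(!is.finite(rowSums(vals)))
  if (length(flagged)) {
    message("zonal_average: ", length(flagged),
            " unit(s) with fully missing data flagged")
  }
  out
}

#' Distance from cell centroids to an expert range polygon
#'
#' Zero for centroids inside or on the boundary of the range; otherwise the
#' Euclidean distance (km, projected plane) to the nearest range edge.
#'
#' @param grid an `ea_grid`.
#' @param range_polygon a [rect_union()] polygon.
#' @return Numeric vector of distances in km, one per cell.
#' @export
distance_to_range <- function(grid, range_polygon) {
  stopifnot(inherits(grid, "ea_grid"))
  if (!inherits(range_polygon, "rect_union") ||
      length(range_polygon$xmin) == 0) {
    stop("range_polygon must be a non-empty rect_union")
  }
  dist_to_rect_union(grid$cells$x, grid$cells$y, range_polygon)
}

#' Pre-screen candidate covariates against presence/absence data
#'
#' Ranks candidates by permutation importance from a random forest fit to
#' the raw presence/absence response (both periods pooled), then accepts
#' them greedily in rank order, skipping any candidate whose absolute
#' Pearson correlation with an already accepted one exceeds `r_max`, until
#' `k` are accepted. Ties in importance are broken by rank order and then
#' by name.
#'
#' @param pa_table data.frame with a binary `y` column and the candidate
#'   columns.
#' @param candidates character vector of candidate column names.
#' @param k number of covariates to keep.
#' @param r_max maximum pairwise |Pearson r| among the selected set.
#' @param seed integer seed for the forest.
#' @param num_trees forest size.
#' @param cor_data optional data.frame holding the candidate columns on
#'   which the correlation matrix is computed (for example the cell-level
#'   covariate table, whose correlations are estimated over many more units
#'   than the survey blobs); defaults to `pa_table`.
#' @return An object of class `screening_result`: list with `importance`
#'   (ranked data.frame), `selected` (length-k character), `cor_matrix`, and
#'   the settings.
#' @export
screen_covariates <- function(pa_table, candidates, k = 4, r_max = 0.6,
                              seed = 1, num_trees = 500,
                              cor_data = pa_table) {
  stopifnot(is.data.frame(pa_table), "y" %in% names(pa_table),
            all(candidates %in% names(pa_table)), length(candidates) >= k,
            all(candidates %in% names(cor_data)))
  y <- pa_table$y
  stopifnot(all(y %in% c(0, 1)))
  Xc <- pa_table[candidates]
  fit <- ranger::ranger(
    x = Xc, y = factor(y), importance = "permutation",
    num.trees = num_trees, seed = as.integer(seed),
    probability = FALSE
  )
  imp <- fit$variable.importance[candidates]
  ord <- order(-imp, seq_along(candidates), candidates)
  ranked <- data.frame(candidate = candidates[ord],
                       importance = unname(imp[ord]))
  r <- stats::cor(as.matrix(cor_data[candidates]))
  selected <- character(0)
  conflicts <- list()
  for (cand in ranked$candidate) {
    if (length(selected) == k) break
    clash <- selected[abs(r[cand, selected]) > r_max]
    if (length(clash) == 0) {
      selected <- c(selected, cand)
    } else {
      conflicts[[cand]] <- clash
    }
  }
  if (length(selected) < k) {
    msg <- paste(vapply(names(conflicts), function(nm) {
      paste0(nm, " ~ {", paste(conflicts[[nm]], collapse = ", "), "}")
    }, character(1)), collapse = "; ")
    stop("cannot select ", k, " covariates under |r| <= ", r_max,
         "; conflict graph: ", msg)
  }
  structure(list(importance = ranked, selected = selected,
                 cor_matrix = r, k = k, r_max = r_max, seed = seed),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result: selected %s (k = %d, |r| <= %.2f)>\n",
              paste(x$selected, collapse = ", "), x$k, x$r_max))
  invisible(x)
}
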