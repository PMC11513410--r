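# The equal-area analysis lattice.

#' Build an equal-area analysis grid
#'
#' Lays out square cells of side `cell_size_km` in the projected plane
#' (Lambert azimuthal equal-area; see [laea_project()]) covering a
#' rectangular extent. The extent may be given directly in projected km
#' (`extent_km`) or as a geographic bounding box (`extent_lonlat`), in which
#' case its corners are projected first and the enclosing projected
#' rectangle is gridded. Cells are laid out from the lower-left corner;
#' partial cells at the top/right edges are included (their nominal area is
#' still `cell_size_km^2` — the lattice is conceptually infinite and the
#' extent merely selects cells).
#'
#' @param extent_km numeric `c(xmin, xmax, ymin, ymax)` in projected km.
#' @param extent_lonlat numeric `c(lonmin, lonmax, latmin, latmax)` degrees;
#'   used only when `extent_km` is missing.
#' @param cell_size_km cell side length in km (default 100).
#' @param lon0,lat0 projection centre (decimal degrees).
#' @return An object of class `ea_grid`: a list with `cells` (a data.frame
#'   with `cell_id`, `row`, `col`, centroid `x`, `y` in km and `area_km2`),
#'   the lattice dimensions `nx`, `ny`, `cell_size_km`, the origin and the
#'   projection centre. Covariates, accessibility, country and
#'   distance-to-range columns are attached to `cells` by later stages.
#' @export
#' @examples
#' g <- build_grid(extent_km = c(0, 400, 0, 300))
#' nrow(g$cells)  # 12 cells
build_grid <- function(extent_km = NULL, extent_lonlat = NULL,
                       cell_size_km = 100, lon0 = -73.125, lat0 = 0) {
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      cell_size_km <= 0) {
    stop("cell_size_km must be a positive scalar")
  }
  if (is.null(extent_km)) {
    if (is.null(extent_lonlat)) stop("provide extent_km or extent_lonlat")
    corners <- expand.grid(lon = extent_lonlat[1:2], lat = extent_lonlat[3:4])
    pr <- laea_project(corners$lon, corners$lat, lon0 = lon0, lat0 = lat0)
    extent_km <- c(min(pr$x), max(pr$x), min(pr$y), max(pr$y))
  }
  stopifnot(length(extent_km) == 4)
  if (extent_km[2] <= extent_km[1] || extent_km[4] <= extent_km[3]) {
    stop("degenerate extent")
  }
  nx <- max(1L, ceiling((extent_km[2] - extent_km[1]) / cell_size_km - 1e-9))
  ny <- max(1L, ceiling((extent_km[4] - extent_km[3]) / cell_size_km - 1e-9))
  ij <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  cells <- data.frame(
    cell_id = seq_len(nrow(ij)),
    row = ij$row, col = ij$col,
    x = extent_km[1] + (ij$col - 0.5) * cell_size_km,
    y = extent_km[3] + (ij$row - 0.5) * cell_size_km,
    area_km2 = cell_size_km^2
  )
  structure(list(cells = cells, nx = nx, ny = ny,
                 cell_size_km = cell_size_km,
                 origin = extent_km[c(1, 3)],
                 lon0 = lon0, lat0 = lat0),
            class = "ea_grid")
}

#' @export
print.ea_grid <- function(x, ...) {
  extras <- setdiff(names(x$cells),
                    c("cell_id", "row", "col", "x", "y", "area_km2"))
  cat(sprintf("<ea_grid: %d x %d cells of %g km (%d cells)>\n",
              x$nx, x$ny, x$cell_size_km, nrow(x$cells)))
  if (length(extras)) cat("  attached:", paste(extras, collapse = ", "), "\n")
  invisible(x)
}

# Map projected points to cell ids; NA for points outside the gridded extent.
grid_cell_index <- function(grid, px, py) {
  stopifnot(inherits(grid, "ea_grid"))
  col <- floor((px - grid$origin[1]) / grid$cell_size_km) + 1
  row <- floor((py - grid$origin[2]) / grid$cell_size_km) + 1
  ok <- col >= 1 & col <= grid$nx & row >= 1 & row <= grid$ny &
    is.finite(col) & is.finite(row)
  id <- rep(NA_integer_, length(px))
  id[ok] <- (row[ok] - 1) * grid$nx + col[ok]
  id
}

# The square polygon of one cell, as xmin/xmax/ymin/ymax.
cell_rect <- function(grid, cell_id) {
  cc <- grid$cells[match(cell_id, grid$cells$cell_id), ]
  h <- grid$cell_size_km / 2
  cbind(xmin = cc$x - h, xmax = cc$x + h, ymin = cc$y - h, ymax = cc$y + h)
}

# Union-of-cells polygon for a set of cell ids.
cells_to_polygon <- function(grid, cell_ids) {
  if (length(cell_ids) == 0) stop("empty cell set")
  r <- cell_rect(grid, cell_ids)
  rect_union(r[, "xmin"], r[, "xmax"], r[, "ymin"], r[, "ymax"])
}
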