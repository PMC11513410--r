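# Planar geometry and equal-area projection primitives.
#
# The analysis lattice lives in a projected plane (km). Grid cells are
# axis-aligned squares, expert ranges are unions of cell squares, and
# camera-trap surveys are discs; everything downstream only needs a handful
# of closed-form operations on those shapes, implemented here.

EARTH_RADIUS_KM <- 6371.0088

#' Lambert azimuthal equal-area projection (spherical)
#'
#' Forward projection of geographic coordinates onto the plane tangent at
#' `(lon0, lat0)`, in kilometres. The default centre (latitude 0, longitude
#' -73.125) is the conventional centre for Neotropical equal-area grids.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @param lon0,lat0 projection centre in decimal degrees.
#' @return A data.frame with columns `x`, `y` in km.
#' @seealso [laea_inverse()]
#' @export
#' @examples
#' laea_project(-73.125, 0)  # the centre maps to (0, 0)
laea_project <- function(lon, lat, lon0 = -73.125, lat0 = 0) {
  stopifnot(is.numeric(lon), is.numeric(lat))
  if (length(lon) != length(lat)) {
    if (length(lon) == 1) lon <- rep(lon, length(lat))
    else if (length(lat) == 1) lat <- rep(lat, length(lon))
    else stop("lon and lat lengths differ")
  }
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 360, na.rm = TRUE)) {
    stop("geographic coordinates out of range")
  }
  rad <- pi / 180
  phi <- lat * rad; phi0 <- lat0 * rad
  dlam <- (lon - lon0) * rad
  # k' = sqrt(2 / (1 + sin(phi0)sin(phi) + cos(phi0)cos(phi)cos(dlam)))
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  kp <- sqrt(2 / denom)
  data.frame(
    x = EARTH_RADIUS_KM * kp * cos(phi) * sin(dlam),
    y = EARTH_RADIUS_KM * kp * (cos(phi0) * sin(phi) -
                                  sin(phi0) * cos(phi) * cos(dlam))
  )
}

#' Inverse Lambert azimuthal equal-area projection (spherical)
#'
#' @param x,y projected coordinates in km.
#' @inheritParams laea_project
#' @return A data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
laea_inverse <- function(x, y, lon0 = -73.125, lat0 = 0) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  rad <- pi / 180
  phi0 <- lat0 * rad
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  lat <- ifelse(rho < 1e-12, lat0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho) / rad)
  lon <- ifelse(rho < 1e-12, lon0,
                lon0 + atan2(x * sin(cc),
                             rho * cos(phi0) * cos(cc) -
                               y * sin(phi0) * sin(cc)) / rad)
  data.frame(lon = lon, lat = lat)
}

# --- rectangle unions (cell polygons, expert ranges) -------------------------

#' Construct a rectangle-union polygon
#'
#' Regions built from grid cells (for example pseudo-expert range maps) are
#' represented as unions of axis-aligned rectangles in the projected plane.
#'
#' @param xmin,xmax,ymin,ymax numeric vectors (one entry per rectangle), km.
#' @return An object of class `rect_union`.
#' @export
rect_union <- function(xmin, xmax, ymin, ymax) {
  stopifnot(length(xmin) == length(xmax), length(xmin) == length(ymin),
            length(xmin) == length(ymax))
  if (length(xmin) == 0) stop("empty polygon")
  if (any(xmax <= xmin) || any(ymax <= ymin)) stop("degenerate rectangle")
  structure(list(xmin = as.numeric(xmin), xmax = as.numeric(xmax),
                 ymin = as.numeric(ymin), ymax = as.numeric(ymax)),
            class = "rect_union")
}

#' @export
print.rect_union <- function(x, ...) {
  cat(sprintf("<rect_union: %d rectangle(s), bbox [%.1f, %.1f] x [%.1f, %.1f] km>\n",
              length(x$xmin), min(x$xmin), max(x$xmax), min(x$ymin), max(x$ymax)))
  invisible(x)
}

#' Point-in-polygon test for rectangle unions
#'
#' Boundary points count as inside.
#'
#' @param px,py point coordinates (km).
#' @param poly a [rect_union()].
#' @return Logical vector.
#' @export
point_in_rect_union <- function(px, py, poly) {
  stopifnot(inherits(poly, "rect_union"))
  inside <- rep(FALSE, length(px))
  for (r in seq_along(poly$xmin)) {
    inside <- inside | (px >= poly$xmin[r] & px <= poly$xmax[r] &
                          py >= poly$ymin[r] & py <= poly$ymax[r])
  }
  inside
}

#' Distance from points to a rectangle-union polygon
#'
#' Zero for points inside or on the boundary, otherwise the Euclidean
#' distance to the nearest rectangle.
#'
#' @inheritParams point_in_rect_union
#' @return Numeric vector of distances (km).
#' @export
dist_to_rect_union <- function(px, py, poly) {
  stopifnot(inherits(poly, "rect_union"))
  d <- rep(Inf, length(px))
  for (r in seq_along(poly$xmin)) {
    dx <- pmax(poly$xmin[r] - px, 0, px - poly$xmax[r])
    dy <- pmax(poly$ymin[r] - py, 0, py - poly$ymax[r])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

# --- disc unions (survey blobs) ----------------------------------------------

# Total length of the union of 1-D intervals [starts, ends].
interval_union_length <- function(starts, ends) {
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Area of a union of discs, optionally clipped to a rectangle
#'
#' Computes the area of the union of discs by quadrature along x: at each
#' abscissa the union of y-chords is resolved exactly as a union of
#' intervals, so only the x-integration is approximate. Accuracy is
#' controlled by `n_steps` (midpoint rule; error is O(n_steps^-2) away from
#' tangencies).
#'
#' @param x,y,r disc centres and radii (km); `r > 0`.
#' @param clip optional clipping rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param n_steps number of quadrature columns.
#' @return Area in km^2.
#' @export
disc_union_area <- function(x, y, r, clip = NULL, n_steps = 2000L) {
  stopifnot(length(x) == length(y), length(x) == length(r))
  if (length(x) == 0) return(0)
  if (any(r <= 0)) stop("disc radii must be positive")
  lo <- min(x - r); hi <- max(x + r)
  if (!is.null(clip)) {
    lo <- max(lo, clip[1]); hi <- min(hi, clip[2])
    if (hi <= lo) return(0)
  }
  h <- (hi - lo) / n_steps
  xs <- lo + (seq_len(n_steps) - 0.5) * h
  area <- 0
  for (xi in xs) {
    dx2 <- r^2 - (xi - x)^2
    hit <- dx2 > 0
    if (!any(hit)) next
    half <- sqrt(dx2[hit])
    ys <- y[hit] - half; ye <- y[hit] + half
    if (!is.null(clip)) {
      ys <- pmax(ys, clip[3]); ye <- pmin(ye, clip[4])
    }
    area <- area + interval_union_length(ys, ye)
  }
  area * h
}

# Fraction of each grid-cell square covered by a union of discs, given cell
# centroids and size; returns a sparse-ish numeric vector over cells.
disc_union_cell_overlap <- function(x, y, r, cell_x, cell_y, cell_size,
                                    n_steps = 200L) {
  half <- cell_size / 2
  near <- vapply(seq_along(cell_x), function(i) {
    any(sqrt((cell_x[i] - x)^2 + (cell_y[i] - y)^2) <= r + half * sqrt(2))
  }, logical(1))
  out <- numeric(length(cell_x))
  for (i in which(near)) {
    clip <- c(cell_x[i] - half, cell_x[i] + half,
              cell_y[i] - half, cell_y[i] + half)
    out[i] <- disc_union_area(x, y, r, clip = clip, n_steps = n_steps)
  }
  out
}
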