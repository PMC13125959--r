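#' Define a regular geographic modelling grid
#'
#' Builds the lattice on which all rasters, occurrence aggregation and model
#' projection operate. Cells are registered by their centers, row 1 is the
#' northernmost row, and point-to-cell assignment uses half-open intervals
#' `[edge, edge + resolution)` in both longitude and latitude, so a point on
#' an interior edge belongs to the east/north cell and points on the extreme
#' east/north boundary fall outside the grid.
#'
#' If the extent is not an integer multiple of `resolution` it is expanded
#' outward (east/north) to the next multiple.
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param resolution Cell size in degrees (default 0.1, the modelling grid
#'   used throughout the package).
#' @return A `grid_spec` object.
#' @examples
#' g <- make_grid(73, 135, 18, 54, 0.1)  # 360 rows x 620 cols
#' @export
make_grid <- function(lon_min, lon_max, lat_min, lat_max, resolution = 0.1) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number")
  if (lon_max <= lon_min) stop("inverted extent: lon_max must exceed lon_min")
  if (lat_max <= lat_min) stop("inverted extent: lat_max must exceed lat_min")
  if (lat_min < -90 || lat_max > 90) stop("latitude bounds must lie in [-90, 90]")

  snap_count <- function(span) {
    n <- span / resolution
    if (abs(n - round(n)) < 1e-8) round(n) else ceiling(n - 1e-8)
  }
  n_cols <- snap_count(lon_max - lon_min)
  n_rows <- snap_count(lat_max - lat_min)
  lon_max <- lon_min + n_cols * resolution
  lat_max <- lat_min + n_rows * resolution
  if (lat_max > 90 + 1e-9)
    stop("extent expansion pushed lat_max above 90; choose a compatible resolution")

  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         resolution = resolution,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs = "geographic lon/lat, spherical datum R = 6371 km"),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols at %g deg\n  lon [%g, %g]  lat [%g, %g]\n",
              x$n_rows, x$n_cols, x$resolution,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lat_min - b$lat_min) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Longitudes of cell centers, west to east
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `n_cols`.
#' @export
grid_lon_centers <- function(grid) {
  grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution
}

#' Latitudes of cell centers, north to south (row order)
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `n_rows`.
#' @export
grid_lat_centers <- function(grid) {
  grid$lat_max - (seq_len(grid$n_rows) - 0.5) * grid$resolution
}

#' Assign points to grid cells
#'
#' Half-open convention: a point belongs to the cell whose west/south edge it
#' lies on; points with `lon == lon_max` or `lat == lat_max` (or beyond the
#' extent) get `NA`.
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Point coordinates (degrees), recycled to common length.
#' @return A data.frame with integer columns `row`, `col`, `cell`
#'   (`cell = (row - 1) * n_cols + col`, row-major linear index); `NA` rows
#'   for points outside the grid.
#' @export
cell_of <- function(grid, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  # snap coordinates that are within float noise of a cell edge onto the edge
  ux <- (lon - grid$lon_min) / grid$resolution
  uy <- (lat - grid$lat_min) / grid$resolution
  ux <- ifelse(abs(ux - round(ux)) < 1e-9, round(ux), ux)
  uy <- ifelse(abs(uy - round(uy)) < 1e-9, round(uy), uy)
  col <- floor(ux) + 1
  row <- grid$n_rows - floor(uy)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1L) * grid$n_cols + col))
}

#' Construct a raster on a grid
#'
#' A raster is a `grid_spec` plus a numeric matrix of values with `NA`
#' marking nodata cells. Row 1 is the northernmost row.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix of dimension `n_rows x n_cols`, or a single
#'   number recycled to the full grid.
#' @return An `sdm_raster` object.
#' @export
sdm_raster <- function(grid, values) {
  if (length(values) == 1) values <- matrix(values, grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop(sprintf("values must be %d x %d", grid$n_rows, grid$n_cols))
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "sdm_raster")
}

#' @export
print.sdm_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<sdm_raster> %d x %d, %d valid cells, range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

raster_values_at <- function(raster, cells) raster$values[cells]

#' Geodesic cell areas on the spherical Earth
#'
#' Each cell's area is the spherical zone slice
#' \eqn{R^2 \Delta\lambda (\sin\phi_{top} - \sin\phi_{bottom})} with
#' \eqn{R = 6371} km, constant within a row, so row sums over a full
#' longitude band reproduce the closed-form zone area
#' \eqn{2\pi R^2(\sin\phi_2 - \sin\phi_1)}.
#'
#' @param grid A `grid_spec`.
#' @return An `sdm_raster` of per-cell areas in km^2.
#' @export
cell_area_raster <- function(grid) {
  R <- 6371
  dlam <- grid$resolution * pi / 180
  lat_top <- grid$lat_max - (seq_len(grid$n_rows) - 1) * grid$resolution
  lat_bot <- lat_top - grid$resolution
  row_area <- R^2 * dlam * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  sdm_raster(grid, matrix(row_area, grid$n_rows, grid$n_cols))
}

#' Resample a raster onto a target grid
#'
#' Bilinear interpolation (for continuous fields) uses the four surrounding
#' source cell centers; it is exact for fields affine in lon/lat and the
#' identity when source and target grids coincide. Target cells whose centers
#' fall outside the hull of source cell centers, or whose four neighbours
#' include a nodata cell, are masked. Nearest-neighbour (for masks and
#' categorical layers) assigns the closest source center, ties going to the
#' west/north cell.
#'
#' @param src An `sdm_raster`.
#' @param target A `grid_spec`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return An `sdm_raster` on `target`.
#' @export
resample_to_grid <- function(src, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  g <- src$grid
  if (g$lon_max <= target$lon_min || target$lon_max <= g$lon_min ||
      g$lat_max <= target$lat_min || target$lat_max <= g$lat_min)
    stop("source and target extents are disjoint")

  xs <- grid_lon_centers(target)
  ys <- grid_lat_centers(target)            # north -> south
  # source center coordinates, 0-based: center j at u = j (j = 0..n-1)
  ux <- (xs - g$lon_min) / g$resolution - 0.5
  uy <- (g$lat_max - ys) / g$resolution - 0.5
  snap <- function(u, hi) {
    u[abs(u) < 1e-9] <- 0
    u[abs(u - hi) < 1e-9] <- hi
    u
  }
  ux <- snap(ux, g$n_cols - 1); uy <- snap(uy, g$n_rows - 1)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)

  if (method == "bilinear") {
    okx <- ux >= 0 & ux <= g$n_cols - 1
    oky <- uy >= 0 & uy <= g$n_rows - 1
    if (any(okx) && any(oky)) {
      j0 <- pmin(floor(ux), g$n_cols - 2); fx <- ux - j0
      i0 <- pmin(floor(uy), g$n_rows - 2); fy <- uy - i0
      jj <- which(okx); ii <- which(oky)
      J0 <- j0[jj] + 1; I0 <- i0[ii] + 1
      FX <- matrix(fx[jj], length(ii), length(jj), byrow = TRUE)
      FY <- matrix(fy[ii], length(ii), length(jj))
      V <- src$values
      v00 <- V[I0, J0, drop = FALSE];     v01 <- V[I0, J0 + 1, drop = FALSE]
      v10 <- V[I0 + 1, J0, drop = FALSE]; v11 <- V[I0 + 1, J0 + 1, drop = FALSE]
      out[ii, jj] <- (1 - FY) * ((1 - FX) * v00 + FX * v01) +
                     FY       * ((1 - FX) * v10 + FX * v11)
    }
  } else {
    # nearest center: index = ceiling(u + 0.5) in 1-based cells; a point
    # exactly equidistant between two centers takes the lower (west/north) one
    vx <- (xs - g$lon_min) / g$resolution
    vy <- (g$lat_max - ys) / g$resolution
    nearest <- function(v, n) {
      v[abs(v - round(v)) < 1e-9] <- round(v[abs(v - round(v)) < 1e-9])
      idx <- ceiling(v)
      idx[v >= 0 & idx == 0] <- 1L   # west/north boundary point
      idx[idx < 1 | idx > n | v < 0 | v > n] <- NA_integer_
      idx
    }
    jx <- nearest(vx, g$n_cols)
    iy <- nearest(vy, g$n_rows)
    ok_i <- which(!is.na(iy)); ok_j <- which(!is.na(jx))
    if (length(ok_i) && length(ok_j))
      out[ok_i, ok_j] <- src$values[iy[ok_i], jx[ok_j], drop = FALSE]
  }
  sdm_raster(target, out)
}
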