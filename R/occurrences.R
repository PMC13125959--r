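# Occurrence cleaning, spatial thinning, grid aggregation and background
# (pseudo-absence) design.

KM_PER_DEG <- 6371 * pi / 180  # meridian km per degree on the spherical datum

#' Clean raw occurrence records
#'
#' Collapses duplicate (species, lon, lat) rows, drops records outside the
#' study extent, records falling on non-land cells (when a land mask is
#' given), and records outside the year window, and attaches a per-stage
#' filter report.
#'
#' @param raw Data frame with columns `species`, `lon`, `lat`, `year`.
#' @param extent A `grid_spec` or numeric `c(lon_min, lon_max, lat_min,
#'   lat_max)`.
#' @param year_range Inclusive year window (default 2014-2024).
#' @param land Optional land `sdm_raster` (records on `NA` cells dropped);
#'   requires `extent` to be a `grid_spec`.
#' @return Cleaned data frame with attribute `filter_report`, a data.frame
#'   of records removed and remaining per stage. Warns (not errors) if
#'   nothing survives.
#' @export
clean_occurrences <- function(raw, extent, year_range = c(2014L, 2024L),
                              land = NULL) {
  if (!nrow(raw)) stop("raw occurrence table is empty")
  need <- c("species", "lon", "lat", "year")
  if (!all(need %in% names(raw))) stop("occurrences need columns: ",
                                       paste(need, collapse = ", "))
  report <- data.frame(stage = character(0), removed = integer(0),
                       remaining = integer(0))
  note <- function(stage, before, after) {
    rbind(report, data.frame(stage = stage, removed = before - after,
                             remaining = after))
  }

  n0 <- nrow(raw)
  df <- raw[!duplicated(raw[c("species", "lon", "lat")]), , drop = FALSE]
  report <- note("duplicates", n0, nrow(df))

  if (inherits(extent, "grid_spec"))
    ext <- c(extent$lon_min, extent$lon_max, extent$lat_min, extent$lat_max)
  else ext <- extent
  n1 <- nrow(df)
  df <- df[df$lon >= ext[1] & df$lon < ext[2] &
           df$lat >= ext[3] & df$lat < ext[4], , drop = FALSE]
  report <- note("extent", n1, nrow(df))

  if (!is.null(land)) {
    if (!inherits(extent, "grid_spec"))
      stop("land masking requires extent to be a grid_spec")
    n2 <- nrow(df)
    cells <- cell_of(extent, df$lon, df$lat)$cell
    on_land <- !is.na(cells) &
      !is.na(as.vector(t(land$values))[cells])
    df <- df[on_land, , drop = FALSE]
    report <- note("off-land", n2, nrow(df))
  }

  n3 <- nrow(df)
  df <- df[df$year >= year_range[1] & df$year <= year_range[2], , drop = FALSE]
  report <- note("year-window", n3, nrow(df))

  if (!nrow(df)) warning("no occurrence records survived cleaning")
  rownames(df) <- NULL
  attr(df, "filter_report") <- report
  df
}

#' Spatially thin occurrences to one record per km-scale cell
#'
#' Records are binned on a local metric grid (longitude scaled by the cosine
#' of each record's latitude, both axes in km) and one record is kept per
#' bin. The retained record is chosen deterministically: smallest
#' (year, lon, lat) in lexicographic order, so thinning is seed-free and
#' idempotent.
#'
#' @param table Cleaned occurrence data frame.
#' @param cell_km Thinning cell size in km (default 1).
#' @return Thinned data frame (never larger than the input).
#' @export
thin_occurrences <- function(table, cell_km = 1) {
  if (!nrow(table)) return(table)
  x_km <- table$lon * KM_PER_DEG * cos(table$lat * pi / 180)
  y_km <- table$lat * KM_PER_DEG
  bin <- paste(table$species, floor(x_km / cell_km), floor(y_km / cell_km))
  ord <- order(bin, table$year, table$lon, table$lat)
  keep <- ord[!duplicated(bin[ord])]
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate occurrences to unique presence cells on the modelling grid
#'
#' @param table Thinned occurrence data frame.
#' @param grid A `grid_spec`.
#' @param valid Optional logical matrix (e.g. `stack$valid`); records on
#'   invalid cells are dropped with a warning.
#' @return Sorted integer vector of unique row-major cell indices.
#' @export
aggregate_to_grid <- function(table, grid, valid = NULL) {
  cells <- cell_of(grid, table$lon, table$lat)$cell
  out <- !is.na(cells)
  if (any(!out)) warning(sum(!out), " record(s) outside the grid dropped")
  cells <- cells[out]
  if (!is.null(valid)) {
    ok <- as.vector(t(valid))[cells]
    if (any(!ok)) warning(sum(!ok), " record(s) on masked cells dropped")
    cells <- cells[ok]
  }
  sort(unique(cells))
}

hav_dist_km <- function(lon1, lat1, lon2, lat2) {
  # thin wrapper: great-circle distance on the package's R = 6371 km sphere
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

#' Coastal-buffer accessible-area mask
#'
#' Marks every grid cell whose center lies within `distance_km` great-circle
#' kilometres of the nearest coast-cell center. This is the accessible-area
#' background for coastal/estuarine taxa.
#'
#' @param grid A `grid_spec`.
#' @param coast An `sdm_raster` with coast cells equal to 1 (e.g. from
#'   [simulate_coastline()]).
#' @param distance_km Buffer distance (default 200).
#' @return Logical matrix (`n_rows x n_cols`), TRUE inside the buffer.
#' @export
coastal_buffer_mask <- function(grid, coast, distance_km = 200) {
  coast_idx <- which(!is.na(coast$values) & coast$values == 1, arr.ind = TRUE)
  if (!nrow(coast_idx)) stop("coast mask is empty")
  lons <- grid_lon_centers(grid)
  lats <- grid_lat_centers(grid)
  c_lon <- lons[coast_idx[, 2]]
  c_lat <- lats[coast_idx[, 1]]

  # one vectorised pass per coast cell, keeping the running minimum
  all_lon <- rep(lons, each = grid$n_rows)    # column-major over the matrix
  all_lat <- rep(lats, times = grid$n_cols)
  d_min <- rep(Inf, grid$n_rows * grid$n_cols)
  for (k in seq_along(c_lon)) {
    d <- hav_dist_km(all_lon, all_lat, c_lon[k], c_lat[k])
    d_min <- pmin(d_min, d)
  }
  matrix(d_min <= distance_km, grid$n_rows, grid$n_cols)
}

#' Sample pseudo-absence (background) cells
#'
#' Draws exactly `ratio` times the number of presence cells, uniformly
#' without replacement, from valid cells that are not presence cells and --
#' for the coastal background -- lie inside the buffer mask. Presence cells
#' are always excluded so no cell can carry both labels.
#'
#' @param valid Logical matrix of model-domain validity (e.g. `stack$valid`).
#' @param presence_cells Integer vector of presence cell indices (row-major).
#' @param ratio Pseudo-absences per presence (default 2, the 1:2 design).
#' @param background `"full-domain"` or `"coastal-buffer"`.
#' @param buffer Logical matrix from [coastal_buffer_mask()] (required for
#'   the coastal background).
#' @param seed Integer seed.
#' @return Sorted integer vector of pseudo-absence cell indices.
#' @export
sample_pseudo_absences <- function(valid, presence_cells, ratio = 2,
                                   background = c("full-domain",
                                                  "coastal-buffer"),
                                   buffer = NULL, seed = 1) {
  background <- match.arg(background)
  elig <- as.vector(t(valid))
  if (background == "coastal-buffer") {
    if (is.null(buffer)) stop("coastal-buffer background requires a buffer mask")
    elig <- elig & as.vector(t(buffer))
  }
  elig[presence_cells] <- FALSE
  pool <- which(elig)
  n_pa <- as.integer(round(ratio * length(presence_cells)))
  if (length(pool) < n_pa)
    stop(sprintf("need %d pseudo-absence cells but only %d eligible (short by %d)",
                 n_pa, length(pool), n_pa - length(pool)))
  set.seed(derive_seed(seed, "pseudo-absences"))
  sort(sample(pool, n_pa, replace = FALSE))
}

#' Build the labelled training table
#'
#' Extracts all predictor values at presence and pseudo-absence cells and
#' discards (with a count) any row with a missing predictor.
#'
#' @param presence_cells,absence_cells Integer cell indices (must be
#'   disjoint).
#' @param stack A `predictor_stack`.
#' @return Data frame with `label` (1 presence / 0 pseudo-absence), `cell`,
#'   and one column per predictor; attribute `n_dropped` counts discarded
#'   rows. Errors if every row is discarded.
#' @export
build_training_table <- function(presence_cells, absence_cells, stack) {
  if (length(intersect(presence_cells, absence_cells)))
    stop("presence and pseudo-absence cells overlap")
  cells <- c(presence_cells, absence_cells)
  lab <- rep(c(1L, 0L), c(length(presence_cells), length(absence_cells)))
  vals <- stack_extract(stack, cells)
  ok <- stats::complete.cases(vals)
  if (!any(ok)) stop("all rows had missing predictor values")
  out <- cbind(data.frame(label = lab[ok], cell = cells[ok]), vals[ok, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}
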