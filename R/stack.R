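#' Predictor layer names used throughout the pipeline
#'
#' Four bioclimatic summaries (annual mean temperature BIO1, temperature
#' seasonality BIO4, annual precipitation BIO12, precipitation seasonality
#' BIO15) and three fractional land-use layers in percent (Urban, Crop,
#' Pasture).
#' @export
SDM_PREDICTORS <- c("BIO1", "BIO4", "BIO12", "BIO15", "Urban", "Crop", "Pasture")

LANDUSE_LAYERS <- c("Urban", "Crop", "Pasture")

#' Bundle aligned predictor rasters into a stack
#'
#' All layers must share one grid. Fractional land-use layers (Urban, Crop,
#' Pasture) must lie in \[0, 100\]; use `clip_landuse = TRUE` to clip small
#' overshoots (e.g. after bilinear resampling). A cell is valid only where
#' every layer is non-missing: nodata propagates, so the valid mask shrinks
#' monotonically as layers are added.
#'
#' @param layers Named list of `sdm_raster` objects (or plain matrices, all
#'   interpreted on `grid`).
#' @param grid Optional `grid_spec`; defaults to the grid of the first layer.
#' @param clip_landuse Clip land-use layers into \[0, 100\] before validation.
#' @return A `predictor_stack` with elements `grid`, `layers` (named list of
#'   matrices) and `valid` (logical matrix).
#' @export
predictor_stack <- function(layers, grid = NULL, clip_landuse = FALSE) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be a fully named list")
  if (is.null(grid)) {
    if (!inherits(layers[[1]], "sdm_raster"))
      stop("grid must be given when layers are plain matrices")
    grid <- layers[[1]]$grid
  }
  mats <- lapply(names(layers), function(nm) {
    l <- layers[[nm]]
    if (inherits(l, "sdm_raster")) {
      if (!grid_equal(l$grid, grid)) stop("layer '", nm, "' is on a different grid")
      l <- l$values
    }
    l <- as.matrix(l)
    if (!all(dim(l) == c(grid$n_rows, grid$n_cols)))
      stop("layer '", nm, "' has wrong dimensions")
    if (nm %in% LANDUSE_LAYERS) {
      if (clip_landuse) l <- pmin(pmax(l, 0), 100)
      rng <- range(l, na.rm = TRUE)
      if (rng[1] < 0 || rng[2] > 100)
        stop("land-use layer '", nm, "' outside [0, 100]; set clip_landuse = TRUE")
    }
    l
  })
  names(mats) <- names(layers)
  valid <- Reduce(`&`, lapply(mats, function(m) !is.na(m)))
  structure(list(grid = grid, layers = mats, valid = valid),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers on %d x %d grid, %d valid cells\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$valid)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Extract predictor values at grid cells
#'
#' @param stack A `predictor_stack`.
#' @param cells Integer vector of row-major linear cell indices (as produced
#'   by [cell_of()]).
#' @return Data frame with one column per layer, rows in `cells` order.
#'   Cells with any missing layer yield `NA` in that column.
#' @export
stack_extract <- function(stack, cells) {
  # layers are stored column-major; convert row-major linear index
  rc <- cell_to_rowcol(stack$grid, cells)
  idx <- cbind(rc$row, rc$col)
  out <- lapply(stack$layers, function(m) m[idx])
  as.data.frame(out, optional = TRUE)
}

cell_to_rowcol <- function(grid, cells) {
  list(row = ((cells - 1L) %/% grid$n_cols) + 1L,
       col = ((cells - 1L) %% grid$n_cols) + 1L)
}

rowcol_to_cell <- function(grid, row, col) (row - 1L) * grid$n_cols + col

#' Linear indices of all valid stack cells (row-major)
#' @param stack A `predictor_stack`.
#' @return Sorted integer vector.
#' @export
stack_valid_cells <- function(stack) {
  which(t(stack$valid))
}

#' Mask a stack to a land mask
#'
#' Sets every layer to `NA` where `mask` is `NA` or 0 (ocean); used to
#' restrict synthetic stacks to the simulated landmass.
#'
#' @param stack A `predictor_stack`.
#' @param mask An `sdm_raster` whose `NA` cells (and zeros if `zero_is_na`)
#'   are removed from the stack.
#' @param zero_is_na Treat 0 as outside (default FALSE: only `NA` masks).
#' @return A new `predictor_stack`.
#' @export
mask_stack <- function(stack, mask, zero_is_na = FALSE) {
  if (!grid_equal(mask$grid, stack$grid)) stop("mask grid mismatch")
  drop <- is.na(mask$values)
  if (zero_is_na) drop <- drop | (!is.na(mask$values) & mask$values == 0)
  layers <- lapply(stack$layers, function(m) { m[drop] <- NA_real_; m })
  predictor_stack(layers, grid = stack$grid)
}

#' Write every layer of a stack as GeoTIFF files
#' @param stack A `predictor_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional filename prefix.
#' @return Named character vector of file paths.
#' @export
write_stack <- function(stack, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".tif"))
    write_geotiff(sdm_raster(stack$grid, stack$layers[[nm]]), p)
    p
  }, character(1))
  paths
}

#' Read a predictor stack from GeoTIFF files
#' @param paths Named character vector of file paths (names become layers).
#' @return A `predictor_stack`.
#' @export
read_stack <- function(paths) {
  if (is.null(names(paths))) stop("paths must be named by layer")
  rasters <- lapply(paths, read_geotiff)
  predictor_stack(rasters, clip_landuse = TRUE)
}
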