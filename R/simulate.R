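# Synthetic landscapes and virtual species.
#
# Downstream stages (background sampling, model fitting, ensembling,
# projection, interpretation) are validated against a taxon whose true
# suitability surface is known by construction. The generator emulates the
# structure of the real inputs -- spatially autocorrelated climate gradients,
# fractional land-use layers, a coastline bounding the accessible area, and
# affine future-scenario perturbations -- not any particular region.

derive_seed <- function(seed, tag) {
  # stable per-stage seed: seed and tag hashed into [1, 2^31 - 2] so adding a
  # stage never perturbs another stage's stream
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h) + 1L
}

# Gaussian random field via separable kernel smoothing of white noise,
# standardised to mean 0 / sd 1 over the grid.
smooth_field <- function(n_rows, n_cols, correlation_length, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  smoother <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    k <- exp(-0.5 * (d / correlation_length)^2)
    k / rowSums(k)
  }
  f <- smoother(n_rows) %*% z %*% t(smoother(n_cols))
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a spatially autocorrelated predictor stack
#'
#' Generates the seven standard layers on `grid`: BIO1 as a south-warm
#' latitudinal gradient plus a smoothed Gaussian field; BIO4, BIO12 and BIO15
#' as independent smoothed fields (distinct derived seeds) around realistic
#' magnitudes; and Urban/Crop/Pasture as logistic-squashed fields on the
#' percentage scale, with Urban concentrated near the (eastern) coast. Output
#' is reproducible for a given seed.
#'
#' @param grid A `grid_spec`, at least 3 x 3.
#' @param correlation_length Smoothing kernel scale in cells (>= 1).
#' @param seed Integer master seed.
#' @param land Optional land/coast `sdm_raster` (e.g. from
#'   [simulate_coastline()]); ocean (`NA`) cells are masked in every layer.
#' @return A `predictor_stack`.
#' @export
simulate_predictor_stack <- function(grid, correlation_length = 6, seed = 1,
                                     land = NULL) {
  if (grid$n_rows < 3 || grid$n_cols < 3) stop("grid too small to simulate (< 3 x 3)")
  if (correlation_length < 1) stop("correlation_length must be >= 1")
  nr <- grid$n_rows; nc <- grid$n_cols
  fld <- function(tag) smooth_field(nr, nc, correlation_length,
                                    derive_seed(seed, tag))
  # 0 at north edge, 1 at south edge
  south <- matrix(seq(0, 1, length.out = nr), nr, nc)
  # distance (in cells) from the eastern edge, scaled by grid width
  east <- matrix(rep((nc - seq_len(nc)) / nc, each = nr), nr, nc)

  layers <- list(
    BIO1   = -5 + 27 * south + 3 * fld("BIO1"),
    BIO4   = 900 - 400 * south + 150 * fld("BIO4"),
    BIO12  = pmax(300 + 1400 * south + 450 * fld("BIO12"), 0),
    BIO15  = pmax(80 + 25 * fld("BIO15"), 0),
    Urban  = 100 * stats::plogis(-2.5 + 1.6 * fld("Urban") + 3.5 * exp(-east / 0.15)),
    Crop   = 100 * stats::plogis(-0.8 + 1.2 * fld("Crop")),
    Pasture = 100 * stats::plogis(-1.2 + 1.1 * fld("Pasture"))
  )
  stack <- predictor_stack(lapply(layers, sdm_raster, grid = grid), grid = grid)
  if (!is.null(land)) stack <- mask_stack(stack, land)
  stack
}

#' Simulate a coastline / land mask
#'
#' The landmass occupies the western part of the grid up to a smoothly
#' meandering eastern boundary; the easternmost land cell of each row is
#' marked as coast. Cells east of the boundary are ocean (`NA`).
#'
#' @param grid A `grid_spec`.
#' @param seed Integer seed for the meander.
#' @param ocean_fraction Approximate fraction of columns left as ocean
#'   (0 gives an all-land grid whose eastern column is the coast).
#' @return An `sdm_raster`: 1 = coast cell, 0 = interior land, `NA` = ocean.
#' @export
simulate_coastline <- function(grid, seed = 1, ocean_fraction = 0.2) {
  nr <- grid$n_rows; nc <- grid$n_cols
  if (ocean_fraction <= 0) {
    coast_col <- rep(nc, nr)
  } else {
    set.seed(derive_seed(seed, "coastline"))
    wiggle <- stats::filter(stats::rnorm(nr), rep(1 / 7, 7), circular = TRUE)
    wiggle <- as.numeric(wiggle) / max(abs(wiggle), 1e-12)
    base <- round(nc * (1 - ocean_fraction))
    amp <- max(1, round(nc * ocean_fraction / 3))
    coast_col <- pmin(nc, pmax(2, base + round(amp * wiggle)))
  }
  v <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    v[i, seq_len(coast_col[i])] <- 0
    v[i, coast_col[i]] <- 1
  }
  sdm_raster(grid, v)
}

#' Define a virtual species from per-predictor response curves
#'
#' Each response maps a predictor layer to a suitability factor in \[0, 1\]:
#' `gaussian(opt, breadth)` gives `exp(-0.5 ((x - opt)/breadth)^2)`,
#' `logistic(mid, slope)` gives `plogis((x - mid)/slope)`, and
#' `linear(lo, hi)` ramps 0 to 1 over \[lo, hi\] (swap for a decreasing
#' ramp). Factors combine by product or geometric mean into the true
#' suitability surface; the construction is deterministic.
#'
#' @param stack A `predictor_stack`.
#' @param responses Named list (by layer) of response definitions, e.g.
#'   `list(BIO1 = list(type = "gaussian", opt = 18, breadth = 4))`.
#' @param combination `"geometric"` (default) or `"product"`.
#' @return A `virtual_species` with elements `responses`, `combination` and
#'   `suitability` (an `sdm_raster` in \[0, 1\], NA off the valid mask).
#' @export
make_virtual_species <- function(stack, responses,
                                 combination = c("geometric", "product")) {
  combination <- match.arg(combination)
  if (!all(names(responses) %in% names(stack$layers)))
    stop("responses name layers absent from the stack")
  if (!any(stack$valid)) stop("stack has an empty valid mask")

  factor_of <- function(x, r) {
    switch(r$type,
      gaussian = exp(-0.5 * ((x - r$opt) / r$breadth)^2),
      logistic = stats::plogis((x - r$mid) / r$slope),
      linear   = pmin(pmax((x - r$lo) / (r$hi - r$lo), 0), 1),
      flat     = matrix(1, nrow(x), ncol(x)),
      stop("unknown response type: ", r$type))
  }
  factors <- lapply(names(responses), function(nm)
    factor_of(stack$layers[[nm]], responses[[nm]]))
  s <- if (combination == "product") Reduce(`*`, factors)
       else Reduce(`*`, factors)^(1 / length(factors))
  s[!stack$valid] <- NA_real_
  structure(list(responses = responses, combination = combination,
                 suitability = sdm_raster(stack$grid, s)),
            class = "virtual_species")
}

#' Sample presence records from a virtual species
#'
#' Cells are drawn without replacement with probability proportional to true
#' suitability (presence-only sampling with detection proportional to local
#' suitability); each record gets coordinates jittered uniformly within its
#' cell and a collection year uniform on `years`.
#'
#' @param species A `virtual_species`.
#' @param n Number of presence records (>= 1).
#' @param seed Integer seed.
#' @param name Species/taxon label for the table.
#' @param years Year range records are drawn from.
#' @return An occurrence data.frame (`species`, `lon`, `lat`, `year`) with
#'   attribute `cells` giving the sampled grid cells.
#' @export
sample_presences <- function(species, n, seed = 1, name = "virtual_sp",
                             years = c(2014L, 2024L)) {
  if (n < 1) stop("n must be >= 1")
  s <- species$suitability
  grid <- s$grid
  w_rowmajor <- as.vector(t(s$values))
  eligible <- which(!is.na(w_rowmajor) & w_rowmajor > 0)
  if (length(eligible) < n)
    stop("n exceeds the ", length(eligible), " cells with positive suitability")
  set.seed(derive_seed(seed, "presences"))
  cells <- if (length(eligible) == 1) eligible else
    sample(eligible, n, replace = FALSE, prob = w_rowmajor[eligible])
  rc <- cell_to_rowcol(grid, cells)
  res <- grid$resolution
  lon <- grid$lon_min + (rc$col - 1) * res + stats::runif(n) * res
  lat <- grid$lat_max - rc$row * res + stats::runif(n) * res
  out <- data.frame(species = name, lon = lon, lat = lat,
                    year = sample(seq(years[1], years[2]), n, replace = TRUE))
  attr(out, "cells") <- cells
  out
}

#' Specify an environmental-change scenario
#'
#' Affine perturbations standing in for a future climate--land-use stack:
#' an additive temperature offset on BIO1 (degrees C), a multiplicative
#' precipitation scaling on BIO12, and additive percentage-point trends on
#' the land-use layers (re-clipped to \[0, 100\]).
#'
#' @param name Scenario label (e.g. `"ssp_low"`).
#' @param temp_offset Offset added to BIO1 (degrees C).
#' @param precip_scale Factor multiplying BIO12.
#' @param landuse_trend Named numeric vector of additive % changes, e.g.
#'   `c(Urban = 5, Crop = -10)`.
#' @param horizon Time-horizon label (e.g. `"2030s"`).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, temp_offset = 0, precip_scale = 1,
                          landuse_trend = numeric(0), horizon = "") {
  if (length(landuse_trend) && is.null(names(landuse_trend)))
    stop("landuse_trend must be named")
  structure(list(name = name, temp_offset = temp_offset,
                 precip_scale = precip_scale, landuse_trend = landuse_trend,
                 horizon = horizon),
            class = "scenario_spec")
}

#' Apply a scenario perturbation to a predictor stack
#'
#' BIO1 gains the temperature offset, BIO12 is scaled, land-use layers shift
#' by their trends and are clipped back into \[0, 100\]; validity masks are
#' unchanged.
#'
#' @param stack A `predictor_stack`.
#' @param spec A `scenario_spec`.
#' @return A perturbed `predictor_stack`.
#' @export
perturb_scenario <- function(stack, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  layers <- stack$layers
  layers$BIO1 <- layers$BIO1 + spec$temp_offset
  layers$BIO12 <- layers$BIO12 * spec$precip_scale
  for (nm in names(spec$landuse_trend)) {
    if (!nm %in% names(layers)) stop("unknown land-use layer: ", nm)
    layers[[nm]] <- pmin(pmax(layers[[nm]] + spec$landuse_trend[[nm]], 0), 100)
  }
  predictor_stack(layers, grid = stack$grid)
}
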