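test_that("cleaning removes duplicates, out-of-extent, off-land and old records", {
  g <- tiny_grid(10)   # lon 100-101, lat 20-21
  raw <- data.frame(
    species = "sp",
    lon = c(100.5, 100.5, 100.2, 99.0, 100.3, 100.4),
    lat = c(20.5, 20.5, 20.2, 20.5, 20.3, 20.4),
    year = c(2018, 2018, 2010, 2018, 2020, 2016))
  out <- clean_occurrences(raw, g)
  rep <- attr(out, "filter_report")
  expect_equal(nrow(out), 3)                       # dup, 2010, off-extent gone
  expect_equal(rep$removed[rep$stage == "duplicates"], 1)
  expect_equal(rep$removed[rep$stage == "extent"], 1)
  expect_equal(rep$removed[rep$stage == "year-window"], 1)

  land <- simulate_coastline(g, seed = 1, ocean_fraction = 0.4)
  ocean_lon <- 100 + (g$n_cols - 0.5) * g$resolution   # far-east column
  raw2 <- data.frame(species = "sp", lon = c(100.05, ocean_lon),
                     lat = c(20.05, 20.05), year = 2020)
  out2 <- clean_occurrences(raw2, g, land = land)
  expect_equal(nrow(out2), 1)
  expect_warning(clean_occurrences(
    data.frame(species = "sp", lon = 100.1, lat = 20.1, year = 1999), g),
    "survived")
})

test_that("thinning keeps one deterministic record per 1-km cell and is idempotent", {
  base <- data.frame(species = "sp", lon = 100, lat = 20, year = 2020)
  near <- base; near$lon <- 100 + 0.1 / 111   # ~100 m east
  far <- base; far$lon <- 100 + 5 / 111 / cos(20 * pi / 180)  # ~5 km east
  tab <- rbind(base, near, far)

  thinned <- thin_occurrences(tab, cell_km = 1)
  expect_equal(nrow(thinned), 2)
  thinned2 <- thin_occurrences(thinned, cell_km = 1)
  expect_identical(thinned, thinned2)

  # earliest (year, lon, lat) wins within a cell
  dup <- rbind(base, transform(base, year = 2015))
  expect_equal(thin_occurrences(dup)$year, 2015)

  # all records in distinct cells: thinning is the identity
  spread <- data.frame(species = "sp", lon = 100 + (0:9) * 0.05,
                       lat = 20, year = 2020)
  expect_identical(thin_occurrences(spread), spread)
})

test_that("grid aggregation counts a cell once and honours the valid mask", {
  g <- tiny_grid(10)
  tab <- data.frame(species = "sp",
                    lon = c(100.11, 100.13, 100.19, 100.31),
                    lat = c(20.55, 20.55, 20.55, 20.55), year = 2020)
  cells <- aggregate_to_grid(tab, g)
  expect_equal(length(cells), 2)    # 3 points in one 0.1-degree cell + 1 other

  # a point on a cell edge goes to the eastern cell (half-open rule)
  edge <- data.frame(species = "sp", lon = 100.2, lat = 20.55, year = 2020)
  expect_equal(aggregate_to_grid(edge, g),
               cell_of(g, 100.2 + 1e-9, 20.55)$cell)

  valid <- matrix(TRUE, g$n_rows, g$n_cols); valid[, 4] <- FALSE  # col of 100.3x
  expect_warning(cells2 <- aggregate_to_grid(tab, g, valid), "masked")
  expect_equal(length(cells2), 1)
  expect_warning(aggregate_to_grid(
    data.frame(species = "sp", lon = 150, lat = 20.5, year = 2020), g),
    "outside")
})

test_that("coastal buffer matches the brute-force haversine oracle", {
  g <- make_grid(100, 103, 20, 23, 0.25)   # 12 x 12
  coast <- simulate_coastline(g, seed = 2, ocean_fraction = 0.3)
  buf <- coastal_buffer_mask(g, coast, distance_km = 120)

  lons <- grid_lon_centers(g); lats <- grid_lat_centers(g)
  cidx <- which(!is.na(coast$values) & coast$values == 1, arr.ind = TRUE)
  oracle <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    dmin <- Inf
    for (k in seq_len(nrow(cidx)))
      dmin <- min(dmin, oracle_hav_km(lons[j], lats[i],
                                      lons[cidx[k, 2]], lats[cidx[k, 1]]))
    oracle[i, j] <- dmin <= 120
  }
  expect_equal(buf, oracle)

  # coast cells themselves are inside; monotone in distance
  expect_true(all(buf[cbind(cidx[, 1], cidx[, 2])]))
  buf_small <- coastal_buffer_mask(g, coast, distance_km = 60)
  expect_true(all(buf[buf_small]))
  expect_error(coastal_buffer_mask(g, sdm_raster(g, 0), 100), "empty")
})

test_that("pseudo-absence sampling hits the exact ratio and constraints", {
  land <- tiny_landscape(n = 25, seed = 3)
  valid <- land$stack$valid
  pres <- which(t(valid))[1:40]

  for (s in 1:4) {
    pa <- sample_pseudo_absences(valid, pres, ratio = 2, seed = s)
    expect_equal(length(pa), 80)
    expect_length(intersect(pa, pres), 0)
    expect_true(all(as.vector(t(valid))[pa]))
  }
  expect_identical(sample_pseudo_absences(valid, pres, seed = 1),
                   sample_pseudo_absences(valid, pres, seed = 1))

  buf <- coastal_buffer_mask(land$grid, land$coast, distance_km = 60)
  pa_c <- sample_pseudo_absences(valid, pres, background = "coastal-buffer",
                                 buffer = buf, seed = 1)
  expect_true(all(as.vector(t(buf))[pa_c]))

  expect_error(sample_pseudo_absences(valid, pres, ratio = 1e5, seed = 1),
               "short by")
})

test_that("training tables carry labels, drop incomplete rows, stay disjoint", {
  land <- tiny_landscape(n = 20, seed = 6)
  valid_cells <- which(t(land$stack$valid))
  pres <- valid_cells[1:15]
  pa <- valid_cells[30:59]
  train <- build_training_table(pres, pa, land$stack)
  expect_equal(sum(train$label == 1), 15)
  expect_equal(sum(train$label == 0), 30)
  expect_equal(ncol(train), 2 + 7)
  expect_false(anyNA(train))
  expect_length(intersect(train$cell[train$label == 1],
                          train$cell[train$label == 0]), 0)

  # poke a hole in one layer: that row is dropped and counted
  stack2 <- land$stack
  rc <- cell_to_rowcol_test(land$grid, pres[1])
  stack2$layers$Urban[rc$row, rc$col] <- NA
  t2 <- build_training_table(pres, pa, stack2)
  expect_equal(nrow(t2), nrow(train) - 1)
  expect_equal(attr(t2, "n_dropped"), 1)
  expect_error(build_training_table(pres, pres, land$stack), "overlap")
})
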