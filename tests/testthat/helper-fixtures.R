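# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, exhaustive enumeration) and never reuse package internals.

# great-circle km on the R = 6371 sphere, scalar haversine by the book
oracle_hav_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(pmin(1, a)))
}

# pairwise Mann-Whitney AUC, ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive threshold scan for max Youden J (rule: presence iff score >= t)
oracle_tss <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s + .Machine$double.eps^0.5, s[length(s)] + 1)
  best <- -Inf
  for (th in cand) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    best <- max(best, sens + spec - 1)
  }
  best
}

# rook-neighbour Moran's I computed the long way
oracle_morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; wsum <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii <= nr && jj <= nc) {
        num <- num + 2 * z[i, j] * z[ii, jj]  # symmetric pair counted twice
        wsum <- wsum + 2
      }
    }
  }
  (nr * nc / wsum) * (num / sum(z^2))
}

rowcol_to_cell_test <- function(g, row, col) (row - 1L) * g$n_cols + col

cell_to_rowcol_test <- function(g, cell)
  list(row = ((cell - 1L) %/% g$n_cols) + 1L, col = ((cell - 1L) %% g$n_cols) + 1L)

tiny_grid <- function(n = 20, res = 0.1, lat_min = 20)
  make_grid(100, 100 + n * res, lat_min, lat_min + n * res, res)

tiny_landscape <- function(n = 30, seed = 42, ocean_fraction = 0.2) {
  grid <- tiny_grid(n)
  coast <- simulate_coastline(grid, seed = seed, ocean_fraction = ocean_fraction)
  stack <- simulate_predictor_stack(grid, correlation_length = 4, seed = seed,
                                    land = coast)
  list(grid = grid, coast = coast, stack = stack)
}

# small training table with a clean monotone signal in x1
toy_training <- function(n = 240, seed = 1, p = 7) {
  set.seed(seed)
  X <- as.data.frame(matrix(runif(n * p), n, p))
  names(X) <- paste0("x", seq_len(p))
  label <- as.integer(X$x1 + 0.2 * rnorm(n) > 0.5)
  cbind(data.frame(label = label, cell = seq_len(n)), X)
}

# a fitted landscape + models, built once per test run and memoised
fitted_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    land <- tiny_landscape(n = 40, seed = 11)
    species <- make_virtual_species(land$stack, list(
      BIO1 = list(type = "gaussian", opt = 18, breadth = 2),
      BIO12 = list(type = "gaussian", opt = 1500, breadth = 350)),
      combination = "product")
    occ <- sample_presences(species, 120, seed = 5)
    pres <- aggregate_to_grid(occ, land$grid, land$stack$valid)
    pa <- sample_pseudo_absences(land$stack$valid, pres, seed = 5)
    train <- build_training_table(pres, pa, land$stack)
    mx <- fit_maxent(train, seed = 3)
    rf <- fit_forest(train, n_trees = 200, seed = 3)
    cache <<- list(land = land, species = species, presences = pres,
                   train = train, maxent = mx, forest = rf)
    cache
  }
})
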