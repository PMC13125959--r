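fake_cv <- function(auc, tss, alg = "m")
  structure(list(mean_auc = auc, mean_tss = tss, k = 5, algorithm = alg),
            class = "cv_metrics")

test_that("the performance gate is inclusive at its boundaries", {
  cv <- list(fake_cv(0.93, 0.75), fake_cv(0.94, 0.76))
  expect_equal(gate_members(cv), c(1L, 2L))
  expect_equal(gate_members(list(fake_cv(0.95, 0.60), fake_cv(0.91, 0.75))), 2L)
  expect_equal(gate_members(list(fake_cv(0.90, 0.70))), 1L)   # >= is inclusive
  expect_error(gate_members(list(fake_cv(0.89, 0.80), fake_cv(0.95, 0.69))),
               "no members passed")
})

test_that("ensemble weights are AUC-proportional and normalized", {
  w <- ensemble_weights(c(0.93, 0.94))
  expect_equal(w, c(0.4973, 0.5027), tolerance = 1e-4)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(ensemble_weights(c(0.8, 0.8)), c(0.5, 0.5))
  expect_equal(ensemble_weights(0.91), 1.0)
  expect_error(ensemble_weights(c(0.9, 0)), "positive")
})

test_that("weighted surfaces are convex combinations of the members", {
  g <- tiny_grid(8)
  a <- sdm_raster(g, matrix(0.2, 8, 8))
  b <- sdm_raster(g, matrix(0.8, 8, 8))
  expect_true(all(ensemble_surface(list(a, b), c(0.5, 0.5))$values == 0.5))
  w <- ensemble_weights(c(0.93, 0.94))
  zo <- ensemble_surface(list(sdm_raster(g, 0), sdm_raster(g, 1)), w)
  expect_equal(zo$values[1, 1], 0.5027, tolerance = 1e-4)

  set.seed(3)
  m1 <- matrix(runif(64), 8, 8); m2 <- matrix(runif(64), 8, 8)
  ens <- ensemble_surface(list(sdm_raster(g, m1), sdm_raster(g, m2)), w)$values
  expect_true(all(ens >= pmin(m1, m2) - 1e-12 & ens <= pmax(m1, m2) + 1e-12))
  # members agreeing everywhere reproduce themselves
  same <- ensemble_surface(list(sdm_raster(g, m1), sdm_raster(g, m1)), w)
  expect_equal(same$values, m1)
  expect_error(ensemble_surface(list(a, b), 1), "align")
})

test_that("P10 uses interpolated quantiles and keeps >= 90% of presences", {
  # Weibull convention: h = (n + 1) p = 1.1 -> between the 1st and 2nd values
  expect_equal(p10_threshold(seq(0.1, 1.0, by = 0.1)), 0.11)
  expect_equal(p10_threshold(rep(0.4, 25)), 0.4)
  expect_warning(t5 <- p10_threshold(c(0.5, 0.3, 0.8)), "fewer than 10")
  expect_equal(t5, 0.3)

  set.seed(21)
  for (i in 1:300) {
    v <- runif(sample(10:400, 1))
    th <- p10_threshold(v)
    expect_gte(mean(v >= th), 0.90)
    # independent interpolated-quantile oracle: h = (n + 1) p
    h <- (length(v) + 1) * 0.1
    sv <- sort(v)
    expect_equal(th, sv[floor(h)] + (h - floor(h)) *
                     (sv[ceiling(h)] - sv[floor(h)]))
  }
})

test_that("binarization is inclusive at the threshold and mask-preserving", {
  g <- tiny_grid(4)
  v <- matrix(c(0.2, 0.5, 0.7, NA), 4, 4)
  s <- sdm_raster(g, v)
  b <- binarize(s, 0.5)
  expect_equal(b$values[2, 1], 1)          # equality counts as suitable
  expect_equal(b$values[1, 1], 0)
  expect_true(is.na(b$values[4, 1]))
  expect_true(all(binarize(s, 0)$values[!is.na(v)] == 1))
  b1 <- binarize(s, 1)
  expect_true(all(b1$values[!is.na(v)] == 0))
  expect_error(binarize(s, 1.2), "0, 1")
})

test_that("suitable area sums cell areas and is additive over disjoint maps", {
  g <- make_grid(0, 1, 0, 1, 0.1)
  areas <- cell_area_raster(g)
  zero <- sdm_raster(g, 0)
  expect_equal(suitable_area(zero, areas), 0)

  one_cell <- sdm_raster(g, 0)
  one_cell$values[10, 1] <- 1              # bottom row touches the equator
  expect_equal(suitable_area(one_cell, areas),
               6371^2 * (0.1 * pi / 180) * sin(0.1 * pi / 180),
               tolerance = 1e-12)

  set.seed(5)
  a <- matrix(rbinom(100, 1, 0.3), 10, 10)
  b <- ifelse(a == 1, 0, rbinom(100, 1, 0.5))
  expect_equal(suitable_area(sdm_raster(g, a + b), areas),
               suitable_area(sdm_raster(g, a), areas) +
                 suitable_area(sdm_raster(g, b), areas))
  expect_error(suitable_area(zero, cell_area_raster(tiny_grid(5))), "mismatch")
})

test_that("build_ensemble gates, weights and thresholds coherently", {
  fx <- fitted_fixture()
  cv_mx <- cross_validate(function(tr, seed) fit_maxent(tr, seed = seed),
                          fx$train, k = 5, seed = 2, algorithm = "maxent-style")
  cv_rf <- cross_validate(function(tr, seed) fit_forest(tr, n_trees = 200,
                                                        seed = seed),
                          fx$train, k = 5, seed = 2, algorithm = "forest")
  ens <- build_ensemble(list(fx$maxent, fx$forest), list(cv_mx, cv_rf),
                        fx$land$stack, fx$presences,
                        auc_min = 0, tss_min = -1)   # no gating here
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_equal(ens$weights,
               ensemble_weights(c(cv_mx$mean_auc, cv_rf$mean_auc)))
  # ensemble surface bounded by members cellwise
  s1 <- predict_surface(fx$maxent, fx$land$stack)$values
  s2 <- predict_surface(fx$forest, fx$land$stack)$values
  ev <- ens$surface$values
  ok <- !is.na(ev)
  expect_true(all(ev[ok] >= pmin(s1, s2)[ok] - 1e-12))
  expect_true(all(ev[ok] <= pmax(s1, s2)[ok] + 1e-12))
  # tabular ensemble prediction is the weighted member mean
  p_tab <- predict_sdm(ens, fx$train)
  expect_equal(p_tab, ens$weights[1] * predict_sdm(fx$maxent, fx$train) +
                      ens$weights[2] * predict_sdm(fx$forest, fx$train))

  desc <- withr::local_tempfile(fileext = ".txt")
  write_ensemble_description(ens, desc)
  expect_match(readLines(desc)[2], "maxent-style, forest")
})
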