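# a transparent additive "model" on 7 predictors: honours the fitted_sdm
# prediction contract without any fitting machinery
additive_model <- function(coefs) {
  structure(list(algorithm = "toy", predictors = names(coefs), coefs = coefs),
            class = c("toy_sdm", "fitted_sdm"))
}
predict_sdm.toy_sdm <- function(model, newdata) {
  nd <- as.matrix(as.data.frame(newdata)[, model$predictors, drop = FALSE])
  pmin(pmax(as.numeric(nd %*% model$coefs), 0), 1)
}
registerS3method("predict_sdm", "toy_sdm", predict_sdm.toy_sdm,
                 envir = asNamespace("ensdm"))

toy_eval <- function(n = 60, seed = 2, p = 7) {
  set.seed(seed)
  X <- as.data.frame(matrix(runif(n * p, 0, 0.3), n, p))
  names(X) <- paste0("x", seq_len(p))
  X
}

test_that("permutation importance is zero for unused predictors, positive for drivers", {
  coefs <- c(x1 = 2, x2 = 1, x3 = 0, x4 = 0, x5 = 0, x6 = 0, x7 = 0)
  model <- additive_model(coefs)
  ev <- toy_eval(200)
  ev$label <- as.integer(predict_sdm(model, ev) +
                           0.1 * rnorm(nrow(ev)) > 0.35)
  imp <- permutation_importance(model, ev, n_reps = 5, seed = 1)
  expect_equal(imp$delta_auc[imp$predictor == "x3"], 0)
  expect_equal(imp$delta_auc[imp$predictor == "x7"], 0)
  expect_gt(imp$delta_auc[imp$predictor == "x1"], 0.05)
  expect_identical(imp, permutation_importance(model, ev, n_reps = 5, seed = 1))
  expect_error(permutation_importance(model, transform(ev, label = 1), 2, 1),
               "both classes")
})

test_that("a pure-signal predictor loses about its whole AUC margin when permuted", {
  train <- toy_training(n = 400, seed = 3)
  train$label <- as.integer(train$x1 > 0.5)
  fit <- fit_forest(train, n_trees = 300, seed = 1)
  # held-out evaluation sample from the same process: the noise predictors
  # cannot substitute for the permuted signal here
  eval_tab <- toy_training(n = 400, seed = 30)
  eval_tab$label <- as.integer(eval_tab$x1 > 0.5)
  imp <- permutation_importance(fit, eval_tab, n_reps = 10, seed = 2)
  base <- attr(imp, "baseline_auc")
  expect_equal(imp$delta_auc[imp$predictor == "x1"], base - 0.5,
               tolerance = 0.05 / (base - 0.5))
})

test_that("exact Shapley values satisfy the additive-attribution axioms", {
  # dummy: predictors with zero coefficients get zero attribution
  coefs <- c(x1 = 1.5, x2 = 0.8, x3 = 0, x4 = 0, x5 = 0, x6 = 0, x7 = 0)
  model <- additive_model(coefs)
  bg <- toy_eval(30, seed = 4)
  ev <- toy_eval(12, seed = 5)
  sh <- shap_values(model, bg, ev, method = "exact")
  expect_true(all(abs(sh$contributions[, c("x3", "x7")]) < 1e-12))

  # local accuracy, exactly, for every point
  expect_lt(max(abs(sh$base_value + rowSums(sh$contributions) -
                      sh$predictions)), 1e-10)

  # symmetry: duplicated predictors with identical values share attribution
  coefs2 <- c(x1 = 1, x2 = 1, x3 = 0, x4 = 0, x5 = 0, x6 = 0, x7 = 0)
  model2 <- additive_model(coefs2)
  bg2 <- bg; bg2$x2 <- bg2$x1
  ev2 <- ev; ev2$x2 <- ev2$x1
  sh2 <- shap_values(model2, bg2, ev2, method = "exact")
  expect_equal(sh2$contributions[, "x1"], sh2$contributions[, "x2"],
               tolerance = 1e-12)
})

test_that("Monte-Carlo Shapley converges to the exact enumeration", {
  coefs <- c(x1 = 1.2, x2 = 0.6, x3 = 0.4, x4 = 0, x5 = 0, x6 = 0, x7 = 0.3)
  model <- additive_model(coefs)
  bg <- toy_eval(15, seed = 6)
  ev <- toy_eval(3, seed = 7)
  exact <- shap_values(model, bg, ev, method = "exact")
  mc <- shap_values(model, bg, ev, method = "sampling", n_mc = 2000, seed = 1)
  expect_lt(mean(abs(exact$contributions - mc$contributions)), 0.01)
})

test_that("effect classes follow the stated cutoffs with inclusive boundaries", {
  expect_equal(classify_shap(0.06), "strong")
  expect_equal(classify_shap(0.05), "strong")
  expect_equal(classify_shap(0.02), "moderate")
  expect_equal(classify_shap(0.049), "moderate")
  expect_equal(classify_shap(0.019), "weak")
  expect_equal(classify_shap(0), "weak")
  expect_equal(classify_shap(c(0.06, 0.02, 0.019)),
               c("strong", "moderate", "weak"))
  expect_error(classify_shap(-0.01), "non-negative")
})

test_that("partial dependence holds the other predictors at their reference centre", {
  coefs <- c(x1 = 1, x2 = 0, x3 = 0, x4 = 0, x5 = 0, x6 = 0, x7 = 0)
  model <- additive_model(coefs)
  ref <- toy_eval(100, seed = 8)
  flat <- partial_dependence(model, "x2", ref, n_grid = 15)
  expect_equal(diff(range(flat$suitability)), 0)

  rising <- partial_dependence(model, "x1", ref, n_grid = 15)
  expect_true(all(diff(rising$suitability) >= 0))
  expect_equal(range(rising$value), range(ref$x1))
  expect_true(all(rising$suitability >= 0 & rising$suitability <= 1))

  # median vs mean conditioning changes the curve level for skewed references
  ref$x2 <- c(rep(0, 90), rep(0.3, 10))
  md <- partial_dependence(additive_model(c(x1 = 1, x2 = 1, x3 = 0, x4 = 0,
                                            x5 = 0, x6 = 0, x7 = 0)),
                           "x1", ref, n_grid = 5)
  mn <- partial_dependence(additive_model(c(x1 = 1, x2 = 1, x3 = 0, x4 = 0,
                                            x5 = 0, x6 = 0, x7 = 0)),
                           "x1", ref, n_grid = 5, conditioning = "mean")
  expect_true(all(mn$suitability >= md$suitability))
  expect_error(partial_dependence(model, "nope", ref), "unknown predictor")
})

test_that("collinearity screening reports unit diagonals and closed-form VIF", {
  set.seed(9)
  X <- as.data.frame(matrix(rnorm(300 * 4), 300, 4))
  names(X) <- paste0("v", 1:4)
  cs <- collinearity_screen(X)
  expect_equal(diag(cs$correlation), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(cs$correlation))
  expect_true(all(cs$vif >= 1 - 1e-9))
  expect_true(all(cs$vif < 1.2))   # independent draws

  # near-duplicate column: VIF explodes; closed form 1/(1-R^2) verified
  X$v5 <- X$v1 + rnorm(300, sd = 0.01)
  cs2 <- collinearity_screen(X)
  r2 <- summary(lm(v5 ~ v1 + v2 + v3 + v4, data = X))$r.squared
  expect_equal(cs2$vif[["v5"]], 1 / (1 - r2), tolerance = 1e-9)
  expect_gt(cs2$vif[["v5"]], 100)

  X$v6 <- 2 * X$v2            # exact collinearity
  expect_equal(collinearity_screen(X)$vif[["v6"]], Inf)
  expect_error(collinearity_screen(transform(X, v7 = 1)), "constant")
})

test_that("interpretation statistics ignore evaluation-row order", {
  fx <- fitted_fixture()
  model <- fx$forest
  n <- nrow(fx$train)
  ev <- fx$train[c(1:30, (n - 29):n), ]   # both classes represented
  perm <- sample(nrow(ev))
  imp1 <- permutation_importance(model, ev, n_reps = 4, seed = 5)
  imp2 <- permutation_importance(model, ev[perm, ], n_reps = 4, seed = 5)
  # the permutation draws differ, but zero/nonzero structure and scale agree
  expect_equal(imp1$delta_auc, imp2$delta_auc, tolerance = 0.2)
  sh1 <- mean_abs_shap(shap_values(model, ev[1:20, ], ev[21:30, ]))
  sh2 <- mean_abs_shap(shap_values(model, ev[1:20, ], ev[30:21, ]))
  expect_equal(sort(unname(sh1)), sort(unname(sh2)), tolerance = 1e-9)
})
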