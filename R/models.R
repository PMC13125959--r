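# The two ensemble members: a MaxEnt-style L1-penalized logistic model on
# linear/quadratic/product/hinge features with cloglog-scaled suitability,
# and a random-forest probability classifier.

#' Feature expansion specification for the MaxEnt-style model
#'
#' @param classes Subset of `c("linear", "quadratic", "product", "hinge")`.
#' @param n_knots Hinge knots per predictor per direction (default 10),
#'   equally spaced strictly between the training minimum and maximum.
#' @return A `feature_spec`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "product", "hinge"),
                         n_knots = 10) {
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(classes = classes, n_knots = as.integer(n_knots)),
            class = "feature_spec")
}

#' Expand predictors into MaxEnt-style features
#'
#' Each predictor is min-max scaled to \[0, 1\] using the *training* bounds
#' (passed back in via `bounds` at prediction time, so there is no leakage),
#' then expanded into linear, quadratic, pairwise-product, forward-hinge and
#' reverse-hinge columns. With 7 predictors and 10 knots that is
#' 7 + 7 + 21 + 70 + 70 = 175 columns. Constant predictors keep a zero
#' linear column but their quadratic/hinge features are dropped with a
#' warning.
#'
#' @param X Data frame or matrix of predictor values (no missing values).
#' @param spec A `feature_spec`.
#' @param bounds Optional 2-row matrix (min/max per predictor) from a
#'   previous training expansion; computed from `X` when `NULL`.
#' @return Numeric feature matrix with attributes `bounds` and `spec`.
#' @export
build_features <- function(X, spec = feature_spec(), bounds = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature expansion requires complete predictor rows")
  p <- ncol(X)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  if (is.null(bounds)) {
    bounds <- rbind(min = apply(X, 2, min), max = apply(X, 2, max))
    colnames(bounds) <- nms
  }
  span <- bounds["max", ] - bounds["min", ]
  constant <- span <= 0
  if (any(constant) && any(c("quadratic", "hinge") %in% spec$classes))
    warning("constant predictor(s) ", paste(nms[constant], collapse = ", "),
            ": quadratic/hinge features dropped")
  Z <- sweep(X, 2, bounds["min", ], `-`)
  Z <- sweep(Z, 2, ifelse(constant, 1, span), `/`)
  Z <- pmin(pmax(Z, 0), 1)
  Z[, constant] <- 0

  cols <- list()
  if ("linear" %in% spec$classes) {
    L <- Z; colnames(L) <- paste0("lin_", nms); cols$linear <- L
  }
  if ("quadratic" %in% spec$classes) {
    Q <- Z[, !constant, drop = FALSE]^2
    colnames(Q) <- paste0("quad_", nms[!constant]); cols$quadratic <- Q
  }
  if ("product" %in% spec$classes && p >= 2) {
    pr <- utils::combn(p, 2)
    P <- Z[, pr[1, ], drop = FALSE] * Z[, pr[2, ], drop = FALSE]
    colnames(P) <- paste0("prod_", nms[pr[1, ]], "_", nms[pr[2, ]])
    cols$product <- P
  }
  if ("hinge" %in% spec$classes && spec$n_knots > 0) {
    knots <- seq_len(spec$n_knots) / (spec$n_knots + 1)  # on the [0,1] scale
    hf <- list(); hr <- list()
    for (j in which(!constant)) {
      for (k in knots) {
        hf[[paste0("hingef_", nms[j], "_", format(k, digits = 3))]] <-
          pmax(0, Z[, j] - k) / (1 - k)
        hr[[paste0("hinger_", nms[j], "_", format(k, digits = 3))]] <-
          pmax(0, k - Z[, j]) / k
      }
    }
    if (length(hf)) {
      cols$hingef <- do.call(cbind, hf)
      cols$hinger <- do.call(cbind, hr)
    }
  }
  F <- do.call(cbind, cols)
  attr(F, "bounds") <- bounds
  attr(F, "spec") <- spec
  F
}

cloglog <- function(eta) 1 - exp(-exp(eta))

#' Fit the MaxEnt-style penalized logistic member
#'
#' An L1-penalized logistic regression of the presence/pseudo-absence label
#' on the expanded feature set (the presence/background reduction of the
#' MaxEnt formulation), with the linear predictor mapped to suitability on
#' the cloglog scale: `s = 1 - exp(-exp(eta + c))`. The calibration constant
#' `c` follows the tau = 0.5 convention: the mean linear predictor over
#' presence rows maps to suitability `tau`. The penalty is chosen by
#' held-out log-likelihood on an internal stratified split over a small
#' lambda grid.
#'
#' @param train Training table from [build_training_table()].
#' @param spec A `feature_spec`.
#' @param penalty_path Optional decreasing lambda grid for [glmnet::glmnet()];
#'   a default data-driven grid is used when `NULL`.
#' @param seed Integer seed (internal validation split).
#' @param tau Calibration suitability at the mean presence linear predictor
#'   (default 0.5).
#' @return A `maxent_sdm` (also `fitted_sdm`); predictions via
#'   [predict_sdm()] lie in \[0, 1\].
#' @export
fit_maxent <- function(train, spec = feature_spec(), penalty_path = NULL,
                       seed = 1, tau = 0.5) {
  y <- train$label
  if (length(unique(y)) < 2) stop("training labels are degenerate (one class)")
  if (sum(y == 1) < 20)
    warning("fewer than 20 presences; penalized fit may be unstable")
  X <- as.matrix(train[, setdiff(names(train), c("label", "cell")), drop = FALSE])
  F <- build_features(X, spec)
  # glmnet requires >= 2 columns; pad degenerate expansions with a zero column
  pad <- ncol(F) < 2
  if (pad) F <- cbind(F, .zero_pad = 0)

  set.seed(derive_seed(seed, "maxent-lambda"))
  val <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1, round(0.2 * length(ix))))))
  path_args <- if (is.null(penalty_path))
    list(nlambda = 60, lambda.min.ratio = 1e-3) else list(lambda = penalty_path)
  fit_path <- do.call(glmnet::glmnet,
                      c(list(x = F[-val, , drop = FALSE], y = y[-val],
                             family = "binomial", alpha = 1,
                             standardize = FALSE), path_args))
  pv <- stats::predict(fit_path, F[val, , drop = FALSE], type = "response")
  pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
  loglik <- colSums(log(pv) * y[val] + log(1 - pv) * (1 - y[val]))
  lambda <- fit_path$lambda[which.max(loglik)]

  fit <- glmnet::glmnet(F, y, family = "binomial", alpha = 1,
                        lambda = fit_path$lambda, standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda))
  eta <- as.numeric(cbind(1, F) %*% beta)
  calib <- log(-log(1 - tau)) - mean(eta[y == 1])

  structure(list(algorithm = "maxent-style",
                 beta = beta, lambda = lambda, calib = calib, tau = tau,
                 pad = pad,
                 bounds = attr(F, "bounds"), spec = spec,
                 predictors = colnames(X),
                 meta = list(n_presence = sum(y == 1),
                             n_background = sum(y == 0), seed = seed)),
            class = c("maxent_sdm", "fitted_sdm"))
}

#' Fit the random-forest member
#'
#' A 500-tree classification forest with `mtry = floor(sqrt(p))`; suitability
#' is the averaged class probability of presence.
#'
#' @param train Training table from [build_training_table()].
#' @param n_trees Number of trees (default 500).
#' @param mtry Predictors tried per split (default `floor(sqrt(p))`).
#' @param seed Integer seed.
#' @return A `forest_sdm` (also `fitted_sdm`).
#' @export
fit_forest <- function(train, n_trees = 500, mtry = NULL, seed = 1) {
  y <- factor(train$label, levels = c(0, 1))
  if (length(unique(train$label)) < 2) stop("training labels are degenerate (one class)")
  X <- train[, setdiff(names(train), c("label", "cell")), drop = FALSE]
  if (is.null(mtry)) mtry <- floor(sqrt(ncol(X)))
  set.seed(derive_seed(seed, "forest"))
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry)
  structure(list(algorithm = "forest", forest = rf,
                 n_trees = n_trees, mtry = mtry,
                 predictors = colnames(X),
                 meta = list(n_presence = sum(train$label == 1),
                             n_background = sum(train$label == 0), seed = seed)),
            class = c("forest_sdm", "fitted_sdm"))
}

#' Predict suitability for tabular predictor rows
#'
#' @param model A `fitted_sdm`.
#' @param newdata Data frame/matrix containing the model's predictor columns.
#' @return Numeric vector of suitabilities in \[0, 1\].
#' @export
predict_sdm <- function(model, newdata) UseMethod("predict_sdm")

#' @export
predict_sdm.maxent_sdm <- function(model, newdata) {
  X <- as.matrix(as.data.frame(newdata)[, model$predictors, drop = FALSE])
  F <- build_features(X, model$spec, bounds = model$bounds)
  if (isTRUE(model$pad)) F <- cbind(F, .zero_pad = 0)
  eta <- as.numeric(cbind(1, F) %*% model$beta)
  cloglog(eta + model$calib)
}

#' @export
predict_sdm.forest_sdm <- function(model, newdata) {
  nd <- as.data.frame(newdata)[, model$predictors, drop = FALSE]
  as.numeric(stats::predict(model$forest, nd, type = "prob")[, "1"])
}

#' Project a fitted model across a predictor stack
#'
#' Evaluates suitability on every valid cell, block-wise so memory stays
#' bounded; masked cells stay masked. Layer names must cover the model's
#' training predictors (extra layers are ignored; insertion order is
#' irrelevant).
#'
#' @param model A `fitted_sdm` (or `ensemble_sdm`).
#' @param stack A `predictor_stack`.
#' @param block_cells Cells evaluated per block (default 20000).
#' @return An `sdm_raster` suitability surface in \[0, 1\].
#' @export
predict_surface <- function(model, stack, block_cells = 20000) {
  missing_layers <- setdiff(model$predictors, names(stack$layers))
  if (length(missing_layers))
    stop("stack lacks layer(s): ", paste(missing_layers, collapse = ", "))
  cells <- stack_valid_cells(stack)
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  for (start in seq(1, length(cells), by = block_cells)) {
    blk <- cells[start:min(start + block_cells - 1, length(cells))]
    vals <- stack_extract(stack, blk)
    rc <- cell_to_rowcol(stack$grid, blk)
    out[cbind(rc$row, rc$col)] <- predict_sdm(model, vals)
  }
  sdm_raster(stack$grid, out)
}
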