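# Model interpretation: permutation DeltaAUC importance, Shapley
# attributions on the suitability scale, partial dependence, and
# collinearity screening.

#' Permutation importance as mean AUC drop
#'
#' For each predictor, the column is permuted `n_reps` times and the mean
#' drop in AUC relative to the unpermuted model is reported. Larger DeltaAUC
#' means the predictor contributes more to discrimination; a predictor the
#' model ignores scores exactly 0.
#'
#' @param model A `fitted_sdm` (or ensemble).
#' @param eval_table Table with `label` and the model's predictor columns.
#' @param n_reps Permutations per predictor (default 10).
#' @param seed Integer seed.
#' @return Data frame `predictor`, `delta_auc` plus attribute
#'   `baseline_auc`.
#' @export
permutation_importance <- function(model, eval_table, n_reps = 10, seed = 1) {
  if (length(unique(eval_table$label)) < 2)
    stop("eval table needs both classes")
  base_auc <- roc_auc(predict_sdm(model, eval_table), eval_table$label)
  set.seed(derive_seed(seed, "perm-importance"))
  deltas <- vapply(model$predictors, function(p) {
    mean(vapply(seq_len(n_reps), function(r) {
      tb <- eval_table
      tb[[p]] <- sample(tb[[p]])
      base_auc - roc_auc(predict_sdm(model, tb), tb$label)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(predictor = model$predictors, delta_auc = unname(deltas))
  attr(out, "baseline_auc") <- base_auc
  out
}

#' Shapley attributions of predicted suitability
#'
#' Attributes each prediction (on the 0-1 suitability scale) across the
#' predictors. Coalition values marginalise the removed predictors over a
#' background sample. With the default exact estimator all `2^p` coalitions
#' are enumerated (cheap at p = 7), so local accuracy -- base value plus
#' contributions equals the prediction -- holds exactly. A Monte-Carlo
#' permutation estimator (`method = "sampling"`) is available for larger p.
#'
#' @param model A `fitted_sdm` (or ensemble).
#' @param background Data frame of background rows (predictor columns).
#' @param eval_points Data frame of rows to explain.
#' @param method `"exact"` (default) or `"sampling"`.
#' @param n_mc Monte-Carlo permutations for `"sampling"`.
#' @param seed Integer seed (sampling only).
#' @return A `shap_result`: matrix `contributions` (points x predictors),
#'   `base_value`, and `predictions`.
#' @export
shap_values <- function(model, background, eval_points,
                        method = c("exact", "sampling"), n_mc = 2000, seed = 1) {
  method <- match.arg(method)
  preds <- model$predictors
  p <- length(preds)
  bg <- as.data.frame(background)[, preds, drop = FALSE]
  ev <- as.data.frame(eval_points)[, preds, drop = FALSE]
  if (!nrow(bg)) stop("background sample is empty")
  n_ev <- nrow(ev); n_bg <- nrow(bg)

  if (method == "exact") {
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    colnames(masks) <- preds
    n_m <- nrow(masks)   # 2^p
    # one prediction batch: for every eval point x coalition x background row
    big <- bg[rep(seq_len(n_bg), times = n_m * n_ev), , drop = FALSE]
    mask_rep <- masks[rep(rep(seq_len(n_m), each = n_bg), times = n_ev), ,
                      drop = FALSE]
    ev_rep <- ev[rep(seq_len(n_ev), each = n_bg * n_m), , drop = FALSE]
    for (j in seq_len(p)) big[mask_rep[, j], j] <- ev_rep[mask_rep[, j], j]
    f <- predict_sdm(model, big)
    # v[point, coalition] = mean over background rows
    v <- matrix(colMeans(matrix(f, nrow = n_bg)), nrow = n_m)  # n_m x n_ev
    sizes <- rowSums(masks)
    wgt <- function(s) exp(lfactorial(s) + lfactorial(p - s - 1) - lfactorial(p))
    contrib <- matrix(0, n_ev, p, dimnames = list(NULL, preds))
    bit <- 2^(seq_len(p) - 1)
    mask_id <- as.integer(masks %*% bit)           # 0-based coalition code
    row_of <- integer(n_m); row_of[mask_id + 1] <- seq_len(n_m)
    for (j in seq_len(p)) {
      without <- which(!masks[, j])
      with_j <- row_of[mask_id[without] + bit[j] + 1]
      w <- wgt(sizes[without])
      contrib[, j] <- as.numeric(t(v[with_j, , drop = FALSE] -
                                   v[without, , drop = FALSE]) %*% w)
    }
    base <- v[row_of[1], ]                          # empty coalition
    prediction <- v[row_of[n_m], ]                  # full coalition
  } else {
    set.seed(derive_seed(seed, "shap-mc"))
    contrib <- matrix(0, n_ev, p, dimnames = list(NULL, preds))
    base <- rep(mean(predict_sdm(model, bg)), n_ev)
    for (i in seq_len(n_ev)) {
      acc <- numeric(p)
      for (m in seq_len(n_mc)) {
        perm <- sample(p)
        b <- bg[sample(n_bg, 1), , drop = FALSE]
        cur <- b
        f_prev <- predict_sdm(model, cur)
        for (j in perm) {
          cur[, j] <- ev[i, j]
          f_new <- predict_sdm(model, cur)
          acc[j] <- acc[j] + (f_new - f_prev)
          f_prev <- f_new
        }
      }
      contrib[i, ] <- acc / n_mc
    }
    prediction <- predict_sdm(model, ev)
  }
  structure(list(contributions = contrib, base_value = unname(base),
                 predictions = unname(prediction), method = method),
            class = "shap_result")
}

#' Mean absolute Shapley value per predictor
#' @param shap A `shap_result`.
#' @return Named numeric vector.
#' @export
mean_abs_shap <- function(shap) colMeans(abs(shap$contributions))

#' Classify a mean |SHAP| value into effect classes
#'
#' `>= 0.05` is strong, `[0.02, 0.05)` moderate, `< 0.02` weak (boundaries
#' inclusive at 0.05 for strong and at 0.02 for moderate).
#'
#' @param x Non-negative mean absolute SHAP value(s).
#' @return Character vector of `"strong"`, `"moderate"`, `"weak"`.
#' @export
classify_shap <- function(x) {
  if (any(x < 0)) stop("mean |SHAP| must be non-negative")
  ifelse(x >= 0.05, "strong", ifelse(x >= 0.02, "moderate", "weak"))
}

#' Partial dependence of suitability on one predictor
#'
#' The focal predictor is varied over `n_grid` equally spaced values spanning
#' its observed range in `reference`, with every other predictor held at its
#' reference median (or mean).
#'
#' @param model A `fitted_sdm` (or ensemble).
#' @param predictor Focal predictor name.
#' @param reference Data frame supplying the observed range and conditioning
#'   values (typically the training table).
#' @param n_grid Curve resolution (default 25).
#' @param conditioning `"median"` (default) or `"mean"`.
#' @return A `pdp_curve` data.frame with columns `value` and `suitability`.
#' @export
partial_dependence <- function(model, predictor, reference, n_grid = 25,
                               conditioning = c("median", "mean")) {
  conditioning <- match.arg(conditioning)
  if (!predictor %in% model$predictors) stop("unknown predictor: ", predictor)
  ref <- as.data.frame(reference)[, model$predictors, drop = FALSE]
  centre <- if (conditioning == "median") vapply(ref, stats::median, numeric(1))
            else vapply(ref, mean, numeric(1))
  grid_vals <- seq(min(ref[[predictor]]), max(ref[[predictor]]),
                   length.out = n_grid)
  nd <- as.data.frame(as.list(centre))[rep(1, n_grid), , drop = FALSE]
  nd[[predictor]] <- grid_vals
  out <- data.frame(value = grid_vals, suitability = predict_sdm(model, nd))
  class(out) <- c("pdp_curve", "data.frame")
  attr(out, "predictor") <- predictor
  attr(out, "conditioning") <- conditioning
  out
}

#' Collinearity screen: Pearson correlations and VIF
#'
#' Pairwise Pearson correlation matrix plus per-predictor variance inflation
#' factors `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the
#' others; a perfectly collinear predictor reports `Inf`.
#'
#' @param X Data frame or matrix of predictor values (>= 3 rows, no constant
#'   column).
#' @return List with `correlation` (symmetric, unit diagonal) and `vif`
#'   (named vector).
#' @export
collinearity_screen <- function(X) {
  X <- as.data.frame(X)
  if (nrow(X) < 3) stop("need at least 3 rows")
  if (any(vapply(X, function(v) stats::sd(v) == 0, logical(1))))
    stop("constant predictor column")
  cm <- stats::cor(as.matrix(X))
  vif <- vapply(seq_along(X), function(j) {
    r2 <- suppressWarnings(   # "essentially perfect fit" on exact collinearity
      summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  list(correlation = cm, vif = vif)
}
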