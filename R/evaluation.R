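# Stratified k-fold cross-validation and discrimination metrics.

#' Stratified k-fold assignment
#'
#' Within each class, rows are shuffled and dealt round-robin to folds, so
#' per-class counts across folds differ by at most one.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per row.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k rows (smallest has ", min(tab), ")")
  set.seed(derive_seed(seed, "kfold"))
  folds <- integer(length(labels))
  for (cl in names(tab)) {
    ix <- sample(which(labels == cl))
    folds[ix] <- rep_len(seq_len(k), length(ix))
  }
  folds
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a random presence outscores a random
#' absence, with ties counted one half (midrank formula).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (1 = presence).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes")
  r <- rank(scores)   # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic at the maximum-Youden threshold
#'
#' Scans candidate thresholds (midpoints between consecutive distinct scores,
#' plus sentinels below/above all scores) for the one maximizing Youden's
#' J = sensitivity + specificity - 1, classifying presence where
#' `score >= threshold`. Ties are broken toward the lower (more sensitive)
#' threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return List with `tss` and `threshold`.
#' @export
tss_max_youden <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("tss_max_youden needs both classes")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  j <- vapply(cand, function(th) {
    sens <- sum(scores >= th & labels == 1) / n1
    spec <- sum(scores < th & labels == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]   # lowest threshold among ties
  list(tss = j[best], threshold = cand[best])
}

#' Cross-validate a model-fitting function
#'
#' Stratified k-fold CV: for each fold the model is fitted on the remaining
#' folds (with a fold-derived seed) and AUC/TSS are computed on the held-out
#' fold. Fold-level metrics are aggregated as mean and sample SD
#' (denominator k - 1).
#'
#' @param fit_fn `function(train, seed) -> fitted_sdm`.
#' @param train Training table (needs a `label` column).
#' @param k Folds (default 5).
#' @param seed Integer master seed.
#' @param algorithm Label stored in the result.
#' @return A `cv_metrics` object: data.frame `folds` (auc, tss, threshold)
#'   plus `mean_auc`, `sd_auc`, `mean_tss`, `sd_tss`, `k`, `algorithm`.
#' @export
cross_validate <- function(fit_fn, train, k = 5, seed = 1, algorithm = "model") {
  folds <- stratified_kfold(train$label, k = k, seed = seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- train[folds != f, , drop = FALSE]
    te <- train[folds == f, , drop = FALSE]
    fit <- tryCatch(fit_fn(tr, seed = derive_seed(seed, paste0("fold", f))),
                    error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                                             call. = FALSE))
    sc <- predict_sdm(fit, te)
    ty <- tss_max_youden(sc, te$label)
    data.frame(fold = f, auc = roc_auc(sc, te$label),
               tss = ty$tss, threshold = ty$threshold)
  })
  folds_df <- do.call(rbind, per_fold)
  structure(list(folds = folds_df,
                 mean_auc = mean(folds_df$auc), sd_auc = stats::sd(folds_df$auc),
                 mean_tss = mean(folds_df$tss), sd_tss = stats::sd(folds_df$tss),
                 k = k, algorithm = algorithm),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("<cv_metrics> %s, %d-fold: AUC %.3f +/- %.3f, TSS %.3f +/- %.3f\n",
              x$algorithm, x$k, x$mean_auc, x$sd_auc, x$mean_tss, x$sd_tss))
  invisible(x)
}

#' Export fold-level and summary CV metrics as a table
#' @param ... One or more `cv_metrics` objects.
#' @return Data frame with one row per fold per model plus summary rows.
#' @export
cv_metrics_table <- function(...) {
  do.call(rbind, lapply(list(...), function(m) {
    rbind(cbind(algorithm = m$algorithm, m$folds),
          data.frame(algorithm = m$algorithm, fold = "mean", auc = m$mean_auc,
                     tss = m$mean_tss, threshold = NA),
          data.frame(algorithm = m$algorithm, fold = "sd", auc = m$sd_auc,
                     tss = m$sd_tss, threshold = NA))
  }))
}
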