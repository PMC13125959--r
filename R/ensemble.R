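# Performance-gated, AUC-weighted ensembling, P10 thresholding and
# suitable-area accounting.

#' Gate candidate members on cross-validated performance
#'
#' A member is retained only if its mean CV AUC and mean CV TSS both reach
#' the (inclusive) gates.
#'
#' @param cv_list List of `cv_metrics`.
#' @param auc_min,tss_min Inclusive gates (defaults 0.90 and 0.70).
#' @return Integer indices of retained members; errors with the metric table
#'   if none pass.
#' @export
gate_members <- function(cv_list, auc_min = 0.90, tss_min = 0.70) {
  if (!length(cv_list)) stop("no candidate members")
  keep <- vapply(cv_list, function(m)
    m$mean_auc >= auc_min && m$mean_tss >= tss_min, logical(1))
  if (!any(keep)) {
    tab <- paste(vapply(cv_list, function(m)
      sprintf("%s: AUC %.3f TSS %.3f", m$algorithm, m$mean_auc, m$mean_tss),
      character(1)), collapse = "; ")
    stop("no members passed the gate (AUC >= ", auc_min, ", TSS >= ", tss_min,
         "): ", tab)
  }
  which(keep)
}

#' AUC-proportional ensemble weights
#' @param mean_aucs Positive mean CV AUCs of the retained members.
#' @return Weights `auc_i / sum(auc)`, summing to 1.
#' @export
ensemble_weights <- function(mean_aucs) {
  if (any(mean_aucs <= 0)) stop("AUCs must be positive")
  mean_aucs / sum(mean_aucs)
}

#' Weighted-mean ensemble suitability surface
#' @param surfaces List of member `sdm_raster` suitability surfaces.
#' @param weights Member weights (same length, summing to 1).
#' @return An `sdm_raster`; cellwise weighted mean, bounded by member
#'   min/max, masked where any member is masked.
#' @export
ensemble_surface <- function(surfaces, weights) {
  if (length(surfaces) != length(weights)) stop("weights do not align with members")
  g <- surfaces[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (i in seq_along(surfaces)) {
    if (!grid_equal(surfaces[[i]]$grid, g)) stop("member surface grid mismatch")
    acc <- acc + weights[i] * surfaces[[i]]$values
  }
  sdm_raster(g, acc)
}

#' P10 threshold from calibration-presence suitability
#'
#' The 10th percentile of suitability at presence locations, using linear
#' interpolation between order statistics at position `h = (n + 1) p`
#' (the Weibull convention, `type = 6`). This convention is chosen because
#' it honours the binding contract of the threshold: for any n >= 10, at
#' least 90% of the calibration presences score at or above the returned
#' value (interpolating at `h = (n - 1) p + 1` instead can misclassify up to
#' 2 extra presences). Below 10 values the empirical minimum is used, with a
#' warning.
#'
#' @param values Suitability at presence locations.
#' @return The P10 threshold.
#' @export
p10_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no presence suitability values")
  if (length(values) < 10) {
    warning("fewer than 10 presence values; using the empirical minimum")
    return(min(values))
  }
  unname(stats::quantile(values, 0.10, type = 6))
}

#' Binarize a suitability surface at a threshold
#'
#' Presence (1) where suitability >= threshold (inclusive), absence (0)
#' otherwise; masked cells stay masked.
#'
#' @param surface An `sdm_raster` in \[0, 1\].
#' @param threshold Threshold in \[0, 1\].
#' @return An `sdm_raster` in {0, 1}.
#' @export
binarize <- function(surface, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  v <- surface$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  sdm_raster(surface$grid, out)
}

#' Total suitable area of a binary surface
#' @param binary An `sdm_raster` in {0, 1}.
#' @param areas Cell-area `sdm_raster` from [cell_area_raster()] (same grid).
#' @return Area in km^2 of cells equal to 1 (masked cells excluded).
#' @export
suitable_area <- function(binary, areas) {
  if (!grid_equal(binary$grid, areas$grid)) stop("grid mismatch")
  sum(areas$values[!is.na(binary$values) & binary$values == 1])
}

#' Build a gated, AUC-weighted ensemble
#'
#' Applies the performance gate, computes AUC-proportional weights over the
#' retained members, projects each member on the baseline stack, derives each
#' member's own P10 from its predictions at the presence cells, forms the
#' weighted-mean baseline surface, and recomputes the ensemble P10 from the
#' ensemble suitability at the same presences.
#'
#' @param members List of `fitted_sdm` (same order as `cv_list`).
#' @param cv_list List of `cv_metrics` for the members.
#' @param stack Baseline `predictor_stack`.
#' @param presence_cells Integer presence cell indices.
#' @param auc_min,tss_min Gates passed to [gate_members()].
#' @return An `ensemble_sdm`: retained `members`, `weights`, `p10`,
#'   `member_p10`, baseline `surface`, `baseline_area_km2` and the presence
#'   cells.
#' @export
build_ensemble <- function(members, cv_list, stack, presence_cells,
                           auc_min = 0.90, tss_min = 0.70) {
  keep <- gate_members(cv_list, auc_min, tss_min)
  members <- members[keep]
  cv_list <- cv_list[keep]
  w <- ensemble_weights(vapply(cv_list, `[[`, numeric(1), "mean_auc"))

  surfaces <- lapply(members, predict_surface, stack = stack)
  pres_rm <- presence_cells   # row-major indices into the value matrices
  member_p10 <- vapply(surfaces, function(s)
    p10_threshold(as.vector(t(s$values))[pres_rm]), numeric(1))
  ens <- ensemble_surface(surfaces, w)
  p10 <- p10_threshold(as.vector(t(ens$values))[pres_rm])
  areas <- cell_area_raster(stack$grid)

  structure(list(members = members, cv = cv_list, weights = w,
                 p10 = p10, member_p10 = member_p10,
                 surface = ens,
                 baseline_area_km2 = suitable_area(binarize(ens, p10), areas),
                 presence_cells = presence_cells,
                 predictors = members[[1]]$predictors,
                 algorithm = "ensemble"),
            class = c("ensemble_sdm", "fitted_sdm"))
}

#' @export
predict_sdm.ensemble_sdm <- function(model, newdata) {
  n <- nrow(as.data.frame(newdata))
  preds <- matrix(0, n, length(model$members))
  for (i in seq_along(model$members))
    preds[, i] <- predict_sdm(model$members[[i]], newdata)
  as.numeric(preds %*% model$weights)
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat(sprintf("<ensemble_sdm> %d member(s), weights %s, P10 %.3f (members: %s)\n",
              length(x$members),
              paste(sprintf("%.4f", x$weights), collapse = "/"),
              x$p10, paste(sprintf("%.3f", x$member_p10), collapse = "/")))
  invisible(x)
}

#' Export an ensemble description as structured text
#' @param ensemble An `ensemble_sdm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_description <- function(ensemble, path) {
  lines <- c(
    "ensemble:",
    sprintf("  members: %s",
            paste(vapply(ensemble$members, `[[`, character(1), "algorithm"),
                  collapse = ", ")),
    sprintf("  weights: %s", paste(format(ensemble$weights, digits = 6),
                                   collapse = ", ")),
    sprintf("  member_p10: %s", paste(format(ensemble$member_p10, digits = 6),
                                      collapse = ", ")),
    sprintf("  ensemble_p10: %s", format(ensemble$p10, digits = 6)),
    sprintf("  baseline_area_km2: %s", format(ensemble$baseline_area_km2,
                                              digits = 10)))
  writeLines(lines, path)
  invisible(path)
}
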