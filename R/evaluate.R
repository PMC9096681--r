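# Agreement and detection metrics: descriptive statistics, regression
# agreement (MBE, RMSE, adjusted R-squared), detection F1, and the
# sphere-target report used to assess fused temperatures.

#' Regression agreement metrics
#'
#' Compares predicted against observed values: mean bias error
#' `MBE = mean(predicted - observed)`, `RMSE`, the coefficient of
#' determination of the least-squares line of predicted on observed, and
#' its adjusted form `R2_adj = 1 - (1 - R2)(n - 1)/(n - p - 1)`.
#' Descriptive statistics (min, max, mean, SD) summarise the predicted
#' values.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 3).
#' @param p number of predictors (default 1).
#' @return An object of class `metrics_report`: list with `n`, `min`,
#'   `max`, `mean`, `sd`, `mbe`, `rmse`, `r2`, `r2_adj`, `slope`,
#'   `intercept`.
#' @export
regression_metrics <- function(observed, predicted, p = 1) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch")
  if (n <= p + 1)
    stop("insufficient data: need n > p + 1 (n = ", n, ", p = ", p, ")")
  diff <- predicted - observed
  fit <- lm(predicted ~ observed)
  r2 <- summary(fit)$r.squared
  structure(list(n = n, min = min(predicted), max = max(predicted),
                 mean = mean(predicted), sd = sd(predicted),
                 mbe = mean(diff), rmse = sqrt(mean(diff^2)),
                 r2 = r2,
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Metrics (n = %d): mean %.3f [%.3f, %.3f], SD %.3f\n",
    x$n, x$mean, x$min, x$max, x$sd))
  cat(sprintf("  MBE %.4f  RMSE %.4f  R2 %.4f  R2_adj %.4f\n",
              x$mbe, x$rmse, x$r2, x$r2_adj))
  invisible(x)
}

#' Detection precision, recall and F1
#'
#' Greedy nearest-distance matching of detected against truth positions
#' within `match_radius`; each truth item is matched at most once.
#'
#' @param detected,truth position matrices (rows = items, any common
#'   dimensionality); vectors are treated as 1D positions.
#' @param match_radius maximum match distance, metres.
#' @return An object of class `detection_report`: list with `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.
#' @export
detection_f1 <- function(detected, truth, match_radius) {
  stopifnot(match_radius > 0)
  if (is.null(dim(detected))) detected <- matrix(detected, ncol = 1)
  if (is.null(dim(truth))) truth <- matrix(truth, ncol = 1)
  nd <- nrow(detected); nt <- nrow(truth)
  tp <- nrow(greedy_match(detected, truth, match_radius))
  fp <- nd - tp; fn <- nt - tp
  precision <- if (nd > 0) tp / nd else 0
  recall <- if (nt > 0) tp / nt else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "Detection: TP %d FP %d FN %d  P %.3f R %.3f F1 %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# greedy one-to-one nearest-distance matching; returns a two-column
# matrix of (detected index, truth index) pairs
greedy_match <- function(detected, truth, match_radius) {
  nd <- nrow(detected); nt <- nrow(truth)
  out <- matrix(integer(0), 0, 2)
  if (nd == 0 || nt == 0) return(out)
  d <- matrix(0, nd, nt)
  for (j in seq_len(ncol(detected)))
    d <- d + outer(detected[, j], truth[, j], "-")^2
  d <- sqrt(d)
  pairs <- which(d <= match_radius, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(out)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- used_t[j] <- TRUE
      out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Sphere-target temperature report
#'
#' Extracts each evaluation sphere's points from a fused cloud (within
#' `radius + tol` of its centre), summarises the fused temperatures per
#' sphere, and regresses the per-sphere means against the manual
#' reference temperatures per material class (S_W white, S_B black).
#' Spheres with no points are flagged and excluded from the regression.
#'
#' @param cloud fused [point_cloud()] with temperatures.
#' @param spheres data.frame with columns `x`, `y`, `z`, `radius`,
#'   `material` (and optionally `sphere_id`).
#' @param manual per-sphere manual reference temperatures, degC.
#' @param tol extraction tolerance beyond the sphere radius, metres.
#' @param sentinel out-of-view marker excluded from statistics, degC.
#' @return List with `per_sphere` (data.frame: n, min, max, mean, sd,
#'   manual, material, flagged) and `per_material` (named list of
#'   `metrics_report`).
#' @export
sphere_report <- function(cloud, spheres, manual, tol = 0.01,
                          sentinel = -10) {
  stopifnot(nrow(spheres) == length(manual))
  rows <- NULL
  for (i in seq_len(nrow(spheres))) {
    ctr <- c(spheres$x[i], spheres$y[i], spheres$z[i])
    d <- sqrt(rowSums(sweep(cloud$points, 2, ctr)^2))
    idx <- which(d <= spheres$radius[i] + tol)
    temps <- cloud$temperature[idx]
    temps <- temps[!is.na(temps) & temps != sentinel]
    rows <- rbind(rows, data.frame(
      sphere = i, material = spheres$material[i], n = length(temps),
      min = if (length(temps)) min(temps) else NA_real_,
      max = if (length(temps)) max(temps) else NA_real_,
      mean = if (length(temps)) mean(temps) else NA_real_,
      sd = if (length(temps) > 1) sd(temps) else
        if (length(temps) == 1) 0 else NA_real_,
      manual = manual[i], flagged = length(temps) == 0))
  }
  per_material <- list()
  for (mat in unique(rows$material)) {
    sel <- rows$material == mat & !rows$flagged
    if (sum(sel) >= 3)
      per_material[[mat]] <- regression_metrics(rows$manual[sel],
                                                rows$mean[sel])
  }
  list(per_sphere = rows, per_material = per_material)
}
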