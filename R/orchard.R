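# From thermal tree clouds to per-fruit surface temperature: align the
# two scanned sides, localize stems from a bivariate density histogram,
# cut cylindrical tree segments, compute eigenvalue curvature and
# reflectance features, threshold them, cluster the candidates into
# fruits and report FST statistics with an east/west label.

#' Align the two scanned sides of a tree row
#'
#' Refines an initial rigid estimate (from platform geometry) by
#' point-to-point ICP of side B onto side A, then merges the clouds.
#' Per-point side provenance is retained in the merged cloud's `extra`
#' table (`side`: 0 = A, 1 = B).
#'
#' @param side_a,side_b [point_cloud()] objects.
#' @param init initial [rigid_transform()] mapping side B into side A's
#'   frame (must be within ICP capture range).
#' @param voxel registration downsampling voxel, metres.
#' @param max_iter,tol ICP iteration controls.
#' @param max_corr_dist correspondence rejection distance, metres
#'   (opposite sides only truly overlap on thin structures).
#' @return List with `cloud` (merged), `transform` (refined B-to-A),
#'   `mean_dist` (final mean correspondence distance, metres),
#'   `converged`, `history`.
#' @export
align_tree_sides <- function(side_a, side_b, init = rigid_transform(),
                             voxel = 0.03, max_iter = 30, tol = 1e-7,
                             max_corr_dist = 0.06) {
  da <- voxel_downsample(side_a, voxel)
  db <- voxel_downsample(cloud_transform(side_b, init), voxel)
  T_cur <- rigid_transform()
  history <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    bt <- transform_points(T_cur, db$points)
    nn <- nn1_points(da$points, bt)
    # opposite scan sides only overlap on thin structures (leaf planes,
    # trunk silhouettes); capping the correspondence distance keeps the
    # front/back canopy faces from being pulled together
    keep <- nn$dist <= max_corr_dist
    if (sum(keep) < 10) {
      warning("align_tree_sides: too few correspondences within ",
              max_corr_dist, " m")
      break
    }
    history <- c(history, mean(nn$dist[keep]))
    T_upd <- fit_rigid(bt[keep, , drop = FALSE],
                       da$points[nn$idx[keep], , drop = FALSE])
    T_cur <- t_compose(T_upd, T_cur)
    if (abs(prev - history[it]) < tol) { converged <- TRUE; break }
    prev <- history[it]
  }
  if (!converged)
    warning("align_tree_sides: ICP not converged after ", max_iter,
            " iterations (mean distance ", signif(tail(history, 1), 3),
            " m)")
  transform <- t_compose(T_cur, init)
  b_full <- cloud_transform(side_b, transform)
  merged <- cloud_rbind(side_a, b_full, frame_label = side_a$frame_label)
  merged$extra <- data.frame(side = rep(c(0, 1), c(n_points(side_a),
                                                   n_points(side_b))))
  list(cloud = merged, transform = transform,
       mean_dist = if (length(history)) tail(history, 1) else NA_real_,
       converged = converged, history = history)
}

#' Detect stem positions from a bivariate density histogram
#'
#' Builds a 2D point-density histogram over the ground-plane coordinates
#' of the trunk height band, finds local maxima above a percentile floor,
#' applies non-maximum suppression at the tree-spacing scale, and refines
#' each peak as the count-weighted centroid of its 3x3 neighbourhood.
#'
#' @param cloud a [point_cloud()] in a row-aligned frame (z up).
#' @param bin histogram bin size, metres.
#' @param expected expected stem count (a warning is given when fewer
#'   peaks are found; surplus peaks are dropped lowest-density first).
#' @param trunk_band height band containing the trunks, metres.
#' @param floor_quantile percentile floor on occupied-cell counts.
#' @param min_separation non-maximum suppression radius, metres.
#' @return Matrix of stem positions (columns `x`, `y`), ordered along y.
#' @export
detect_stems <- function(cloud, bin = 0.05, expected = NULL,
                         trunk_band = c(0.2, 0.8), floor_quantile = 0.75,
                         min_separation = 0.5) {
  p <- cloud$points
  sel <- p[, 3] >= trunk_band[1] & p[, 3] <= trunk_band[2]
  if (!any(sel)) {
    warning("detect_stems: no points in the trunk height band")
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  xy <- p[sel, 1:2, drop = FALSE]
  x0 <- min(xy[, 1]) - bin; y0 <- min(xy[, 2]) - bin
  ix <- floor((xy[, 1] - x0) / bin) + 1L
  iy <- floor((xy[, 2] - y0) / bin) + 1L
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
  counts[] <- as.integer(tab)
  # floor: percentile of occupied cells, capped relative to the global
  # maximum (when trunks are nearly the only occupants, the percentile
  # alone would land inside the trunk counts and drop weaker stems)
  floor_count <- min(quantile(counts[counts > 0], floor_quantile),
                     0.3 * max(counts))
  peaks <- NULL
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      c0 <- counts[i, j]
      if (c0 < floor_count || c0 == 0) next
      nbh <- counts[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (c0 < max(nbh)) next
      if (sum(nbh == c0) > 1) {
        # plateau tie-break: keep only the raster-first tying cell
        w <- which(nbh == c0, arr.ind = TRUE)
        gi <- i - 2 + w[, 1]; gj <- j - 2 + w[, 2]
        first <- order(gj, gi)[1]
        if (!(gi[first] == i && gj[first] == j)) next
      }
      peaks <- rbind(peaks, c(i, j, c0))
    }
  }
  if (is.null(peaks))
    return(cbind(x = numeric(0), y = numeric(0)))
  peaks <- peaks[order(-peaks[, 3]), , drop = FALSE]
  kept <- NULL
  for (r in seq_len(nrow(peaks))) {
    pos <- (peaks[r, 1:2] - 0.5) * bin + c(x0, y0)
    if (is.null(kept) ||
        all(sqrt(rowSums(sweep(kept[, 1:2, drop = FALSE], 2,
                               pos)^2)) >= min_separation))
      kept <- rbind(kept, c(pos, peaks[r, ]))
  }
  if (!is.null(expected)) {
    if (nrow(kept) < expected)
      warning("detect_stems: found ", nrow(kept), " of ", expected,
              " expected stems")
    if (nrow(kept) > expected)
      kept <- kept[seq_len(expected), , drop = FALSE]
  }
  # refine each peak: count-weighted centroid of the 3x3 neighbourhood
  out <- t(apply(kept, 1, function(k) {
    i <- k[3]; j <- k[4]
    ii <- max(1, i - 1):min(nx, i + 1)
    jj <- max(1, j - 1):min(ny, j + 1)
    w <- counts[ii, jj, drop = FALSE]
    cx <- sum(outer((ii - 0.5) * bin + x0, rep(1, length(jj))) * w) / sum(w)
    cy <- sum(outer(rep(1, length(ii)), (jj - 0.5) * bin + y0) * w) / sum(w)
    c(cx, cy)
  }))
  out <- out[order(out[, 2]), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Cut a cylindrical tree segment around a stem
#'
#' @param cloud a [point_cloud()].
#' @param stem stem position, `c(x, y)` ground-plane coordinates.
#' @param radius cylinder radius, metres (default keeps neighbouring
#'   trees at the standard 0.95 m pitch disjoint).
#' @return An object of class `tree_segment`: list with `cloud` (member
#'   [point_cloud()]), `indices` (into the input cloud), `stem`, `radius`.
#' @export
segment_tree <- function(cloud, stem, radius = 0.45) {
  d2 <- (cloud$points[, 1] - stem[1])^2 + (cloud$points[, 2] - stem[2])^2
  idx <- which(d2 <= radius^2)
  structure(list(cloud = cloud_subset(cloud, idx), indices = idx,
                 stem = c(x = stem[1], y = stem[2]), radius = radius),
            class = "tree_segment")
}

# vectorized eigenvalues of symmetric 3x3 matrices (trigonometric form),
# entries given as vectors; returns cbind(l1 >= l2 >= l3)
eigen_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detb / 2))
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

#' Per-point eigenvalue curvature features
#'
#' For each point, the k-nearest-neighbour set (including the point) is
#' mean-centred and its covariance eigen-decomposed into
#' `lambda1 >= lambda2 >= lambda3 >= 0`. The raw change-of-curvature
#' `c = lambda3 / (lambda1 + lambda2 + lambda3)` is high on locally
#' spherical surfaces (fruit) and low on planar or gently curved ones
#' (leaves, trunk bark at this scale). Per cloud, `c` is affinely
#' rescaled to the range 0..100 so that thresholds are comparable across
#' trees.
#'
#' @param cloud a [point_cloud()] (reflectance carried into the field).
#' @param k neighbourhood size (>= 4; cloud must have more than k points).
#' @return An object of class `feature_field`: list with `curvature`
#'   (scaled, 0..100), `raw_curvature`, `eigenvalues` (n x 3),
#'   `reflectance`, `k`, `degenerate` (duplicate-point neighbourhoods,
#'   curvature forced to 0).
#' @export
curvature_features <- function(cloud, k = 30) {
  n <- n_points(cloud)
  if (k < 4) stop("k must be at least 4")
  if (n <= k) stop("cloud must contain more than k points")
  P <- cloud$points
  nn <- knn_points(P, P, k)
  sx <- sy <- sz <- sxx <- syy <- szz <- sxy <- sxz <- syz <- numeric(n)
  for (t in seq_len(k)) {
    xi <- P[nn$idx[, t], 1]; yi <- P[nn$idx[, t], 2]
    zi <- P[nn$idx[, t], 3]
    sx <- sx + xi; sy <- sy + yi; sz <- sz + zi
    sxx <- sxx + xi * xi; syy <- syy + yi * yi; szz <- szz + zi * zi
    sxy <- sxy + xi * yi; sxz <- sxz + xi * zi; syz <- syz + yi * zi
  }
  mx <- sx / k; my <- sy / k; mz <- sz / k
  lam <- eigen_sym3(sxx / k - mx^2, syy / k - my^2, szz / k - mz^2,
                    sxy / k - mx * my, sxz / k - mx * mz,
                    syz / k - my * mz)
  lam <- pmax(lam, 0)
  tot <- rowSums(lam)
  degenerate <- tot <= 0
  raw <- ifelse(degenerate, 0, lam[, 3] / ifelse(tot > 0, tot, 1))
  rng <- range(raw)
  scaled <- if (diff(rng) > 0) 100 * (raw - rng[1]) / diff(rng)
    else rep(0, n)
  structure(list(curvature = scaled, raw_curvature = raw,
                 eigenvalues = lam, reflectance = cloud$reflectance,
                 k = k, degenerate = degenerate),
            class = "feature_field")
}

#' Estimate curvature and reflectance thresholds
#'
#' `kde_valley` places each threshold at the density minimum between the
#' two dominant modes of the feature's kernel density estimate, falling
#' back to a percentile when the distribution is unimodal. `percentile`
#' uses the direct quantile. Apples are the high-curvature,
#' high-reflectance class, so both thresholds are lower bounds.
#'
#' @param field a [curvature_features()] field (needs reflectance).
#' @param method `"kde_valley"` or `"percentile"`.
#' @param params list: `p` percentile (0..100) used by `"percentile"` and
#'   as the fallback; optionally `p_curvature` / `p_reflectance` to
#'   override per feature.
#' @return List with `C_th`, `R_th` and `method` (the rule actually used
#'   per feature).
#' @export
estimate_thresholds <- function(field,
                                method = c("kde_valley", "percentile"),
                                params = list(p = 90)) {
  method <- match.arg(method)
  if (is.null(field$reflectance))
    stop("feature field carries no reflectance")
  one <- function(x, name, p) {
    if (length(unique(x)) < 2)
      stop("constant feature: ", name)
    if (method == "percentile")
      return(list(th = unname(quantile(x, p / 100)), used = "percentile"))
    d <- density(x)
    y <- d$y
    loc_max <- which(y > c(-Inf, head(y, -1)) & y >= c(tail(y, -1), Inf))
    loc_max <- loc_max[y[loc_max] >= 0.05 * max(y)]
    # merge modes separated only by a shallow saddle (overlapping
    # sub-populations, e.g. leaf vs trunk reflectance, are one class)
    while (length(loc_max) >= 2) {
      saddle <- vapply(seq_len(length(loc_max) - 1), function(i)
        min(y[loc_max[i]:loc_max[i + 1]]), 0)
      depth <- saddle / pmin(y[head(loc_max, -1)], y[tail(loc_max, -1)])
      i <- which.max(depth)
      if (depth[i] < 0.5) break
      drop <- if (y[loc_max[i]] < y[loc_max[i + 1]]) i else i + 1
      loc_max <- loc_max[-drop]
    }
    if (length(loc_max) >= 2) {
      top2 <- sort(loc_max[order(-y[loc_max])][1:2])
      between <- top2[1]:top2[2]
      valley <- between[which.min(y[between])]
      list(th = d$x[valley], used = "kde_valley")
    } else {
      list(th = unname(quantile(x, p / 100)), used = "percentile_fallback")
    }
  }
  pc <- params$p_curvature %||% params$p
  pr <- params$p_reflectance %||% params$p
  cth <- one(field$curvature, "curvature", pc)
  rth <- one(field$reflectance, "reflectance", pr)
  list(C_th = cth$th, R_th = rth$th,
       method = c(curvature = cth$used, reflectance = rth$used))
}

#' Segment fruit candidates into per-fruit clusters
#'
#' Points satisfying `C_th <= C` and `R_th <= R` are grouped by
#' single-linkage Euclidean clustering at `cluster_eps`; clusters below
#' `min_points` are discarded. Each cluster is summarised by its
#' centroid, a least-squares sphere radius, and FST statistics computed
#' over non-sentinel temperatures.
#'
#' @param tree a `tree_segment` (or any [point_cloud()]).
#' @param field the matching [curvature_features()] field.
#' @param thresholds list with `C_th`, `R_th` (see
#'   [estimate_thresholds()]).
#' @param cluster_eps single-linkage distance, metres.
#' @param min_points minimum cluster size.
#' @param sentinel out-of-view temperature marker, degC.
#' @return List of `fruit_segment` objects: `indices` (into the tree
#'   cloud), `centroid`, `radius`, `fst` (mean/min/max/sd/n), `height`,
#'   `side` (NA until [categorize_side()]).
#' @export
segment_fruits <- function(tree, field, thresholds, cluster_eps = 0.020,
                           min_points = 30, sentinel = -10) {
  cloud <- if (inherits(tree, "tree_segment")) tree$cloud else tree
  if (is.null(field$reflectance))
    stop("feature field carries no reflectance")
  cand <- which(field$curvature >= thresholds$C_th &
                  field$reflectance >= thresholds$R_th)
  if (length(cand) == 0) return(list())
  lab <- cluster_eps_cpp(cloud$points[cand, , drop = FALSE], cluster_eps)
  out <- list()
  for (l in seq_len(max(lab))) {
    idx <- cand[lab == l]
    if (length(idx) < min_points) next
    pts <- cloud$points[idx, , drop = FALSE]
    centroid <- colMeans(pts)
    radius <- fit_sphere_radius(pts)
    temps <- cloud$temperature[idx]
    temps <- temps[!is.na(temps) & temps != sentinel]
    fst <- if (length(temps))
      list(mean = mean(temps), min = min(temps), max = max(temps),
           sd = if (length(temps) > 1) sd(temps) else 0,
           n = length(temps))
    else list(mean = NA_real_, min = NA_real_, max = NA_real_,
              sd = NA_real_, n = 0L)
    out[[length(out) + 1]] <- structure(
      list(indices = idx, centroid = centroid, radius = radius,
           fst = fst, height = centroid[3], side = NA_character_),
      class = "fruit_segment")
  }
  out
}

# algebraic least-squares sphere fit; returns the radius
fit_sphere_radius <- function(pts) {
  if (nrow(pts) < 4) return(NA_real_)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NA_real_)
  sqrt(max(sol[4] + sum(sol[1:3]^2), 0))
}

#' @export
print.fruit_segment <- function(x, ...) {
  cat(sprintf(
    "Fruit segment: %d points, centroid (%.3f, %.3f, %.3f) m, r %.3f m\n",
    length(x$indices), x$centroid[1], x$centroid[2], x$centroid[3],
    x$radius))
  if (!is.na(x$fst$mean))
    cat(sprintf("  FST mean %.2f degC (min %.2f, max %.2f, SD %.2f, n %d)%s\n",
                x$fst$mean, x$fst$min, x$fst$max, x$fst$sd, x$fst$n,
                if (!is.na(x$side)) paste0(", side ", x$side) else ""))
  invisible(x)
}

#' Label fruits east or west of the row plane
#'
#' The sign of each fruit centroid's offset along the configured east
#' normal sets its side; a centroid exactly on the plane is
#' deterministically labelled east (and reported).
#'
#' @param fruits list of `fruit_segment` objects.
#' @param east_normal unit vector pointing east of the row.
#' @param origin a point on the row plane.
#' @return The fruits with `side` set to `"east"` or `"west"`.
#' @export
categorize_side <- function(fruits, east_normal = c(1, 0, 0),
                            origin = c(0, 0, 0)) {
  lapply(fruits, function(f) {
    off <- sum((f$centroid - origin) * east_normal)
    if (off == 0)
      message("categorize_side: centroid exactly on the row plane, ",
              "tie-broken to east")
    f$side <- if (off >= 0) "east" else "west"
    f
  })
}

#' Summarise fruit segments as a data.frame
#'
#' @param fruits list of `fruit_segment` objects.
#' @return data.frame with centroid, radius, FST statistics, side, height.
#' @export
fruit_table <- function(fruits) {
  if (length(fruits) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0), n_points = integer(0),
                      fst_mean = numeric(0), fst_min = numeric(0),
                      fst_max = numeric(0), fst_sd = numeric(0),
                      side = character(0), height = numeric(0)))
  do.call(rbind, lapply(fruits, function(f) data.frame(
    x = f$centroid[1], y = f$centroid[2], z = f$centroid[3],
    radius = f$radius, n_points = length(f$indices),
    fst_mean = f$fst$mean, fst_min = f$fst$min, fst_max = f$fst$max,
    fst_sd = f$fst$sd, side = f$side, height = f$height,
    row.names = NULL)))
}

#' Full fruit-surface-temperature pipeline on a thermal row cloud
#'
#' Detects stems, cuts cylindrical tree segments, computes curvature and
#' reflectance features per tree, estimates thresholds, clusters fruit
#' candidates and labels tree sides.
#'
#' @param cloud merged thermal [point_cloud()] of the row (z up, row
#'   along y, temperatures fused).
#' @param n_trees expected tree count.
#' @param k curvature neighbourhood size.
#' @param cluster_eps,min_points fruit clustering parameters.
#' @param cylinder_radius tree segment radius, metres.
#' @param stem_bin stem histogram bin, metres.
#' @param trunk_band trunk height band, metres.
#' @param threshold_method,threshold_params see [estimate_thresholds()].
#' @param east_normal east direction of the row plane.
#' @param sentinel out-of-view marker, degC.
#' @return List with `stems`, `fruits` (flat list across trees, each with
#'   a `tree` element), `per_tree` (thresholds used).
#' @export
orchard_fst <- function(cloud, n_trees, k = 30, cluster_eps = 0.020,
                        min_points = 30, cylinder_radius = 0.45,
                        stem_bin = 0.05, trunk_band = c(0.2, 0.8),
                        threshold_method = "kde_valley",
                        threshold_params = list(p_curvature = 25,
                                                p_reflectance = 90),
                        east_normal = c(1, 0, 0), sentinel = -10) {
  stems <- detect_stems(cloud, bin = stem_bin, expected = n_trees,
                        trunk_band = trunk_band)
  fruits <- list()
  per_tree <- list()
  for (s in seq_len(nrow(stems))) {
    tree <- segment_tree(cloud, stems[s, ], radius = cylinder_radius)
    if (n_points(tree$cloud) <= k) next
    field <- curvature_features(tree$cloud, k = k)
    th <- estimate_thresholds(field, method = threshold_method,
                              params = threshold_params)
    fr <- segment_fruits(tree, field, th, cluster_eps = cluster_eps,
                         min_points = min_points, sentinel = sentinel)
    fr <- categorize_side(fr, east_normal = east_normal,
                          origin = c(stems[s, 1], stems[s, 2], 0))
    fr <- lapply(fr, function(f) { f$tree <- s; f })
    fruits <- c(fruits, fr)
    per_tree[[s]] <- th
  }
  list(stems = stems, fruits = fruits, per_tree = per_tree)
}
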