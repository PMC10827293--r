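# Hudson FST between sliding-grid cells, the FST-distance
# (isolation-by-distance) curve with lowess smoothing, and an overlap-aware
# spatial bootstrap for its confidence bands.

#' Hudson's FST estimator with unequal sample-size correction
#'
#' Per site, with sample frequencies p1, p2 from n1, n2 called alleles:
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`; the multi-site estimate is the ratio of sums
#' `sum(N) / sum(D)` (not a mean of ratios).  Sites require at least two
#' called alleles in both groups.  Negative estimates are possible (the
#' estimator is unbiased) and are reported as-is.
#'
#' @param derA,calledA,derB,calledB per-site derived and called allele
#'   counts for the two groups.
#' @return list with `fst`, `n_sites`, and the sums `N` and `D`;
#'   `fst` is NA (with a warning) when the denominator sum is zero.
#' @export
hudson_fst <- function(derA, calledA, derB, calledB) {
  use <- calledA >= 2 & calledB >= 2
  if (!any(use)) return(list(fst = NA_real_, n_sites = 0L, N = 0, D = 0))
  p1 <- derA[use] / calledA[use]
  p2 <- derB[use] / calledB[use]
  n1 <- calledA[use]; n2 <- calledB[use]
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  sN <- sum(N); sD <- sum(D)
  if (sD == 0) {
    warning("Hudson FST undefined: zero denominator")
    return(list(fst = NA_real_, n_sites = sum(use), N = sN, D = sD))
  }
  list(fst = sN / sD, n_sites = sum(use), N = sN, D = sD)
}

#' Sliding-grid specification
#'
#' Cells are `cell_deg` x `cell_deg` degrees, anchored at `anchor`
#' (lon, lat), and the grid is slid `n_offsets` times by `step_deg` degrees
#' north and east (offsets 0, 1, ..., n_offsets-1).
#'
#' @param cell_deg cell width (degrees; default 10).
#' @param step_deg slide step (default 1).
#' @param n_offsets number of offset grids (default 10).
#' @param anchor c(lon0, lat0); default c(-180, -90).
#' @param min_cell_n minimum samples for a cell to count as populated.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(cell_deg = 10, step_deg = 1, n_offsets = 10,
                      anchor = c(-180, -90), min_cell_n = 2) {
  if (n_offsets * step_deg > cell_deg)
    stop("n_offsets * step_deg must not exceed cell_deg")
  structure(list(cell_deg = cell_deg, step_deg = step_deg,
                 n_offsets = n_offsets, anchor = anchor,
                 min_cell_n = min_cell_n), class = "grid_spec")
}

#' Assign samples to grid cells for one offset
#'
#' Cell index (i, j) = floor((lon - lon0 - g) / cell),
#' floor((lat - lat0 - g) / cell) where g = offset * step_deg.  Cells with
#' fewer than `min_cell_n` samples are dropped.
#'
#' @param lon,lat coordinates.
#' @param spec a [grid_spec()].
#' @param offset offset index (0-based).
#' @return data.frame sample index, cell ix, iy, cell id string; populated
#'   cells only.
#' @export
assign_cells <- function(lon, lat, spec, offset = 0) {
  g <- offset * spec$step_deg
  ix <- floor((lon - spec$anchor[1] - g) / spec$cell_deg)
  iy <- floor((lat - spec$anchor[2] - g) / spec$cell_deg)
  cells <- data.frame(sample = seq_along(lon), ix = ix, iy = iy,
                      cell = paste0("g", offset, ":", ix, ",", iy))
  counts <- table(cells$cell)
  keep <- names(counts)[counts >= spec$min_cell_n]
  cells[cells$cell %in% keep, , drop = FALSE]
}

#' Geographic distance
#'
#' Haversine great-circle distance in km (Earth radius 6371.0088 km), or
#' plain euclidean distance for simulated (unit-square) habitats.
#'
#' @param lon1,lat1,lon2,lat2 coordinates (degrees, or habitat units in
#'   euclidean mode).  Vectorized.
#' @param mode `"haversine"` or `"euclidean"`.
#' @return distances (km, or habitat units).
#' @export
geographic_distance <- function(lon1, lat1, lon2, lat2,
                                mode = c("haversine", "euclidean")) {
  mode <- match.arg(mode)
  if (mode == "euclidean") return(sqrt((lon1 - lon2)^2 + (lat1 - lat2)^2))
  R <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# mean pairwise distance between two sets of coordinates
.mean_cross_distance <- function(lonA, latA, lonB, latB, mode) {
  nA <- length(lonA); nB <- length(lonB)
  mean(geographic_distance(rep(lonA, times = nB), rep(latA, times = nB),
                           rep(lonB, each = nA), rep(latB, each = nA),
                           mode = mode))
}

#' FST-distance table over the sliding grids
#'
#' For each offset grid independently, computes Hudson FST and mean pairwise
#' individual geographic distance between all unordered pairs of populated
#' cells; points are pooled over all grids.  Samples within `cell_deg` of the
#' antimeridian are rejected with a warning (no wrap handling).
#'
#' @param gm a [geno_matrix].
#' @param meta metadata with columns id, lat, lon (subset to `gm` samples).
#' @param spec a [grid_spec()].
#' @param mode distance mode, see [geographic_distance()].
#' @return data.frame of class `fst_points`: offset, cellA, cellB, nA, nB,
#'   fst, mean_km, plus cell-extent columns used by the spatial bootstrap.
#' @export
grid_fst_distance_table <- function(gm, meta, spec = grid_spec(),
                                    mode = "haversine") {
  idx <- match(gm$samples, meta$id)
  if (anyNA(idx)) stop("metadata missing sample(s): ",
                       paste(gm$samples[is.na(idx)][1], collapse = ", "))
  meta <- meta[idx, ]
  if (mode == "haversine" &&
      any(meta$lon > 180 - spec$cell_deg | meta$lon < -180 + 0)) {
    if (any(meta$lon > 180 - spec$cell_deg))
      warning("samples near the antimeridian rejected (no wrap handling)")
    keep <- meta$lon <= 180 - spec$cell_deg
    gm <- subset_geno(gm, samples = which(keep))
    meta <- meta[keep, ]
  }
  rows <- list(); k <- 0; any_pair <- FALSE
  for (off in seq_len(spec$n_offsets) - 1) {
    asg <- assign_cells(meta$lon, meta$lat, spec, off)
    cells <- unique(asg$cell)
    if (length(cells) < 2) next
    groups <- setNames(asg$cell, meta$id[asg$sample])
    cnt <- group_allele_counts(subset_geno(gm, samples = asg$sample),
                               groups)
    g <- off * spec$step_deg
    for (i in seq_along(cells)) for (j in seq_len(i - 1)) {
      a <- cells[i]; b <- cells[j]
      sa <- asg$sample[asg$cell == a]; sb <- asg$sample[asg$cell == b]
      hf <- hudson_fst(cnt$derived[, a], cnt$called[, a],
                       cnt$derived[, b], cnt$called[, b])
      if (is.na(hf$fst)) next
      any_pair <- TRUE
      dist <- .mean_cross_distance(meta$lon[sa], meta$lat[sa],
                                   meta$lon[sb], meta$lat[sb], mode)
      ia <- asg[asg$cell == a, ][1, ]; ib <- asg[asg$cell == b, ][1, ]
      k <- k + 1
      rows[[k]] <- data.frame(
        offset = off, cellA = a, cellB = b,
        nA = length(sa), nB = length(sb), fst = hf$fst, mean_km = dist,
        # cell extents in degrees, for the overlap graph
        A_lon0 = spec$anchor[1] + g + ia$ix * spec$cell_deg,
        A_lat0 = spec$anchor[2] + g + ia$iy * spec$cell_deg,
        B_lon0 = spec$anchor[1] + g + ib$ix * spec$cell_deg,
        B_lat0 = spec$anchor[2] + g + ib$iy * spec$cell_deg,
        stringsAsFactors = FALSE)
    }
  }
  if (!any_pair)
    stop("fewer than 2 populated cells in every offset grid")
  out <- do.call(rbind, rows)
  attr(out, "cell_deg") <- spec$cell_deg
  class(out) <- c("fst_points", "data.frame")
  out
}

#' Lowess fit of FST against distance
#'
#' Locally weighted regression (lowess, 3 robustifying iterations) of `fst`
#' on `mean_km`, evaluated by interpolation on `n_eval` equally spaced
#' distances spanning the observed range.
#'
#' @param points an `fst_points` data.frame (or any data.frame with columns
#'   `mean_km`, `fst`).
#' @param frac lowess span (default 0.67).
#' @param n_eval evaluation-grid size (default 100).
#' @param eval_at optional explicit evaluation distances.
#' @return data.frame distance, fit.
#' @export
lowess_fit <- function(points, frac = 0.67, n_eval = 100, eval_at = NULL) {
  if (nrow(points) < 10) stop("need >= 10 points for lowess")
  lw <- lowess(points$mean_km, points$fst, f = frac, iter = 3)
  if (is.null(eval_at))
    eval_at <- seq(min(points$mean_km), max(points$mean_km),
                   length.out = n_eval)
  fit <- approx(lw$x, lw$y, xout = eval_at, rule = 2, ties = mean)$y
  data.frame(distance = eval_at, fit = fit)
}

# union-find connected components of the cell-overlap graph; two cells
# overlap iff their lon AND lat intervals intersect with positive length.
.overlap_components <- function(lon0, lat0, cell_deg) {
  n <- length(lon0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (abs(lon0[i] - lon0[j]) < cell_deg &&
        abs(lat0[i] - lat0[j]) < cell_deg) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Spatial bootstrap confidence bands for the FST-distance curve
#'
#' Populated cells (pooled over all offset grids) are grouped into connected
#' components of the overlap graph, so overlapping cells — which share
#' individuals — are resampled jointly: individuals are either fully in a
#' bootstrap replicate or not at all.  Components are resampled with
#' replacement; a point enters a replicate once per joint inclusion of its
#' two components, the lowess curve is refit, and the 2.5/97.5 percentiles
#' per evaluation distance form the bands.
#'
#' @param points output of [grid_fst_distance_table()].
#' @param B number of bootstrap replicates (default 200).
#' @param frac,n_eval lowess parameters, see [lowess_fit()].
#' @return list of class `ibd_curve`: data.frame `curve` (distance, fit, lo,
#'   hi), `n_points`, `n_bootstrap`, `n_components`, and the B x n_eval
#'   matrix of replicate curves.
#' @export
spatial_bootstrap_ci <- function(points, B = 200, frac = 0.67,
                                 n_eval = 100) {
  cell_deg <- attr(points, "cell_deg")
  if (is.null(cell_deg)) cell_deg <- 10
  cells <- unique(data.frame(
    lon0 = c(points$A_lon0, points$B_lon0),
    lat0 = c(points$A_lat0, points$B_lat0)))
  comp <- .overlap_components(cells$lon0, cells$lat0, cell_deg)
  key <- paste(cells$lon0, cells$lat0)
  compA <- comp[match(paste(points$A_lon0, points$A_lat0), key)]
  compB <- comp[match(paste(points$B_lon0, points$B_lat0), key)]
  ncomp <- max(comp)
  if (ncomp == 1)
    warning("all cells form one overlap component; bootstrap is degenerate")
  fit0 <- lowess_fit(points, frac = frac, n_eval = n_eval)
  curves <- matrix(NA_real_, B, n_eval)
  for (b in seq_len(B)) {
    draw <- tabulate(sample.int(ncomp, ncomp, replace = TRUE), ncomp)
    mult <- ifelse(compA == compB, draw[compA], draw[compA] * draw[compB])
    idx <- rep(seq_len(nrow(points)), times = mult)
    if (length(idx) < 10) next  # degenerate replicate, left as NA
    curves[b, ] <- lowess_fit(points[idx, , drop = FALSE], frac = frac,
                              eval_at = fit0$distance)$fit
  }
  lo <- apply(curves, 2, quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(curves, 2, quantile, probs = 0.975, na.rm = TRUE)
  structure(list(curve = data.frame(distance = fit0$distance,
                                    fit = fit0$fit, lo = lo, hi = hi),
                 n_points = nrow(points), n_bootstrap = B,
                 n_components = ncomp, replicates = curves),
            class = "ibd_curve")
}

#' @export
print.ibd_curve <- function(x, ...) {
  cat("isolation-by-distance curve: ", x$n_points, " FST points, ",
      x$n_bootstrap, " bootstrap replicates over ", x$n_components,
      " spatial components\n", sep = "")
  invisible(x)
}

# Fast pairwise Hudson FST between all pairs of groups with complete data
# (no missingness, uniform called-allele counts per group) -- the simulation
# grid path.  freq: sites x cells frequency matrix; n_alleles: called
# alleles per cell (vector).  Returns matrices fst/N/D, cells x cells.
.hudson_fst_matrix <- function(freq, n_alleles) {
  G <- crossprod(freq)                      # sum p_a p_b
  s <- colSums(freq)
  ssq <- diag(G)
  sq_diff <- outer(ssq, ssq, "+") - 2 * G   # sum (p_a - p_b)^2
  corr <- colSums(freq * (1 - freq)) / (n_alleles - 1)
  N <- sq_diff - outer(corr, corr, "+")
  D <- outer(s, s, "+") - 2 * G
  fst <- N / D
  diag(fst) <- 0
  list(fst = fst, N = N, D = D)
}
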