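#' Resample a morphology into length-weighted sample points
#'
#' Every parent-child edge is subdivided into segments no longer than `step`
#' voxels; each sample point (segment midpoint) carries its share of arc
#' length, so the total weight equals the total cable length. This makes the
#' downstream deviation metric insensitive to node density. A morphology with
#' no positive-length edges falls back to its node positions with unit
#' weights.
#'
#' @param m Non-empty `swc_morphology`.
#' @param step Maximum sample spacing in voxels (default 1).
#' @return List with `points` (n x 3 matrix, columns x, y, z) and `weights`.
#' @export
resample_morphology <- function(m, step = 1) {
  assert_swc(m)
  nd <- m$nodes
  if (nrow(nd) == 0L) stop("morphology is empty", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  pidx <- match(nd$parent, nd$id)
  pts <- list(); wts <- list(); j <- 0L
  for (i in seq_len(nrow(nd))) {
    p <- pidx[i]
    if (is.na(p)) next
    a <- c(nd$x[p], nd$y[p], nd$z[p])
    b <- c(nd$x[i], nd$y[i], nd$z[i])
    L <- sqrt(sum((b - a)^2))
    if (L == 0) next
    ns <- ceiling(L / step)
    t <- (seq_len(ns) - 0.5) / ns
    j <- j + 1L
    pts[[j]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
    wts[[j]] <- rep(L / ns, ns)
  }
  if (j == 0L) {
    return(list(points = cbind(nd$x, nd$y, nd$z),
                weights = rep(1, nrow(nd))))
  }
  list(points = do.call(rbind, pts), weights = unlist(wts))
}

# Uniform-grid spatial index for exact nearest-neighbor distances. Cells of
# side `cell`; queries expand over Chebyshev rings and stop once the best
# distance cannot be beaten by any unvisited ring (every point in ring k+1 is
# strictly farther than k * cell from the query).
build_grid_index <- function(points, cell) {
  keys <- paste(floor(points[, 1] / cell),
                floor(points[, 2] / cell),
                floor(points[, 3] / cell), sep = ",")
  buckets <- split(seq_len(nrow(points)), keys)
  list(points = points, cell = cell, buckets = buckets,
       cmin = floor(apply(points, 2, min) / cell),
       cmax = floor(apply(points, 2, max) / cell))
}

# exact min distance from q to the indexed points; may stop early (returning a
# value that is <= stop_at but not necessarily minimal) once the distance is
# known to be <= stop_at
grid_nn_dist <- function(index, q, stop_at = -Inf) {
  cell <- index$cell
  qc <- floor(q / cell)
  kmax <- max(abs(qc - index$cmin), abs(qc - index$cmax))
  best <- Inf
  k <- 0L
  repeat {
    offs <- ring_offsets(k)
    for (r in seq_len(nrow(offs))) {
      key <- paste(qc[1] + offs[r, 1], qc[2] + offs[r, 2], qc[3] + offs[r, 3],
                   sep = ",")
      ids <- index$buckets[[key]]
      if (is.null(ids)) next
      p <- index$points[ids, , drop = FALSE]
      d2 <- (p[, 1] - q[1])^2 + (p[, 2] - q[2])^2 + (p[, 3] - q[3])^2
      best <- min(best, sqrt(min(d2)))
    }
    if (best <= stop_at) break
    if (best <= k * cell) break
    if (k > kmax) break
    k <- k + 1L
  }
  best
}

ring_offsets <- function(k) {
  if (k == 0L) return(matrix(0L, 1, 3))
  g <- as.matrix(expand.grid(-k:k, -k:k, -k:k))
  g[pmax(abs(g[, 1]), abs(g[, 2]), abs(g[, 3])) == k, , drop = FALSE]
}

#' Percent of different structures (PDS)
#'
#' Both morphologies are resampled at `step`-voxel spacing; a sample point of
#' `m` deviates when its minimum Euclidean distance (voxel units) to any sample
#' point of `ref` exceeds `thr`. PDS is the length fraction of `m` carried by
#' deviating samples, in `[0, 1]`. Distances ignore Z-anisotropy: the distance
#' limit is specified in voxels.
#'
#' @param m Morphology under evaluation.
#' @param ref Reference morphology.
#' @param thr Distance limit in voxels (default 15, roughly 3 um at typical
#'   lateral resolutions).
#' @param step Resampling step in voxels (default 1); discretization error is
#'   bounded by `step / 2`.
#' @return PDS in `[0, 1]`.
#' @export
pds <- function(m, ref, thr = 15, step = 1) {
  assert_swc(m, "m"); assert_swc(ref, "ref")
  if (nrow(m$nodes) == 0L || nrow(ref$nodes) == 0L) {
    stop("pds requires non-empty morphologies", call. = FALSE)
  }
  sm <- resample_morphology(m, step)
  sr <- resample_morphology(ref, step)
  idx <- build_grid_index(sr$points, cell = max(thr, step))
  deviating <- vapply(seq_len(nrow(sm$points)), function(i) {
    grid_nn_dist(idx, sm$points[i, ], stop_at = thr) > thr
  }, logical(1))
  sum(sm$weights[deviating]) / sum(sm$weights)
}

#' Score a reconstruction against a gold standard
#'
#' `precision = 1 - PDS(recon, gold)`, `recall = 1 - PDS(gold, recon)`, and F1
#' their harmonic mean (0 when precision + recall = 0). An empty
#' reconstruction scores (0, 0, 0) with a warning rather than an error.
#'
#' @param recon Reconstructed `swc_morphology`.
#' @param gold Non-empty gold-standard `swc_morphology`.
#' @param thr Distance limit in voxels (default 15).
#' @param step Resampling step in voxels (default 1).
#' @return A `tracing_score`: `precision`, `recall`, `f1`, `pds_forward`,
#'   `pds_reverse`, `threshold_voxels`.
#' @export
trace_score <- function(recon, gold, thr = 15, step = 1) {
  assert_swc(gold, "gold")
  if (nrow(gold$nodes) == 0L) stop("gold standard is empty", call. = FALSE)
  if (!is_swc(recon) || nrow(recon$nodes) == 0L) {
    warning("empty reconstruction: precision = recall = f1 = 0")
    return(structure(list(precision = 0, recall = 0, f1 = 0,
                          pds_forward = 1, pds_reverse = 1,
                          threshold_voxels = thr),
                     class = "tracing_score"))
  }
  pf <- pds(recon, gold, thr, step)
  pr <- pds(gold, recon, thr, step)
  precision <- 1 - pf
  recall <- 1 - pr
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 pds_forward = pf, pds_reverse = pr, threshold_voxels = thr),
            class = "tracing_score")
}

#' @export
print.tracing_score <- function(x, ...) {
  cat(sprintf("<tracing_score> precision %.4f  recall %.4f  F1 %.4f (thr %g voxels)\n",
              x$precision, x$recall, x$f1, x$threshold_voxels))
  invisible(x)
}

#' Fraction of gold cable covered by bright voxels
#'
#' Resamples the morphology and reports the length fraction of sample points
#' whose containing voxel is at or above `threshold` in the image. A cheap
#' tracer-free recall proxy: cable that falls below a tracer's minimal
#' detectable intensity is cable the tracer will miss.
#'
#' @param vol A `volume3d`.
#' @param m Morphology in the volume's voxel coordinates.
#' @param threshold Intensity threshold (default 10 on the 8-bit scale, a
#'   typical minimal detectable level).
#' @param step Resampling step (default 1).
#' @return Covered length fraction in `[0, 1]`.
#' @export
cable_coverage <- function(vol, m, threshold = 10, step = 1) {
  assert_volume3d(vol)
  s <- resample_morphology(m, step)
  dm <- dim(vol$data)
  iz <- pmin(pmax(round(s$points[, 3]) + 1, 1), dm[1])
  iy <- pmin(pmax(round(s$points[, 2]) + 1, 1), dm[2])
  ix <- pmin(pmax(round(s$points[, 1]) + 1, 1), dm[3])
  v <- vol$data[cbind(iz, iy, ix)]
  sum(s$weights[v >= threshold]) / sum(s$weights)
}
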