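#' Rasterize a morphology into foreground/background masks
#'
#' The foreground is the union of spheres at every node and conical frusta
#' (linearly interpolated radius) along every parent-child edge, i.e. the
#' radius-profiled neuronal mask. The "enlarged" mask is the same construction
#' with all radii multiplied by `enlargement` (geometric scaling about the
#' centerline, not a fixed-ball dilation); the background is the enlarged mask
#' minus the foreground — a shell hugging the neuron, so background statistics
#' measure the noise the tracer actually competes with.
#'
#' @param morph Non-empty `swc_morphology` in voxel coordinates.
#' @param shape `(Nz, Ny, Nx)` of the target volume.
#' @param enlargement Radius multiplier for the enlarged mask (default 2).
#' @return A `region_masks` object: logical arrays `foreground`, `background`,
#'   plus `enlargement_factor`.
#' @export
rasterize_masks <- function(morph, shape, enlargement = 2) {
  assert_swc(morph)
  if (nrow(morph$nodes) == 0L) stop("morphology is empty", call. = FALSE)
  if (enlargement < 1) stop("enlargement must be >= 1", call. = FALSE)
  fg <- raster_morphology(morph, shape, radius_scale = 1)
  if (!any(fg)) stop("morphology lies entirely outside the volume", call. = FALSE)
  if (enlargement == 1) {
    bg <- array(FALSE, dim = shape)
  } else {
    enlarged <- raster_morphology(morph, shape, radius_scale = enlargement)
    bg <- enlarged & !fg
  }
  structure(list(foreground = fg, background = bg,
                 enlargement_factor = enlargement),
            class = "region_masks")
}

# Paint the radius-profiled tube mask. Node coordinates are 0-based voxel
# centers: SWC (x, y, z) maps to array index (z + 1, y + 1, x + 1). Radii of 0
# are promoted to 0.5 voxel so thin terminal segments still mark their voxel.
# Capsules clamp the projection parameter, so each edge also covers the
# spheres at both of its endpoints; explicit spheres are only needed for
# isolated nodes.
raster_morphology <- function(morph, shape, radius_scale = 1) {
  nd <- morph$nodes
  r <- pmax(nd$radius, 0.5) * radius_scale
  pidx <- match(nd$parent, nd$id)
  mask <- array(FALSE, dim = shape)
  idx <- vector("list", nrow(nd))
  in_edge <- !is.na(pidx)
  in_edge[pidx[!is.na(pidx)]] <- TRUE
  for (i in seq_len(nrow(nd))) {
    p <- pidx[i]
    if (!is.na(p)) {
      idx[[i]] <- capsule_indices(shape,
                                  a = c(nd$z[p], nd$y[p], nd$x[p]),
                                  b = c(nd$z[i], nd$y[i], nd$x[i]),
                                  ra = r[p], rb = r[i])
    } else if (!in_edge[i]) {
      idx[[i]] <- capsule_indices(shape, a = c(nd$z[i], nd$y[i], nd$x[i]),
                                  b = NULL, ra = r[i], rb = r[i])
    }
  }
  mask[unlist(idx)] <- TRUE
  mask
}

# linear indices of voxels inside a sphere (b = NULL) or rounded frustum,
# vectorized over the element's bounding box; (z, y, x) voxel-center coords
capsule_indices <- function(shape, a, b, ra, rb) {
  rmax <- max(ra, rb)
  lohi <- if (is.null(b)) rbind(a, a) else rbind(pmin(a, b), pmax(a, b))
  lo <- pmax(floor(lohi[1, ] - rmax), 0) + 1        # to 1-based index
  hi <- pmin(ceiling(lohi[2, ] + rmax), shape - 1) + 1
  if (any(lo > hi)) return(integer(0))
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  bz <- length(zs); by <- length(ys); bx <- length(xs)
  Z <- rep(zs - 1, times = by * bx)
  Y <- rep(rep(ys - 1, each = bz), times = bx)
  X <- rep(xs - 1, each = bz * by)
  if (is.null(b) || sum((b - a)^2) == 0) {
    inside <- (Z - a[1])^2 + (Y - a[2])^2 + (X - a[3])^2 <= rmax^2
  } else {
    v <- b - a
    L2 <- sum(v^2)
    t <- ((Z - a[1]) * v[1] + (Y - a[2]) * v[2] + (X - a[3]) * v[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    rt <- ra + t * (rb - ra)
    inside <- (Z - (a[1] + t * v[1]))^2 + (Y - (a[2] + t * v[2]))^2 +
      (X - (a[3] + t * v[3]))^2 <= rt^2
  }
  li <- (Z + 1) + shape[1] * (Y + (X) * shape[2])  # column-major (z, y, x)
  li[inside]
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Signal-background contrast
#'
#' `median(fg) / (median(bg) + 1)`; the +1 guards against division by zero on
#' fully cleared backgrounds.
#'
#' @param fg_values,bg_values Numeric vectors of foreground and background
#'   voxel intensities.
#' @return SBC value (>= 0 for nonnegative images).
#' @export
sbc <- function(fg_values, bg_values) {
  if (length(fg_values) == 0L) stop("empty foreground region", call. = FALSE)
  if (length(bg_values) == 0L) stop("empty background region", call. = FALSE)
  stats::median(fg_values) / (stats::median(bg_values) + 1)
}

#' Background within-image homogeneity (uniformity)
#'
#' The whole image is z-normalized (population sd), the background voxels'
#' z-scores are histogrammed into `bins` equal-width bins spanning their
#' observed range, and the uniformity is `sum(p_i^2)` over bin fractions. 1
#' means all background mass in one bin (perfectly flat background); small
#' values mean the background intensities are spread out.
#'
#' @param bg_values Background voxel intensities.
#' @param whole_image All voxel intensities of the image (for the
#'   z-normalization).
#' @param bins Number of histogram bins (default 256, matching 8-bit
#'   granularity).
#' @return Uniformity in `(0, 1]`.
#' @export
background_uniformity <- function(bg_values, whole_image, bins = 256) {
  if (length(bg_values) == 0L) stop("empty background region", call. = FALSE)
  s <- pop_sd(whole_image)
  if (s == 0) stop("zero variance: image is constant", call. = FALSE)
  z <- (bg_values - mean(whole_image)) / s
  lo <- min(z); hi <- max(z)
  if (hi == lo) return(1)
  idx <- pmin(bins, floor((z - lo) / (hi - lo) * bins) + 1L)
  p <- tabulate(idx, nbins = bins) / length(z)
  sum(p^2)
}

#' Foreground relative standard deviation
#'
#' `sd(fg) / (median(fg) + 1)` with population sd. An increase after
#' enhancement indicates signal loss/inhomogenization of the neuron itself.
#'
#' @param fg_values Foreground voxel intensities.
#' @return RSD (>= 0).
#' @export
foreground_rsd <- function(fg_values) {
  if (length(fg_values) == 0L) stop("empty foreground region", call. = FALSE)
  pop_sd(fg_values) / (stats::median(fg_values) + 1)
}

#' Image-quality report for an (image, morphology) pair
#'
#' Rasterizes the gold-standard morphology into foreground/background masks
#' and reports SBC, background uniformity and foreground RSD.
#'
#' @param vol A `volume3d`.
#' @param morph Gold-standard `swc_morphology` in voxel coordinates.
#' @param enlargement Radius multiplier for the background shell (default 2).
#' @param bins Histogram bins for the uniformity (default 256).
#' @param masks Optional precomputed `region_masks` (reused across reports on
#'   volumes sharing one morphology).
#' @return A `quality_report`: `sbc`, `bg_uniformity`, `fg_rsd`,
#'   `n_fg_voxels`, `n_bg_voxels`, plus the parameters used.
#' @export
quality_report <- function(vol, morph, enlargement = 2, bins = 256, masks = NULL) {
  assert_volume3d(vol)
  if (is.null(masks)) masks <- rasterize_masks(morph, dim(vol$data), enlargement)
  fg <- vol$data[masks$foreground]
  bg <- vol$data[masks$background]
  structure(list(
    sbc = sbc(fg, bg),
    bg_uniformity = background_uniformity(bg, vol$data, bins),
    fg_rsd = foreground_rsd(fg),
    n_fg_voxels = length(fg),
    n_bg_voxels = length(bg),
    enlargement = masks$enlargement_factor,
    bins = bins
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  SBC:                   %.4g\n", x$sbc))
  cat(sprintf("  background uniformity: %.4g\n", x$bg_uniformity))
  cat(sprintf("  foreground RSD:        %.4g\n", x$fg_rsd))
  cat(sprintf("  voxels: %d fg, %d bg (enlargement %g, %d bins)\n",
              x$n_fg_voxels, x$n_bg_voxels, x$enlargement, x$bins))
  invisible(x)
}
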