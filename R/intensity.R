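#' Choose the dynamic range for 8-bit conversion
#'
#' The lower bound is the `(1 - keep_fraction)` quantile of all voxel
#' intensities, so only the brightest `keep_fraction` of the (sparse) volume
#' survives clipping — this clears most of the background. The upper bound is
#' instance-aware by default: the lesser of `lower + 255` and half the peak
#' intensity inside a soma-centered block, so that a weak neuron's dynamic
#' range is stretched over the full 8-bit span rather than compressed under a
#' global scale. With `instance_aware = FALSE` the span is fixed at
#' `lower + 255`.
#'
#' @param vol A `volume3d` (typically the float high-pass output).
#' @param keep_fraction Fraction of voxels to keep above the lower bound,
#'   in `(0, 0.5)`; default 0.01 (top 1%), suited to sparse dendrite blocks at
#'   sub-micrometer resolution, adjustable by roughly +/-0.005 for other
#'   resolutions.
#' @param soma_center `(z, y, x)` voxel coordinates (0-based) of the soma;
#'   default the volume center (blocks are cropped soma-centered).
#' @param soma_block `(dz, dy, dx)` block size in voxels, default
#'   `c(32, 128, 128)` (i.e. 128 x 128 x 32 in XYZ order).
#' @param instance_aware Use the soma-peak rule for the upper bound.
#' @return An `intensity_bounds` object: `lower`, `upper`, `soma_peak`,
#'   `method`, and `fallback` (TRUE when the soma rule produced
#'   `upper <= lower` and the fixed span was used instead).
#' @export
compute_bounds <- function(vol, keep_fraction = 0.01, soma_center = NULL,
                           soma_block = c(32, 128, 128), instance_aware = TRUE) {
  assert_volume3d(vol)
  if (!is.finite(keep_fraction) || keep_fraction <= 0 || keep_fraction >= 0.5) {
    stop("keep_fraction must be in (0, 0.5)", call. = FALSE)
  }
  d <- vol$data
  if (length(d) == 0L) stop("empty volume", call. = FALSE)
  lower <- stats::quantile(d, probs = 1 - keep_fraction, names = FALSE)

  dm <- dim(d)
  if (is.null(soma_center)) soma_center <- (dm - 1) / 2
  ctr <- soma_center + 1  # to 1-based index space
  half <- soma_block / 2
  lo <- pmax(1, ceiling(ctr - half))
  hi <- pmin(dm, floor(ctr + half))
  if (any(lo > hi)) stop("soma block lies outside the volume", call. = FALSE)
  soma_peak <- max(d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])

  fallback <- FALSE
  if (instance_aware) {
    upper <- min(lower + 255, 0.5 * soma_peak)
    if (upper <= lower) {
      upper <- lower + 255
      fallback <- TRUE
    }
  } else {
    upper <- lower + 255
  }
  structure(list(lower = lower, upper = upper, soma_peak = soma_peak,
                 method = if (instance_aware) "instance_aware" else "fixed_span",
                 fallback = fallback),
            class = "intensity_bounds")
}

#' @export
print.intensity_bounds <- function(x, ...) {
  cat(sprintf("<intensity_bounds> [%g, %g] (%s%s), soma peak %g\n",
              x$lower, x$upper, x$method,
              if (isTRUE(x$fallback)) ", fallback to fixed span" else "",
              x$soma_peak))
  invisible(x)
}

#' Clip-rescale a float volume into 8 bits
#'
#' `out = round(255 * clamp((v - lower) / (upper - lower), 0, 1))`, with
#' half-away-from-zero rounding. Monotone non-decreasing in the input.
#'
#' @param vol A `volume3d`.
#' @param bounds An `intensity_bounds` (or any list with `lower` and `upper`,
#'   `upper > lower`).
#' @return `uint8` `volume3d`.
#' @export
shift_to_8bit <- function(vol, bounds) {
  assert_volume3d(vol)
  if (!is.numeric(bounds$lower) || !is.numeric(bounds$upper) ||
      bounds$upper <= bounds$lower) {
    stop("bounds must satisfy upper > lower", call. = FALSE)
  }
  u <- (vol$data - bounds$lower) / (bounds$upper - bounds$lower)
  vol$data <- round_half_up(255 * pmin(pmax(u, 0), 1))
  vol$dtype <- "uint8"
  vol
}
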