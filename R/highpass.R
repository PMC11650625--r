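#' Slice-recursive diffusion filter for axial flare/attenuation noise
#'
#' Sectioning-based whole-brain microscopy (fMOST) leaves an asymmetric flare
#' artifact: excited tissue below the knife surface bleeds into subsequent
#' sections, so each Z-slice is contaminated by a progressively blurred copy of
#' everything restored before it. Modeling that degradation as thermal
#' diffusion (one Gaussian blur of standard deviation `speed` per section), the
#' accumulated noise admits a two-slice recursion
#'
#'   noise_n = G_s * (res_[n-1] + noise_[n-1]),  noise_1 = 0
#'
#' and each slice is restored as `res_n = raw_n - alpha_n * noise_n` with the
#' noise-matching multiplier `alpha_n = k * mean(raw_n) / mean(noise_n)`
#' (`alpha_n = 0` when the noise estimate is identically zero; means are over
#' all pixels of the slice). `k = 1` subtracts the full matched noise —
#' aggressive, can break weak signal; the default `k = 0.9` is gentler.
#' Restored slices are clipped at 0 before being fed back into the recursion:
#' the model assumes a nonnegative signal, and feeding back negatives makes the
#' estimate oscillate.
#'
#' @param vol A `volume3d` (any dtype; processed as float).
#' @param speed Diffusion speed `s`: Gaussian std increment per slice, pixels.
#'   Default `0.25 / lateral_res_um` (1 px at 0.25 um/px) — the blur a 1-um
#'   section adds scales with how many pixels a micrometer spans.
#' @param k Noise-matching multiplier in `[0, 1]`, default 0.9.
#' @param truncate Kernel half-width in sigmas (default 4).
#' @param z_reverse Traverse slices in decreasing Z instead. The flare extends
#'   opposite to the sectioning direction; if a stack is stored with Z flipped,
#'   set this flag.
#' @param sigma_form `"recursive"` (default): each earlier slice's contribution
#'   is blurred once more per intervening section, so slice `i` reaches slice
#'   `n` with effective std `s * sqrt(n - i)`. `"flat"`: the accumulated signal
#'   is blurred with a single kernel of std `(n - 1) * s`, an alternative
#'   reading in which the blur width grows linearly with depth.
#' @param keep_noise Attach the per-slice noise estimates as attribute
#'   `"noise"` (list of matrices) for diagnostics.
#' @return Float `volume3d`; the input is unchanged.
#' @export
diffusion_filter <- function(vol, speed = NULL, k = 0.9, truncate = 4,
                             z_reverse = FALSE, sigma_form = c("recursive", "flat"),
                             keep_noise = FALSE) {
  assert_volume3d(vol)
  sigma_form <- match.arg(sigma_form)
  if (is.null(speed)) speed <- 0.25 / vol$lateral_res_um
  if (!is.finite(speed) || speed <= 0) stop("diffusion speed must be positive", call. = FALSE)
  if (!is.finite(k) || k < 0 || k > 1) stop("k must be in [0, 1]", call. = FALSE)

  d <- vol$data
  nz <- dim(d)[1]
  order_z <- if (z_reverse) nz:1 else 1:nz
  out <- array(0, dim = dim(d))
  noises <- if (keep_noise) vector("list", nz) else NULL

  res_prev <- d[order_z[1], , ]
  out[order_z[1], , ] <- res_prev
  noise_prev <- matrix(0, dim(d)[2], dim(d)[3])
  if (keep_noise) noises[[1]] <- noise_prev
  sum_res <- res_prev  # only used by sigma_form = "flat"

  for (n in seq_len(nz)[-1]) {
    raw_n <- d[order_z[n], , ]
    noise_n <- if (sigma_form == "recursive") {
      gaussian_blur2d(res_prev + noise_prev, speed, truncate)
    } else {
      gaussian_blur2d(sum_res, (n - 1) * speed, truncate)
    }
    mn <- mean(noise_n)
    alpha_n <- if (mn > 0) k * mean(raw_n) / mn else 0
    res_n <- pmax(raw_n - alpha_n * noise_n, 0)
    out[order_z[n], , ] <- res_n
    if (keep_noise) noises[[n]] <- noise_n
    noise_prev <- noise_n
    res_prev <- res_n
    if (sigma_form == "flat") sum_res <- sum_res + res_n
  }

  vol$data <- out
  vol$dtype <- "float"
  if (keep_noise) attr(vol, "noise") <- noises
  vol
}

#' Orthogonal profile filter for separable low-frequency backgrounds
#'
#' Stripe artifacts, uneven illumination and mosaic-boundary steps are well
#' approximated by a field `f(y, z) + g(x, z)`: constant along one lateral axis
#' within each slice. The filter estimates the two mean profiles
#' `P_yz(z, y) = mean_x(vol)` and `P_xz(z, x) = mean_y(vol)` and subtracts
#' their direct sum, adding the per-slice mean `m(z)` back once (each profile
#' contains the slice mean, so the plain sum would remove it twice):
#'
#'   out = vol - P_yz - P_xz + m(z)
#'
#' Any exactly separable field is annihilated, and the filter is idempotent
#' before clipping.
#'
#' @param vol A `volume3d` (processed as float).
#' @param clip Clip negative residuals to 0 (default `TRUE`).
#' @return Float `volume3d`.
#' @export
orthogonal_filter <- function(vol, clip = TRUE) {
  assert_volume3d(vol)
  d <- vol$data
  dm <- dim(d)
  nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
  p_yz <- rowMeans(d, dims = 2)                       # (nz, ny): mean over x
  p_xz <- rowMeans(aperm(d, c(1, 3, 2)), dims = 2)    # (nz, nx): mean over y
  m_z <- rowMeans(d, dims = 1)                        # (nz): per-slice mean
  # broadcast: first dims cycle fastest in R arrays
  out <- d - as.vector(p_yz)                                   # over x
  out <- out - aperm(array(p_xz, dim = c(nz, nx, ny)), c(1, 3, 2))  # over y
  out <- out + m_z
  if (clip) out <- pmax(out, 0)
  vol$data <- out
  vol$dtype <- "float"
  vol
}

#' High-pass filtering module
#'
#' Applies the diffusion filter then the orthogonal filter, each individually
#' deactivatable through the configuration (for ablation experiments).
#'
#' @param vol A `volume3d`.
#' @param cfg An [enhancement_config()].
#' @return Float `volume3d`.
#' @export
highpass_filter <- function(vol, cfg = enhancement_config()) {
  assert_volume3d(vol)
  cfg <- validate_config(cfg)
  out <- as_float(vol)
  if (isTRUE(cfg$diffusion$enabled)) {
    speed <- cfg$diffusion$speed
    if (is.null(speed)) speed <- 0.25 / cfg$lateral_res_um
    out <- diffusion_filter(out, speed = speed, k = cfg$diffusion$k,
                            truncate = cfg$diffusion$truncate,
                            z_reverse = isTRUE(cfg$diffusion$z_reverse),
                            sigma_form = cfg$diffusion$sigma_form)
  }
  if (isTRUE(cfg$orthogonal$enabled)) {
    out <- orthogonal_filter(out, clip = isTRUE(cfg$orthogonal$clip))
  }
  out
}
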