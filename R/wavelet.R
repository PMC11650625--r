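# Orthonormal 2D Haar transform. Orthonormality matters: it makes the
# finest-level diagonal coefficients carry the image noise at its native
# standard deviation, which the robust median estimator below relies on.

# one analysis level; pads odd dimensions by edge replication, remembers shape
haar_dwt2 <- function(m) {
  od <- dim(m)
  if (od[1] %% 2L == 1L) m <- rbind(m, m[od[1], , drop = FALSE])
  if (od[2] %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  s2 <- sqrt(2)
  oc <- seq(1L, ncol(m), by = 2L)
  lo_c <- (m[, oc, drop = FALSE] + m[, oc + 1L, drop = FALSE]) / s2
  hi_c <- (m[, oc, drop = FALSE] - m[, oc + 1L, drop = FALSE]) / s2
  or <- seq(1L, nrow(m), by = 2L)
  list(
    ll = (lo_c[or, , drop = FALSE] + lo_c[or + 1L, , drop = FALSE]) / s2,
    lh = (hi_c[or, , drop = FALSE] + hi_c[or + 1L, , drop = FALSE]) / s2,
    hl = (lo_c[or, , drop = FALSE] - lo_c[or + 1L, , drop = FALSE]) / s2,
    hh = (hi_c[or, , drop = FALSE] - hi_c[or + 1L, , drop = FALSE]) / s2,
    orig_dim = od
  )
}

haar_idwt2 <- function(w) {
  s2 <- sqrt(2)
  nr <- nrow(w$ll); nc <- ncol(w$ll)
  lo_c <- matrix(0, 2L * nr, nc); hi_c <- matrix(0, 2L * nr, nc)
  or <- seq(1L, 2L * nr, by = 2L)
  lo_c[or, ] <- (w$ll + w$hl) / s2
  lo_c[or + 1L, ] <- (w$ll - w$hl) / s2
  hi_c[or, ] <- (w$lh + w$hh) / s2
  hi_c[or + 1L, ] <- (w$lh - w$hh) / s2
  m <- matrix(0, 2L * nr, 2L * nc)
  oc <- seq(1L, 2L * nc, by = 2L)
  m[, oc] <- (lo_c + hi_c) / s2
  m[, oc + 1L] <- (lo_c - hi_c) / s2
  m[seq_len(w$orig_dim[1]), seq_len(w$orig_dim[2]), drop = FALSE]
}

#' Robust noise estimate from diagonal wavelet detail coefficients
#'
#' `sigma_hat = median(|coeff|) / 0.6745`, the standard robust estimator used
#' by the BayesShrink scheme, applied to the finest-level diagonal (HH) band.
#'
#' @param diag_detail Matrix (or vector) of HH detail coefficients.
#' @return Estimated noise standard deviation.
#' @export
estimate_noise_sigma <- function(diag_detail) {
  if (length(diag_detail) == 0L) stop("empty coefficient array", call. = FALSE)
  stats::median(abs(diag_detail)) / 0.6745
}

#' BayesShrink threshold for one detail sub-band
#'
#' With `var(detail)` taken as the raw second moment (detail bands are
#' zero-mean by construction), the signal spread is
#' `sigma_signal = sqrt(max(var(detail) - sigma_noise^2, 0))` and the threshold
#' is `sigma_noise^2 / sigma_signal`. When the band variance does not exceed
#' the noise floor (`sigma_signal = 0`) the band is considered pure noise and
#' the threshold is `max(|detail|)`, zeroing every coefficient.
#'
#' @param detail Matrix (or vector) of detail coefficients.
#' @param noise_sigma Noise standard deviation (see [estimate_noise_sigma()]).
#' @return Threshold value.
#' @export
bayes_threshold <- function(detail, noise_sigma) {
  if (length(detail) == 0L) return(0)
  v <- mean(detail^2)
  sig <- sqrt(max(v - noise_sigma^2, 0))
  if (sig > 0) noise_sigma^2 / sig else max(abs(detail))
}

hard_threshold <- function(coef, thr) {
  coef[abs(coef) <= thr] <- 0
  coef
}

#' Denoise one XY-slice with the Haar wavelet
#'
#' Up to `max_level` (default 2, matching the axial/lateral resolution gap)
#' analysis levels; every detail sub-band is hard-thresholded at its
#' BayesShrink threshold, with the noise sigma estimated once from the
#' level-1 HH band and reused at the coarser level. Approximation
#' coefficients are untouched.
#'
#' @param slice2d Numeric matrix.
#' @param max_level Maximum decomposition level (>= 1).
#' @return Denoised matrix (float; not clamped or rounded).
#' @export
denoise_slice <- function(slice2d, max_level = 2) {
  if (!is.matrix(slice2d)) stop("slice must be a matrix", call. = FALSE)
  if (max_level < 1) stop("max_level must be >= 1", call. = FALSE)
  if (any(dim(slice2d) < 2L)) {
    warning("slice smaller than 2x2; passing through unchanged")
    return(slice2d)
  }
  w1 <- haar_dwt2(slice2d)
  sigma <- estimate_noise_sigma(w1$hh)
  for (b in c("lh", "hl", "hh")) {
    w1[[b]] <- hard_threshold(w1[[b]], bayes_threshold(w1[[b]], sigma))
  }
  if (max_level >= 2 && all(dim(w1$ll) >= 2L)) {
    w2 <- haar_dwt2(w1$ll)
    for (b in c("lh", "hl", "hh")) {
      w2[[b]] <- hard_threshold(w2[[b]], bayes_threshold(w2[[b]], sigma))
    }
    w1$ll <- haar_idwt2(w2)
  }
  haar_idwt2(w1)
}

#' Slice-wise wavelet low-pass filtering of an 8-bit volume
#'
#' Runs [denoise_slice()] on every XY-slice (slice-wise to bound memory),
#' clamps to `[0, 255]` and re-quantizes. Removes high-frequency residue left
#' or amplified by the earlier stages, including 1-2 voxel bulges and
#' breakups.
#'
#' @param vol `uint8` `volume3d`.
#' @param max_level Maximum wavelet level (default 2).
#' @return `uint8` `volume3d`.
#' @export
wavelet_denoise <- function(vol, max_level = 2) {
  assert_volume3d(vol)
  if (vol$dtype != "uint8") {
    stop("wavelet denoising runs on the 8-bit volume (after intensity shifting)",
         call. = FALSE)
  }
  d <- vol$data
  for (k in seq_len(dim(d)[1])) {
    d[k, , ] <- round_half_up(pmin(pmax(denoise_slice(d[k, , ], max_level), 0), 255))
  }
  vol$data <- d
  vol
}
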