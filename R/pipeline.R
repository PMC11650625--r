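#' Pipeline configuration
#'
#' All tunables of the enhancement pipeline, grouped by stage. Each stage
#' carries an `enabled` flag so any combination can be ablated. Serializes
#' to/from plain-text YAML via [write_config()] / [read_config()].
#'
#' @param lateral_res_um Lateral resolution in um/px; sets the default
#'   diffusion speed `0.25 / lateral_res_um`.
#' @param diffusion Overrides for the diffusion stage: `enabled`, `speed`
#'   (NULL = derive from resolution), `k`, `truncate`, `z_reverse`,
#'   `sigma_form`.
#' @param orthogonal Overrides: `enabled`, `clip`.
#' @param shift Overrides for intensity shifting: `enabled`, `keep_fraction`,
#'   `instance_aware`, `soma_center` (NULL = volume center), `soma_block`.
#' @param wavelet Overrides: `enabled`, `max_level`.
#' @return An `enhancement_config` object.
#' @export
enhancement_config <- function(lateral_res_um = 0.25, diffusion = list(),
                               orthogonal = list(), shift = list(),
                               wavelet = list()) {
  cfg <- list(
    lateral_res_um = lateral_res_um,
    diffusion = utils::modifyList(
      list(enabled = TRUE, speed = NULL, k = 0.9, truncate = 4,
           z_reverse = FALSE, sigma_form = "recursive"),
      diffusion, keep.null = TRUE),
    orthogonal = utils::modifyList(list(enabled = TRUE, clip = TRUE), orthogonal),
    shift = utils::modifyList(
      list(enabled = TRUE, keep_fraction = 0.01, instance_aware = TRUE,
           soma_center = NULL, soma_block = c(32, 128, 128)),
      shift, keep.null = TRUE),
    wavelet = utils::modifyList(list(enabled = TRUE, max_level = 2), wavelet)
  )
  class(cfg) <- "enhancement_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "enhancement_config")) {
    stop("cfg must be an enhancement_config", call. = FALSE)
  }
  known <- c("lateral_res_um", "diffusion", "orthogonal", "shift", "wavelet")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) stop("unknown config key(s): ", paste(extra, collapse = ", "),
                              call. = FALSE)
  stopifnot(is.numeric(cfg$lateral_res_um), cfg$lateral_res_um > 0)
  d <- cfg$diffusion
  if (!is.null(d$speed) && (!is.numeric(d$speed) || d$speed <= 0)) {
    stop("diffusion speed must be positive", call. = FALSE)
  }
  if (!is.numeric(d$k) || d$k < 0 || d$k > 1) stop("k must be in [0, 1]", call. = FALSE)
  if (!d$sigma_form %in% c("recursive", "flat")) {
    stop("sigma_form must be 'recursive' or 'flat'", call. = FALSE)
  }
  s <- cfg$shift
  if (s$keep_fraction <= 0 || s$keep_fraction >= 0.5) {
    stop("keep_fraction must be in (0, 0.5)", call. = FALSE)
  }
  if (length(s$soma_block) != 3L) stop("soma_block must be (dz, dy, dx)", call. = FALSE)
  if (cfg$wavelet$max_level < 1) stop("wavelet max_level must be >= 1", call. = FALSE)
  cfg
}

#' @export
print.enhancement_config <- function(x, ...) {
  cat("<enhancement_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Write a configuration as YAML
#' @param cfg An `enhancement_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a YAML configuration
#' @param path Path to a YAML file written by [write_config()].
#' @return An `enhancement_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("lateral_res_um", "diffusion", "orthogonal", "shift", "wavelet")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) stop("unknown config key(s): ", paste(extra, collapse = ", "),
                              call. = FALSE)
  do.call(enhancement_config, raw)
}

#' Run the full enhancement pipeline
#'
#' Fixed stage order: high-pass filtering (diffusion then orthogonal),
#' instance-aware intensity shifting with 8-bit downgrade, slice-wise wavelet
#' denoising. Each stage honors its `enabled` flag; with intensity shifting
#' disabled the volume is rescaled over the full bit-depth range of the input
#' (so an 8-bit input with every stage disabled passes through unchanged).
#' Pure function of `(vol, cfg)`: no randomness, identical inputs give
#' bitwise-identical outputs.
#'
#' @param vol Integer-typed `volume3d` (8- or 16-bit).
#' @param cfg An [enhancement_config()].
#' @param verbose Log resolved parameters and stage timings to stderr.
#' @return `uint8` `volume3d`, with the intensity bounds used attached as
#'   attribute `"bounds"`.
#' @export
niend_enhance <- function(vol, cfg = enhancement_config(), verbose = FALSE) {
  assert_volume3d(vol)
  cfg <- validate_config(cfg)
  if (vol$dtype == "float") {
    stop("niend_enhance expects an integer-typed (8- or 16-bit) volume", call. = FALSE)
  }
  if (verbose) {
    message("resolved config:\n", yaml::as.yaml(unclass(cfg)))
  }
  in_top <- bit_depth_max(vol$dtype)
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) {
    if (verbose) message(sprintf("[niend] %-12s %6.2f s", name, tic() - t0))
  }

  t0 <- tic()
  out <- tryCatch(highpass_filter(vol, cfg),
                  error = function(e) stop("highpass: ", conditionMessage(e), call. = FALSE))
  stage("highpass", t0)

  t0 <- tic()
  if (isTRUE(cfg$shift$enabled)) {
    bounds <- tryCatch(
      compute_bounds(out, keep_fraction = cfg$shift$keep_fraction,
                     soma_center = cfg$shift$soma_center,
                     soma_block = cfg$shift$soma_block,
                     instance_aware = isTRUE(cfg$shift$instance_aware)),
      error = function(e) stop("intensity: ", conditionMessage(e), call. = FALSE))
  } else {
    # no instance-aware windowing: plain downgrade over the input bit range
    bounds <- structure(list(lower = 0, upper = in_top, soma_peak = NA_real_,
                             method = "full_range", fallback = FALSE),
                        class = "intensity_bounds")
  }
  out <- shift_to_8bit(out, bounds)
  stage("intensity", t0)

  t0 <- tic()
  if (isTRUE(cfg$wavelet$enabled)) {
    out <- tryCatch(wavelet_denoise(out, max_level = cfg$wavelet$max_level),
                    error = function(e) stop("wavelet: ", conditionMessage(e), call. = FALSE))
  }
  stage("wavelet", t0)

  attr(out, "bounds") <- bounds
  out
}

#' LZMA compression rate of a volume
#'
#' Serializes the volume as an uncompressed TIFF and reports
#' `compressed size / full file size` after LZMA (xz) compression of the byte
#' stream. Well-enhanced sparse images compress to around a percent; raw
#' 16-bit acquisitions do not.
#'
#' @param vol Integer-typed `volume3d`.
#' @param codec Only `"lzma"`.
#' @return Compression rate in `(0, 1]`.
#' @export
compression_rate <- function(vol, codec = "lzma") {
  assert_volume3d(vol)
  codec <- match.arg(codec, "lzma")
  if (vol$dtype == "float") {
    stop("compression rate is defined for integer-typed volumes", call. = FALSE)
  }
  tf <- tempfile(fileext = ".tiff")
  on.exit(unlink(tf))
  write_stack(vol, tf, compression = "none")
  raw_bytes <- readBin(tf, "raw", n = file.info(tf)$size)
  comp <- memCompress(raw_bytes, type = "xz")
  length(comp) / length(raw_bytes)
}
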