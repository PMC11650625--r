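#' 3D image volume
#'
#' Container for a 3D grayscale image stack. Data are stored slice-major in
#' `(z, y, x)` order, so `data[k, , ]` is the k-th optical/physical section:
#' every filter in the pipeline iterates over Z-slices and this layout keeps
#' slice access contiguous. File formats and figure captions in microscopy
#' usually quote shapes in XYZ order; conversion happens at the I/O boundary
#' only.
#'
#' @param data Numeric 3D array, indexed `(z, y, x)`.
#' @param dtype One of `"uint8"`, `"uint16"`, `"float"`. Integer dtypes are
#'   validated against their range; `"float"` volumes are intermediate results
#'   and must be converted before being written to disk.
#' @param voxel_size Numeric length-3 `(z, y, x)` voxel pitch in micrometers.
#'   Defaults to `c(1, lateral_res_um, lateral_res_um)`: sectioning systems
#'   are typically ~1 um axially and sub-micrometer laterally. Carried as
#'   metadata; in-pipeline distances are in voxel units.
#' @param lateral_res_um Micrometers per pixel in X/Y (used for the default
#'   diffusion speed).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, dtype = c("uint16", "uint8", "float"),
                     voxel_size = NULL, lateral_res_um = 0.25) {
  dtype <- match.arg(dtype)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("volume data contains NA", call. = FALSE)
  if (dtype != "float") {
    top <- bit_depth_max(dtype)
    rng <- range(data)
    if (rng[1] < 0 || rng[2] > top) {
      stop(sprintf("values [%g, %g] outside %s range [0, %d]",
                   rng[1], rng[2], dtype, top), call. = FALSE)
    }
    if (any(data != floor(data))) {
      stop(sprintf("%s volume has non-integer values", dtype), call. = FALSE)
    }
  }
  if (is.null(voxel_size)) voxel_size <- c(1, lateral_res_um, lateral_res_um)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 strictly positive numbers (z, y, x)", call. = FALSE)
  }
  if (!is.finite(lateral_res_um) || lateral_res_um <= 0) {
    stop("lateral_res_um must be positive", call. = FALSE)
  }
  structure(
    list(data = data, dtype = dtype, voxel_size = voxel_size,
         lateral_res_um = as.numeric(lateral_res_um)),
    class = "volume3d"
  )
}

bit_depth_max <- function(dtype) {
  switch(dtype, uint8 = 255L, uint16 = 65535L,
         stop("no integer range for dtype ", dtype, call. = FALSE))
}

is_volume3d <- function(x) inherits(x, "volume3d")

assert_volume3d <- function(x, what = "input") {
  if (!is_volume3d(x)) stop(what, " must be a volume3d object", call. = FALSE)
  invisible(x)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d (z, y, x), %s\n", d[1], d[2], d[3], x$dtype))
  cat(sprintf("  voxel size (um): z=%g y=%g x=%g; lateral res %g um/px\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$lateral_res_um))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Convert a volume to float dtype
#'
#' @param vol A `volume3d`.
#' @return The same volume with `dtype = "float"`.
#' @export
as_float <- function(vol) {
  assert_volume3d(vol)
  vol$dtype <- "float"
  vol
}

#' Quantize a float volume to an unsigned integer dtype
#'
#' Values are clamped to the dtype range and rounded half away from zero
#' (platform-stable, unlike IEEE round-half-even).
#'
#' @param vol A `volume3d`.
#' @param dtype `"uint8"` or `"uint16"`.
#' @return Integer-typed `volume3d`.
#' @export
quantize <- function(vol, dtype = c("uint8", "uint16")) {
  assert_volume3d(vol)
  dtype <- match.arg(dtype)
  top <- bit_depth_max(dtype)
  d <- round_half_up(pmin(pmax(vol$data, 0), top))
  vol$data <- d
  vol$dtype <- dtype
  vol
}

# round half away from zero; inputs here are always >= 0
round_half_up <- function(x) floor(x + 0.5)
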