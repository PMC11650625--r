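# Phantom generator and forward degradation models. These emulate the noise
# classes seen in sectioning-based whole-brain imaging: the axial flare
# (cumulative Gaussian diffusion of preceding sections), separable
# low-frequency backgrounds (stripes / mosaic boundaries / uneven
# illumination) and additive sensor noise over a baseline offset.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic neuronal phantom
#'
#' Defaults describe a typical sparse soma-centered dendrite block at 0.25
#' um/px lateral and 1 um axial resolution, 16-bit acquisition: a handful of
#' tubular neurites radiating from a central soma, foreground around 2000
#' counts (weak relative to the 16-bit range, as real neurites are), a soma
#' several-fold brighter, flare diffusion speed of 1 px per section, a
#' separable background field of a couple hundred counts, sensor noise sigma
#' of 10 counts over a 100-count baseline.
#'
#' @param shape `(Nz, Ny, Nx)`, minimum `(8, 32, 32)`.
#' @param n_neurites Number of neurites (0 = soma only).
#' @param radius_range Neurite radius range in voxels.
#' @param soma_radius Soma radius in voxels.
#' @param fg_intensity Neurite intensity (16-bit counts).
#' @param flare_speed Diffusion speed `s` for the forward flare model.
#' @param separable_amp Amplitude of the separable background field.
#' @param noise_sigma Additive Gaussian noise sd.
#' @param bg_offset Baseline offset.
#' @param seed RNG seed; identical seeds give bitwise-identical phantoms.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(64, 256, 256), n_neurites = 5,
                         radius_range = c(1.5, 3), soma_radius = 6,
                         fg_intensity = 2000, flare_speed = 1,
                         separable_amp = 200, noise_sigma = 10,
                         bg_offset = 100, seed = 42) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(8L, 32L, 32L))) {
    stop("shape must be (Nz, Ny, Nx) with minimum (8, 32, 32)", call. = FALSE)
  }
  for (v in list(fg_intensity, flare_speed, separable_amp, noise_sigma,
                 bg_offset, soma_radius)) {
    if (!is.finite(v) || v < 0) stop("all amplitudes must be >= 0", call. = FALSE)
  }
  if (n_neurites < 0) stop("n_neurites must be >= 0", call. = FALSE)
  structure(list(shape = shape, n_neurites = as.integer(n_neurites),
                 radius_range = as.numeric(radius_range),
                 soma_radius = soma_radius, fg_intensity = fg_intensity,
                 flare_speed = flare_speed, separable_amp = separable_amp,
                 noise_sigma = noise_sigma, bg_offset = bg_offset,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a clean phantom volume with its gold-standard morphology
#'
#' Neurites are smooth random-walk centerlines of unit step radiating from a
#' central soma, painted as tubes with Gaussian radial falloff calibrated so
#' the half-intensity surface sits at the nominal radius (the gold-standard
#' radius). The soma is a brighter blob (4x the neurite intensity, as somata
#' typically are) with the same half-intensity calibration. The gold SWC holds
#' the soma node plus one node per centerline step, in 0-based voxel
#' coordinates.
#'
#' @param spec A [phantom_spec()].
#' @return List with `clean` (float `volume3d`) and `gold`
#'   (`swc_morphology`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec", call. = FALSE)
  shp <- spec$shape
  if (2 * spec$soma_radius >= min(shp)) {
    stop("soma does not fit in the volume", call. = FALSE)
  }
  with_seed(spec$seed, {
    vol <- array(0, dim = shp)
    ctr <- (shp - 1) / 2  # (z, y, x)
    blobs <- list()  # (linear index, value) pairs, max-combined at the end
    # soma: value 4*fg * 2^(-3 (d/R)^2) -> exactly fg/2 at d = R
    blobs[[1]] <- blob_values(shp, ctr, spec$soma_radius, 4 * spec$fg_intensity,
                              sharpness = 3)
    margin <- max(spec$radius_range) + 2
    # neurite length scales with the block so sparsity stays realistic
    n_steps <- as.integer(round(1.5 * max(shp)))
    n_total <- 1L + spec$n_neurites * n_steps
    id <- seq_len(n_total)
    type <- c(1L, rep(3L, n_total - 1L))
    xx <- numeric(n_total); yy <- numeric(n_total); zz <- numeric(n_total)
    rad <- numeric(n_total); par <- integer(n_total)
    xx[1] <- ctr[3]; yy[1] <- ctr[2]; zz[1] <- ctr[1]
    rad[1] <- spec$soma_radius; par[1] <- -1L
    next_id <- 2L
    for (nn in seq_len(spec$n_neurites)) {
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      dir <- normalize3(stats::rnorm(3))
      pos <- ctr + dir * spec$soma_radius
      parent <- 1L
      for (s in seq_len(n_steps)) {
        dir <- normalize3(dir + 0.2 * stats::rnorm(3))
        nxt <- pos + dir
        # bounce off the volume walls, keeping the tube inside
        for (ax in 1:3) {
          if (nxt[ax] < margin || nxt[ax] > shp[ax] - 1 - margin) {
            dir[ax] <- -dir[ax]
            nxt[ax] <- pos[ax] + dir[ax]
          }
        }
        pos <- nxt
        blobs[[length(blobs) + 1L]] <- blob_values(shp, pos, r,
                                                   spec$fg_intensity,
                                                   sharpness = 1)
        xx[next_id] <- pos[3]; yy[next_id] <- pos[2]; zz[next_id] <- pos[1]
        rad[next_id] <- r; par[next_id] <- parent
        parent <- next_id
        next_id <- next_id + 1L
      }
    }
    li <- unlist(lapply(blobs, `[[`, "li"))
    val <- unlist(lapply(blobs, `[[`, "val"))
    # ascending-value writes: the last (largest) write wins, i.e. max-combine
    ord <- order(val)
    vol[li[ord]] <- val[ord]
    nodes <- data.frame(id = id, type = type, x = xx, y = yy, z = zz,
                        radius = rad, parent = par)
    clean <- volume3d(vol, dtype = "float", lateral_res_um = 0.25)
    gold <- swc_morphology(nodes,
                           provenance = sprintf("phantom seed %d", spec$seed))
    list(clean = clean, gold = gold)
  })
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

# radial blob value = amp * 2^(-sharpness * (d/r)^2) within reach 2r, as
# (linear index, value) pairs; the caller max-combines all blobs in one pass
blob_values <- function(shp, center, r, amp, sharpness = 1) {
  reach <- 2 * r
  lo <- pmax(floor(center - reach), 0) + 1
  hi <- pmin(ceiling(center + reach), shp - 1) + 1
  if (any(lo > hi)) return(list(li = integer(0), val = numeric(0)))
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  bz <- length(zs); by <- length(ys); bx <- length(xs)
  Z <- rep(zs - 1, times = by * bx)
  Y <- rep(rep(ys - 1, each = bz), times = bx)
  X <- rep(xs - 1, each = bz * by)
  d2 <- (Z - center[1])^2 + (Y - center[2])^2 + (X - center[3])^2
  list(li = (Z + 1) + shp[1] * (Y + X * shp[2]),
       val = amp * 2^(-sharpness * d2 / r^2))
}

#' Forward flare/attenuation degradation
#'
#' Runs the diffusion noise model forward: each slice receives a Gaussian-
#' blurred copy of everything that came before it,
#' `noise_n = G_s * (clean_[n-1] + noise_[n-1])`, `noise_1 = 0`, and the
#' degraded slice is `clean_n + noise_n`. This is exactly the degradation the
#' diffusion filter inverts at `k = 1`.
#'
#' @param clean Float `volume3d`.
#' @param s Diffusion speed (Gaussian std per slice, pixels).
#' @param truncate Kernel half-width in sigmas.
#' @return Degraded float `volume3d`.
#' @export
apply_flare_forward <- function(clean, s, truncate = 4) {
  assert_volume3d(clean)
  if (!is.finite(s) || s <= 0) stop("s must be positive", call. = FALSE)
  d <- clean$data
  nz <- dim(d)[1]
  out <- d
  noise_prev <- matrix(0, dim(d)[2], dim(d)[3])
  for (n in seq_len(nz)[-1]) {
    noise_n <- gaussian_blur2d(d[n - 1, , ] + noise_prev, s, truncate)
    out[n, , ] <- d[n, , ] + noise_n
    noise_prev <- noise_n
  }
  clean$data <- out
  clean$dtype <- "float"
  clean
}

# bilinear upsampling of a coarse random grid to (n1, n2), scaled to [0, 1]
smooth_field <- function(n1, n2, coarse = 5) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  rows <- apply(g, 2, function(col) {
    stats::approx(seq(0, 1, length.out = coarse), col,
                  xout = seq(0, 1, length.out = n1))$y
  })
  full <- t(apply(rows, 1, function(row) {
    stats::approx(seq(0, 1, length.out = coarse), row,
                  xout = seq(0, 1, length.out = n2))$y
  }))
  rng <- range(full)
  if (rng[2] > rng[1]) (full - rng[1]) / (rng[2] - rng[1]) else full * 0
}

#' Add a separable low-frequency background field
#'
#' Adds `f(y, z) + g(x, z)`: two smooth random fields constant along one
#' lateral axis, plus a step edge in `g` mimicking a mosaic boundary. This is
#' precisely the class of artifact the orthogonal filter annihilates.
#'
#' @param vol A `volume3d` (processed as float).
#' @param amp Field amplitude (counts); 0 adds nothing.
#' @param seed RNG seed.
#' @return Float `volume3d`.
#' @export
add_separable_background <- function(vol, amp, seed = 1) {
  assert_volume3d(vol)
  if (amp < 0) stop("amp must be >= 0", call. = FALSE)
  if (amp == 0) return(as_float(vol))
  dm <- dim(vol$data)
  nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
  with_seed(seed, {
    f_yz <- amp * smooth_field(nz, ny)            # (nz, ny)
    g_xz <- 0.5 * amp * smooth_field(nz, nx)      # (nz, nx)
    cut <- sample(seq(floor(nx / 4), ceiling(3 * nx / 4)), 1)
    g_xz[, cut:nx] <- g_xz[, cut:nx] + 0.5 * amp  # mosaic boundary step
    out <- vol$data + as.vector(f_yz)             # broadcast over x
    out <- out + aperm(array(g_xz, dim = c(nz, nx, ny)), c(1, 3, 2))
    vol$data <- out
    vol$dtype <- "float"
    vol
  })
}

#' Add baseline offset and Gaussian sensor noise, quantize to 16-bit
#'
#' `out = clamp(round(vol + offset + N(0, sigma)), 0, 65535)` as `uint16`,
#' matching 16-bit acquisition.
#'
#' @param vol A `volume3d`.
#' @param sigma Noise standard deviation (counts).
#' @param offset Baseline offset (counts).
#' @param seed RNG seed.
#' @return `uint16` `volume3d`.
#' @export
add_noise <- function(vol, sigma, offset = 0, seed = 1) {
  assert_volume3d(vol)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  with_seed(seed, {
    d <- vol$data + offset
    if (sigma > 0) d <- d + stats::rnorm(length(d), 0, sigma)
    vol$data <- d
    quantize(vol, "uint16")
  })
}

#' Degrade a clean phantom with the full noise stack
#'
#' Convenience wrapper: flare diffusion, separable background, then offset +
#' sensor noise with 16-bit quantization, using the amplitudes in `spec`.
#'
#' @param clean Float `volume3d` (from [make_phantom()]).
#' @param spec The [phantom_spec()] holding the degradation amplitudes.
#' @return `uint16` `volume3d`.
#' @export
degrade_phantom <- function(clean, spec) {
  out <- clean
  if (spec$flare_speed > 0) out <- apply_flare_forward(out, spec$flare_speed)
  out <- add_separable_background(out, spec$separable_amp, seed = spec$seed + 1L)
  add_noise(out, spec$noise_sigma, spec$bg_offset, seed = spec$seed + 2L)
}

#' Displace a contiguous fraction of a morphology's cable
#'
#' Walks the tree in depth-first order, takes the suffix of edges carrying
#' exactly `fraction` of the total cable length (splitting the boundary edge
#' with an inserted node so the fraction is exact), and displaces that part by
#' `displacement` voxels. The displaced part becomes a separate root;
#' displaced nodes whose parent stayed put are likewise detached, so no edge
#' is stretched between the two parts. Used to construct morphologies with a
#' known deviating-length fraction.
#'
#' @param gold Non-empty `swc_morphology`.
#' @param fraction Cable-length fraction to displace, in `[0, 1]`.
#' @param displacement Displacement magnitude in voxels.
#' @param seed Seed for the random displacement direction (unused when
#'   `direction` is given).
#' @param direction Optional `(dx, dy, dz)` direction (normalized internally).
#' @return Perturbed `swc_morphology`.
#' @export
perturb_morphology <- function(gold, fraction, displacement, seed = 1,
                               direction = NULL) {
  assert_swc(gold)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (fraction == 0) return(gold)
  dvec <- if (is.null(direction)) {
    with_seed(seed, normalize3(stats::rnorm(3)))
  } else {
    normalize3(direction)
  }
  dvec <- dvec * displacement  # (dx, dy, dz)
  nd <- gold$nodes
  if (fraction == 1) {
    nd$x <- nd$x + dvec[1]; nd$y <- nd$y + dvec[2]; nd$z <- nd$z + dvec[3]
    return(swc_morphology(nd, provenance = "perturbed (all)"))
  }
  # depth-first edge order
  children <- split(seq_len(nrow(nd)), factor(nd$parent, levels = nd$id))
  roots <- which(nd$parent == -1)
  edge_child <- integer(0)
  stack <- rev(roots)
  while (length(stack) > 0L) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd$parent[i] != -1) edge_child <- c(edge_child, i)
    kids <- children[[as.character(nd$id[i])]]
    if (!is.null(kids)) stack <- c(stack, rev(kids))
  }
  pidx <- match(nd$parent, nd$id)
  elen <- vapply(edge_child, function(i) {
    p <- pidx[i]
    sqrt((nd$x[i] - nd$x[p])^2 + (nd$y[i] - nd$y[p])^2 + (nd$z[i] - nd$z[p])^2)
  }, numeric(1))
  total <- sum(elen)
  if (total == 0) stop("morphology has no cable to displace", call. = FALSE)
  target <- fraction * total
  # find the boundary edge scanning from the end of the DFS order
  cum <- 0
  bi <- length(edge_child)
  while (bi >= 1L && cum + elen[bi] < target) {
    cum <- cum + elen[bi]
    bi <- bi - 1L
  }
  if (bi < 1L) bi <- 1L
  displaced <- if (bi < length(edge_child)) edge_child[(bi + 1L):length(edge_child)] else integer(0)
  need <- target - cum  # displaced length taken from the boundary edge
  ci <- edge_child[bi]; pi_ <- pidx[ci]
  a <- c(nd$x[pi_], nd$y[pi_], nd$z[pi_])
  b <- c(nd$x[ci], nd$y[ci], nd$z[ci])
  L <- elen[bi]
  tsplit <- 1 - min(need / L, 1)  # split point measured from parent end
  M <- a + tsplit * (b - a)
  rM <- nd$radius[pi_] + tsplit * (nd$radius[ci] - nd$radius[pi_])
  id_m <- max(nd$id) + 1L
  id_m2 <- max(nd$id) + 2L
  disp_set <- c(ci, displaced)
  out <- nd
  out$x[disp_set] <- out$x[disp_set] + dvec[1]
  out$y[disp_set] <- out$y[disp_set] + dvec[2]
  out$z[disp_set] <- out$z[disp_set] + dvec[3]
  # detach displaced nodes whose parent stayed in place
  kept <- setdiff(seq_len(nrow(nd)), disp_set)
  for (i in disp_set) {
    if (i == ci) next
    if (pidx[i] %in% kept) out$parent[i] <- -1L
  }
  # kept side ends at M; displaced side starts at a new root M + d
  out <- rbind(out,
               data.frame(id = id_m, type = out$type[ci], x = M[1], y = M[2],
                          z = M[3], radius = rM, parent = out$parent[ci]),
               data.frame(id = id_m2, type = out$type[ci],
                          x = M[1] + dvec[1], y = M[2] + dvec[2],
                          z = M[3] + dvec[3], radius = rM, parent = -1L))
  out$parent[ci] <- id_m2
  swc_morphology(out, provenance = sprintf("perturbed fraction=%g disp=%g",
                                           fraction, displacement))
}
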