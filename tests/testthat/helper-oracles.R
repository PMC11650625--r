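# Independent oracles and fixture builders. Everything here recomputes
# quantities by a different route than the package (naive convolution,
# all-pairs distances, direct profile sums) so agreement is meaningful.

# naive Gaussian blur: dense kernel outer product, mirror extension, direct
# double loop over kernel taps (no shared code path with the package blur)
oracle_blur <- function(m, sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k1 <- exp(-0.5 * ((-r:r) / sigma)^2)
  k1 <- k1 / sum(k1)
  mirror <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (a in -r:r) {
    rows <- mirror((1:nr) + a, nr)
    tmp <- matrix(0, nr, nc)
    for (b in -r:r) {
      cols <- mirror((1:nc) + b, nc)
      tmp <- tmp + k1[b + r + 1L] * m[rows, cols, drop = FALSE]
    }
    out <- out + k1[a + r + 1L] * tmp
  }
  out
}

# explicit accumulated-noise sum: noise_n = sum_{i<n} res_i blurred (n - i)
# successive times with std s (composition applied literally, no recursion)
oracle_noise_sum <- function(res_slices, n, s, truncate = 4) {
  acc <- matrix(0, nrow(res_slices[[1]]), ncol(res_slices[[1]]))
  for (i in seq_len(n - 1)) {
    contrib <- res_slices[[i]]
    for (j in seq_len(n - i)) contrib <- oracle_blur(contrib, s, truncate)
    acc <- acc + contrib
  }
  acc
}

# all-pairs minimum distances from each row of a to the rows of b
oracle_min_dists <- function(a, b) {
  apply(a, 1, function(p) {
    sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2 + (b[, 3] - p[3])^2))
  })
}

oracle_pds <- function(m, ref, thr = 15, step = 1) {
  sm <- resample_morphology(m, step)
  sr <- resample_morphology(ref, step)
  d <- oracle_min_dists(sm$points, sr$points)
  sum(sm$weights[d > thr]) / sum(sm$weights)
}

# direct histogram uniformity (independent binning route via cut())
oracle_uniformity <- function(bg, whole, bins = 256) {
  z <- (bg - mean(whole)) / sqrt(mean((whole - mean(whole))^2))
  br <- seq(min(z), max(z), length.out = bins + 1)
  cnt <- table(cut(z, breaks = br, include.lowest = TRUE))
  sum((as.numeric(cnt) / length(z))^2)
}

# straight polyline morphology along +x starting at `origin` (x, y, z)
line_morphology <- function(length_voxels, node_spacing = 5,
                            origin = c(0, 0, 0), radius = 1) {
  n <- ceiling(length_voxels / node_spacing) + 1L
  x <- origin[1] + seq(0, length_voxels, length.out = n)
  swc_morphology(data.frame(
    id = seq_len(n), type = 3L, x = x, y = origin[2], z = origin[3],
    radius = radius, parent = c(-1L, seq_len(n - 1L))
  ))
}

# small random tree morphology for property tests
random_tree <- function(n_nodes, seed, spread = 40) {
  set.seed(seed)
  x <- numeric(n_nodes); y <- numeric(n_nodes); z <- numeric(n_nodes)
  parent <- integer(n_nodes)
  x[1] <- spread / 2; y[1] <- spread / 2; z[1] <- spread / 2; parent[1] <- -1L
  for (i in seq_len(n_nodes)[-1]) {
    p <- sample(i - 1L, 1L)
    parent[i] <- p
    x[i] <- x[p] + rnorm(1, sd = 2)
    y[i] <- y[p] + rnorm(1, sd = 2)
    z[i] <- z[p] + rnorm(1, sd = 2)
  }
  swc_morphology(data.frame(id = seq_len(n_nodes), type = 3L, x = x, y = y,
                            z = z, radius = runif(n_nodes, 0.5, 2),
                            parent = parent))
}

# small shared phantom for module tests (kept cheap)
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(16, 48, 48), n_neurites = 2, soma_radius = 4,
         radius_range = c(1, 2), seed = 11),
    list(...))
  do.call(phantom_spec, args)
}
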