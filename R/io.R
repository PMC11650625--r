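#' Read a multi-page TIFF into a volume
#'
#' Pages map to Z-slices; each page must be single-channel grayscale of
#' identical shape, 8- or 16-bit unsigned. TIFF resolution metadata is not
#' trusted: voxel size comes from the caller.
#'
#' @param path Path to a multi-page TIFF file.
#' @param lateral_res_um Micrometers per pixel in X/Y.
#' @param voxel_size Optional explicit `(z, y, x)` voxel size in micrometers.
#' @return A `volume3d` with integer dtype read from the file.
#' @export
read_stack <- function(path, lateral_res_um = 0.25, voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has no pages: ", path, call. = FALSE)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L) {
      stop(sprintf("unsupported sample format: page %d is not single-channel grayscale", i),
           call. = FALSE)
    }
  }
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp)) {
      stop(sprintf("mixed page shapes: page 1 is %dx%d but page %d is %dx%d",
                   shp[1], shp[2], i, dim(pages[[i]])[1], dim(pages[[i]])[2]),
           call. = FALSE)
    }
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported sample format: ", bits, " bits per sample", call. = FALSE)
  }
  arr <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  volume3d(arr, dtype = if (bits == 8L) "uint8" else "uint16",
           voxel_size = voxel_size, lateral_res_um = lateral_res_um)
}

#' Write a volume as a multi-page TIFF
#'
#' Lossless: `read_stack(write_stack(v))` returns bitwise-equal data. Float
#' volumes must be quantized first (see [quantize()]).
#'
#' @param vol Integer-typed `volume3d`.
#' @param path Output path.
#' @param compression `"none"` (default), `"LZW"` or `"deflate"`.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(vol, path, compression = "none") {
  assert_volume3d(vol)
  if (vol$dtype == "float") {
    stop("cannot write a float volume; quantize() it to uint8/uint16 first",
         call. = FALSE)
  }
  top <- bit_depth_max(vol$dtype)
  bits <- if (vol$dtype == "uint8") 8L else 16L
  nz <- dim(vol$data)[1]
  pages <- vector("list", nz)
  for (k in seq_len(nz)) pages[[k]] <- vol$data[k, , ] / top
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = compression,
                  reduce = FALSE)
  invisible(path)
}

#' Neuron morphology (SWC)
#'
#' A tree (or forest) of nodes in the standard 7-column SWC layout. All
#' coordinates are voxel units, 0-based at voxel centers, in the same frame as
#' the companion image stack: SWC `(x, y, z)` corresponds to array index
#' `(z + 1, y + 1, x + 1)`.
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent` (parent `-1` marks a root).
#' @param provenance Free-text origin (file path, generator seed).
#' @return An object of class `swc_morphology`.
#' @export
swc_morphology <- function(nodes = empty_swc_nodes(), provenance = "") {
  nodes <- as.data.frame(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop("nodes must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  nodes <- nodes[, need]
  if (nrow(nodes) > 0L) {
    if (anyDuplicated(nodes$id)) {
      stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1], call. = FALSE)
    }
    bad <- !(nodes$parent == -1 | nodes$parent %in% nodes$id)
    if (any(bad)) {
      stop("node ", nodes$id[which(bad)[1]], " references missing parent ",
           nodes$parent[which(bad)[1]], call. = FALSE)
    }
    if (any(nodes$radius < 0)) stop("negative radius", call. = FALSE)
    check_acyclic(nodes)
    if (!any(nodes$parent == -1)) stop("morphology has no root node", call. = FALSE)
  }
  structure(list(nodes = nodes, provenance = provenance), class = "swc_morphology")
}

empty_swc_nodes <- function() {
  data.frame(id = integer(), type = integer(), x = numeric(), y = numeric(),
             z = numeric(), radius = numeric(), parent = integer())
}

check_acyclic <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)  # NA for roots
  depth <- rep(NA_integer_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    j <- i
    chain <- integer(0)
    while (is.na(depth[j])) {
      if (j %in% chain) stop("cycle detected at node ", nodes$id[j], call. = FALSE)
      chain <- c(chain, j)
      p <- idx[j]
      if (is.na(p)) { depth[j] <- 0L; break }
      j <- p
    }
    for (k in rev(chain)) {
      p <- idx[k]
      if (!is.na(p) && is.na(depth[k])) depth[k] <- depth[p] + 1L
    }
  }
  invisible(depth)
}

n_nodes <- function(m) nrow(m$nodes)

is_swc <- function(x) inherits(x, "swc_morphology")

assert_swc <- function(x, what = "morphology") {
  if (!is_swc(x)) stop(what, " must be an swc_morphology", call. = FALSE)
  invisible(x)
}

#' @export
print.swc_morphology <- function(x, ...) {
  n <- nrow(x$nodes)
  roots <- sum(x$nodes$parent == -1)
  cat(sprintf("<swc_morphology> %d nodes, %d root(s), total cable %.1f voxels\n",
              n, roots, total_cable_length(x)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Total cable length of a morphology (voxel units)
#'
#' Sum of parent-child edge lengths.
#'
#' @param m An `swc_morphology`.
#' @return Numeric scalar.
#' @export
total_cable_length <- function(m) {
  assert_swc(m)
  nd <- m$nodes
  if (nrow(nd) == 0L) return(0)
  pi <- match(nd$parent, nd$id)
  has <- !is.na(pi)
  if (!any(has)) return(0)
  sum(sqrt((nd$x[has] - nd$x[pi[has]])^2 +
           (nd$y[has] - nd$y[pi[has]])^2 +
           (nd$z[has] - nd$z[pi[has]])^2))
}

#' Read an SWC reconstruction file
#'
#' Standard whitespace-delimited 7-column format; `#` lines are comments.
#' Coordinates are taken as voxel units; use `scale` to convert
#' micrometer-scaled files.
#'
#' @param path Path to an SWC file.
#' @param scale Multiplier `(x, y, z)` applied to coordinates and radius
#'   (radius uses the x factor).
#' @return An `swc_morphology`.
#' @export
read_swc <- function(path, scale = c(1, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) != 7L) {
      stop(sprintf("line %d: expected 7 columns, got %d", ln, length(f)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric field", ln), call. = FALSE)
    rows[[i]] <- v
  }
  if (length(rows) == 0L) return(swc_morphology(provenance = path))
  m <- do.call(rbind, rows)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3] * scale[1], y = m[, 4] * scale[2],
                      z = m[, 5] * scale[3], radius = m[, 6] * scale[1],
                      parent = as.integer(m[, 7]))
  dup <- duplicated(nodes$id)
  if (any(dup)) {
    stop(sprintf("line %d: duplicate id %d", keep[which(dup)[1]], nodes$id[which(dup)[1]]),
         call. = FALSE)
  }
  bad <- !(nodes$parent == -1 | nodes$parent %in% nodes$id)
  if (any(bad)) {
    stop(sprintf("line %d: node %d references missing parent %d",
                 keep[which(bad)[1]], nodes$id[which(bad)[1]], nodes$parent[which(bad)[1]]),
         call. = FALSE)
  }
  swc_morphology(nodes, provenance = path)
}

#' Write a morphology as an SWC file
#'
#' @param m An `swc_morphology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(m, path) {
  assert_swc(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  nd <- m$nodes
  if (nrow(nd) > 0L) {
    writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                       nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent), con)
  }
  invisible(path)
}
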