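test_that("volume3d validates shape, range and voxel size", {
  expect_error(volume3d(matrix(0, 2, 2)), "3D array")
  expect_error(volume3d(array(-1, c(2, 2, 2)), dtype = "uint8"), "outside")
  expect_error(volume3d(array(256, c(2, 2, 2)), dtype = "uint8"), "outside")
  expect_error(volume3d(array(0.5, c(2, 2, 2)), dtype = "uint16"), "non-integer")
  expect_error(volume3d(array(0, c(2, 2, 2)), voxel_size = c(1, 0, 1)), "positive")
  v <- volume3d(array(0.5, c(2, 2, 2)), dtype = "float")
  expect_s3_class(v, "volume3d")
  expect_equal(dim(v), c(2L, 2L, 2L))
})

test_that("TIFF stacks round-trip bitwise for 8- and 16-bit volumes", {
  tf <- withr::local_tempfile(fileext = ".tiff")
  set.seed(1)
  v16 <- volume3d(array(sample(0:65535, 4 * 8 * 8, TRUE), c(4, 8, 8)), "uint16")
  write_stack(v16, tf)
  r <- read_stack(tf)
  expect_equal(dim(r), c(4L, 8L, 8L))
  expect_identical(r$dtype, "uint16")
  expect_identical(r$data, v16$data)

  v8 <- volume3d(array(sample(0:255, 3 * 5 * 7, TRUE), c(3, 5, 7)), "uint8")
  write_stack(v8, tf)
  r8 <- read_stack(tf)
  expect_identical(r8$dtype, "uint8")
  expect_identical(r8$data, v8$data)

  # extremes survive quantization in the writer
  vmax <- volume3d(array(65535, c(2, 2, 2)), "uint16")
  write_stack(vmax, tf)
  expect_identical(read_stack(tf)$data, vmax$data)
  vzero <- volume3d(array(0, c(2, 2, 2)), "uint8")
  write_stack(vzero, tf)
  expect_identical(read_stack(tf)$data, vzero$data)
})

test_that("stack I/O rejects unsupported inputs with descriptive errors", {
  tf <- withr::local_tempfile(fileext = ".tiff")
  expect_error(write_stack(volume3d(array(0.5, c(2, 2, 2)), "float"), tf),
               "quantize")
  expect_error(read_stack(file.path(tempdir(), "no-such-file.tiff")),
               "not found")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), tf)  # RGB page
  expect_error(read_stack(tf), "unsupported sample format")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 5, 4)), tf,
                  bits.per.sample = 8)
  expect_error(read_stack(tf), "mixed page shapes")
})

test_that("page index maps to Z: a marker voxel keeps its (z, y, x) address", {
  tf <- withr::local_tempfile(fileext = ".tiff")
  a <- array(0, c(4, 6, 8))
  a[2, 3, 5] <- 200
  write_stack(volume3d(a, "uint8"), tf)
  r <- read_stack(tf)
  expect_equal(which(r$data == 200, arr.ind = TRUE)[1, ], c(dim1 = 2, dim2 = 3, dim3 = 5),
               ignore_attr = TRUE)
  # and the marker sits on page 2 of the file
  pages <- tiff::readTIFF(tf, all = TRUE, as.is = TRUE)
  expect_equal(pages[[2]][3, 5], 200)
  expect_true(all(pages[[1]] == 0))
})

test_that("SWC parsing handles the standard format and reports bad lines", {
  tf <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 2 -1", "2 3 5 0 0 1 1"), tf)
  m <- read_swc(tf)
  expect_equal(nrow(m$nodes), 2L)
  expect_equal(sum(m$nodes$parent == -1), 1L)
  expect_equal(m$nodes$x[2], 5)

  writeLines(c("# only", "# comments"), tf)
  expect_equal(nrow(read_swc(tf)$nodes), 0L)

  writeLines(c("1 1 0 0 0 2 -1", "1 3 5 0 0 1 1"), tf)
  expect_error(read_swc(tf), "line 2.*duplicate id")
  writeLines(c("1 1 0 0 0 2 -1", "2 3 5 0 0 1 9"), tf)
  expect_error(read_swc(tf), "line 2.*missing parent")
  writeLines(c("1 1 0 0 0 2"), tf)
  expect_error(read_swc(tf), "expected 7 columns")
})

test_that("SWC round-trip preserves ids, topology, coordinates and radii", {
  tf <- withr::local_tempfile(fileext = ".swc")
  for (seed in c(3, 17)) {
    m <- random_tree(40, seed)
    write_swc(m, tf)
    r <- read_swc(tf)
    expect_equal(r$nodes$id, m$nodes$id)
    expect_equal(r$nodes$parent, m$nodes$parent)
    expect_equal(r$nodes$x, m$nodes$x, tolerance = 1e-6)
    expect_equal(r$nodes$y, m$nodes$y, tolerance = 1e-6)
    expect_equal(r$nodes$z, m$nodes$z, tolerance = 1e-6)
    expect_equal(r$nodes$radius, m$nodes$radius, tolerance = 1e-6)
  }
})

test_that("morphology constructor rejects inconsistent trees", {
  nd <- data.frame(id = c(1L, 2L), type = 3L, x = 0, y = 0, z = 0,
                   radius = 1, parent = c(2L, 1L))
  expect_error(swc_morphology(nd), "cycle|root")
  nd2 <- data.frame(id = c(1L, 1L), type = 3L, x = 0, y = 0, z = 0,
                    radius = 1, parent = -1L)
  expect_error(swc_morphology(nd2), "duplicate")
})
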