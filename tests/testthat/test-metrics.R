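test_that("a single node rasterizes to a sphere with a shell background", {
  m <- swc_morphology(data.frame(id = 1L, type = 1L, x = 10, y = 10, z = 10,
                                 radius = 3, parent = -1L))
  rm_ <- rasterize_masks(m, c(21, 21, 21), enlargement = 2)
  # brute-force geometry oracle over all voxel centers
  g <- expand.grid(z = 0:20, y = 0:20, x = 0:20)
  d <- sqrt((g$z - 10)^2 + (g$y - 10)^2 + (g$x - 10)^2)
  expect_identical(as.vector(rm_$foreground), d <= 3)
  expect_identical(as.vector(rm_$background), d > 3 & d <= 6)
  # enlargement 1: no background shell
  expect_false(any(rasterize_masks(m, c(21, 21, 21), 1)$background))
})

test_that("a straight segment rasterizes to the brute-force capsule", {
  m <- swc_morphology(data.frame(id = 1:2, type = 3L, x = c(4, 16),
                                 y = c(6, 12), z = c(5, 5), radius = 2.5,
                                 parent = c(-1L, 1L)))
  shape <- c(11, 21, 24)
  fg <- rasterize_masks(m, shape, 2)$foreground
  g <- expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1), x = 0:(shape[3] - 1))
  a <- c(4, 6, 5); b <- c(16, 12, 5)  # (x, y, z)
  v <- b - a
  t <- pmin(pmax(((g$x - a[1]) * v[1] + (g$y - a[2]) * v[2] + (g$z - a[3]) * v[3]) /
                   sum(v^2), 0), 1)
  d <- sqrt((g$x - (a[1] + t * v[1]))^2 + (g$y - (a[2] + t * v[2]))^2 +
              (g$z - (a[3] + t * v[3]))^2)
  expect_identical(as.vector(fg), d <= 2.5)
  expect_equal(sum(fg), sum(d <= 2.5))
})

test_that("mask construction rejects degenerate inputs", {
  far <- swc_morphology(data.frame(id = 1L, type = 1L, x = 500, y = 500,
                                   z = 500, radius = 2, parent = -1L))
  expect_error(rasterize_masks(far, c(10, 10, 10)), "outside")
  expect_error(rasterize_masks(swc_morphology(), c(10, 10, 10)), "empty")
})

test_that("SBC follows median(fg) / (median(bg) + 1)", {
  expect_equal(sbc(rep(100, 5), rep(4, 9)), 20)
  expect_equal(sbc(rep(7, 3), rep(7, 3)), 7 / 8)
  expect_equal(sbc(c(50, 60, 70), rep(0, 10)), 60)  # zero-division guard
  expect_error(sbc(numeric(0), 1), "foreground")
  expect_error(sbc(1, numeric(0)), "background")
})

test_that("background uniformity: point masses, two bins, histogram oracle", {
  whole <- c(rep(5, 50), rep(9, 50))
  expect_equal(background_uniformity(rep(5, 30), whole), 1)
  # two equally-filled point masses -> 0.25 + 0.25
  expect_equal(background_uniformity(c(rep(5, 20), rep(9, 20)), whole), 0.5)
  set.seed(51)
  img <- rnorm(1e5, 100, 20)
  bg <- img[1:4e4]
  expect_equal(background_uniformity(bg, img),
               oracle_uniformity(bg, img), tolerance = 1e-6)
  expect_error(background_uniformity(rep(1, 5), rep(3, 10)), "zero variance")
})

test_that("foreground RSD uses population sd over median + 1", {
  expect_equal(foreground_rsd(rep(42, 10)), 0)
  expect_equal(foreground_rsd(c(0, 10)), 5 / 6)
  set.seed(52)
  x <- runif(2e5, 0, 200)  # sd = 200/sqrt(12), median = 100
  expect_equal(foreground_rsd(x), (200 / sqrt(12)) / 101, tolerance = 0.01)
})

test_that("quality report composes the metrics with voxel counts", {
  m <- swc_morphology(data.frame(id = 1L, type = 1L, x = 10, y = 10, z = 10,
                                 radius = 3, parent = -1L))
  d <- array(4, c(21, 21, 21))
  g <- expand.grid(z = 0:20, y = 0:20, x = 0:20)
  dist <- sqrt((g$z - 10)^2 + (g$y - 10)^2 + (g$x - 10)^2)
  d[dist <= 3] <- 100
  qr <- quality_report(volume3d(d, "float"), m)
  expect_equal(qr$sbc, 20)
  expect_equal(qr$fg_rsd, 0)
  expect_equal(qr$bg_uniformity, 1)
  expect_equal(qr$n_fg_voxels, sum(dist <= 3))
  expect_equal(qr$n_bg_voxels, sum(dist > 3 & dist <= 6))
})

test_that("uniformity is invariant to a global intensity shift", {
  set.seed(53)
  img <- array(runif(10 * 12 * 12, 0, 500), c(10, 12, 12))
  bgmask <- array(runif(length(img)) < 0.3, dim(img))
  u1 <- background_uniformity(img[bgmask], img)
  u2 <- background_uniformity(img[bgmask] + 77, img + 77)
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("SBC strictly increases when foreground is amplified over background", {
  set.seed(54)
  fg <- runif(100, 50, 150)
  bg <- runif(300, 0, 30)
  expect_gt(sbc(fg * 2, bg), sbc(fg, bg))
})
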