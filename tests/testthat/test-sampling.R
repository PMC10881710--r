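axial_plane <- function(z, extent = c(20, 20), px = 1, thick = 6) {
  plane_geometry(c(0, 0, z), u = c(1, 0, 0), v = c(0, 1, 0), extent = extent,
                 pixel_spacing = px, thickness = thick, id = "ax")
}

test_that("slab sampling a constant volume returns that constant", {
  vol <- array(42, c(40, 40, 40))
  aff <- centered_affine_pub(c(40, 40, 40), 1)
  img <- sample_slab(vol, axial_plane(0), affine = aff)
  expect_true(all(abs(img - 42) < 1e-12))
})

test_that("slab mean of a linear field equals the centre-plane value", {
  aff <- centered_affine_pub(c(40, 40, 40), 1)
  zc <- ((1:40) - 1) + aff[3, 4]
  vol <- array(rep(zc, each = 1600), c(40, 40, 40))   # f(x, y, z) = z
  for (c0 in c(0, 2.5, -4)) {
    img <- sample_slab(vol, axial_plane(c0, thick = 6), n_sublayers = 5,
                       affine = aff)
    expect_true(all(abs(img - c0) < 1e-9))
  }
})

test_that("a single sublayer equals plain trilinear resampling", {
  set.seed(12)
  vol <- array(rnorm(27000), c(30, 30, 30))
  aff <- centered_affine_pub(c(30, 30, 30), 1)
  pl <- axial_plane(1.3, extent = c(10, 10), px = 0.8)
  img1 <- sample_slab(vol, pl, n_sublayers = 1, affine = aff)
  grid <- mvphantom:::plane_pixel_grid(pl)
  pts <- cbind(rep(grid$us, times = length(grid$vs)),
               rep(grid$vs, each = length(grid$us)), 1.3)
  direct <- sample_volume(vol, aff, pts)
  expect_equal(as.vector(img1), direct, tolerance = 1e-12)
  expect_error(sample_slab(vol, pl, n_sublayers = 2, affine = aff), "odd")
})

test_that("out-of-volume pixels fall back to the fill value with a warning", {
  vol <- array(5, c(10, 10, 10))
  aff <- centered_affine_pub(c(10, 10, 10), 1)
  expect_warning(img <- sample_slab(vol, axial_plane(0, extent = c(60, 60)),
                                    fill = -1, affine = aff),
                 "outside")
  expect_true(any(img == -1))
})

test_that("two-step in-plane resampling preserves constants exactly", {
  img <- matrix(3.7, 64, 64)
  out <- resample_inplane(img, from_spacing = 0.7)
  expect_true(all(abs(out - 3.7) < 1e-12))
  expect_equal(attr(out, "pixel_spacing"), 0.87)
})

test_that("equal spacings make resampling the identity", {
  set.seed(3)
  img <- matrix(rnorm(400), 20, 20)
  out <- resample_inplane(img, 1.4, 1.4, 1.4)
  expect_equal(unclass(out)[, ], img, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("box-averaging to acquisition resolution reduces variance", {
  n <- 80
  cb <- outer(1:n, 1:n, function(i, j) (-1)^(i + j))  # 0.5 mm checkerboard
  acq <- mvphantom:::resample_image(cb, 0.5, 1.4, "box")
  expect_lt(var(as.vector(acq)), var(as.vector(cb)))
})

test_that("geometry metadata tracks the resampling chain", {
  img <- matrix(rnorm(3600), 60, 60)
  out <- resample_inplane(img, 0.7, 1.4, 0.87)
  expect_equal(attr(out, "pixel_spacing"), 0.87)
  # 42 mm field of view: 30 acquired pixels, back up to ~48 reconstructed.
  expect_equal(nrow(out), round(30 * 1.4 / 0.87))
})
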