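test_that("zero-sd model gives an exactly piecewise-constant volume", {
  vol <- two_label_volume(10L)
  tab <- default_intensity_table()
  tab$sd <- 0
  out <- assign_intensities(vol, intensity_model(tab))
  expect_true(all(out$data[vol$labels == 1L] == 266))
  expect_true(all(out$data[vol$labels == 3L] == 357))
})

test_that("sampled intensities reproduce the model mean and sd", {
  vol <- two_label_volume(24L)   # 13824 voxels per block
  out <- assign_intensities(vol, seed = 4711L)
  for (ent in c("mitral_valve", "la_cavity")) {
    row <- default_intensity_table()
    row <- row[row$entity == ent, ]
    x <- out$data[vol$labels == default_label_map()[[ent]]]
    expect_lt(abs(mean(x) - row$mean), 3 * row$sd / sqrt(length(x)))
    expect_lt(abs(sd(x) - row$sd) / row$sd, 0.05)
  }
})

test_that("labels without a model entry are reported by name", {
  vol <- two_label_volume(4L, c("mitral_valve", "liver"))
  tab <- default_intensity_table()
  tab <- tab[tab$entity != "liver", ]
  expect_error(assign_intensities(vol, intensity_model(tab)), "liver")
})

test_that("additive noise has the configured statistics", {
  x <- array(100, c(50, 50, 40))
  expect_identical(add_noise(x, 0), x)
  y <- add_noise(x, 38, seed = 99L)
  eps <- y - x
  expect_lt(abs(sd(eps) - 38) / 38, 0.01)
  expect_lt(abs(mean(eps)), 3 * 38 / sqrt(length(eps)))
  expect_error(add_noise(x, -1), "parameter error")
})

test_that("smoothing is the identity for zero kernels and constants", {
  x <- array(rnorm(8000), c(20, 20, 20))
  expect_identical(smooth_volume(x, 0), x)
  const <- array(7, c(15, 15, 15))
  expect_equal(smooth_volume(const, 1.2, spacing = 1), const, tolerance = 1e-12)
})

test_that("smoothing reduces white-noise sd by the kernel-weight factor", {
  set.seed(31L)
  n <- 48L
  x <- array(rnorm(n^3, 0, 38), rep(n, 3L))
  y <- smooth_volume(x, 0.8, spacing = 1)
  # Oracle: sd scales by (sum of squared 1D kernel weights)^(3/2).
  K <- mvphantom:::gaussian_operator(n, 0.8)
  w2 <- sum(K[n / 2, ]^2)
  inner <- y[6:(n - 5), 6:(n - 5), 6:(n - 5)]
  expect_lt(sd(inner), 38)
  expect_lt(abs(sd(inner) - 38 * w2^(3 / 2)) / (38 * w2^(3 / 2)), 0.05)
})

test_that("intensity model round-trips through CSV and JSON", {
  m <- intensity_model()
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    write_intensity_model(m, f)
    m2 <- read_intensity_model(f)
    expect_equal(m2$table$mean, m$table$mean)
    expect_equal(m2$table$sd, m$table$sd)
    expect_equal(m2$table$entity, m$table$entity)
  }
})
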