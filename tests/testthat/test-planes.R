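test_that("valve axis of a flat mesh is the plane normal", {
  set.seed(5)
  pts <- cbind(runif(200, -20, 20), runif(200, -15, 15), 5)
  va <- compute_valve_axis(pts, atrial_ref = c(0, 0, 50))
  expect_equal(abs(va$axis), c(0, 0, 1), tolerance = 1e-9)
  expect_gt(va$axis[3L], 0)             # oriented towards the atrial side
  expect_equal(va$center[3L], 5, tolerance = 1e-9)
})

test_that("valve axis co-rotates with the mesh", {
  set.seed(6)
  pts <- cbind(runif(300, -20, 20), runif(300, -15, 15), 0)
  R <- random_rotation(7)
  va <- compute_valve_axis(pts %*% t(R), atrial_ref = drop(R %*% c(0, 0, 50)))
  expect_lt(min(max(abs(va$axis - drop(R %*% c(0, 0, 1)))),
                max(abs(va$axis + drop(R %*% c(0, 0, 1))))), 1e-9)
})

test_that("saddle valve axis is close to the construction axis", {
  mesh <- generate_valve_mesh()
  va <- compute_valve_axis(mesh)
  ang <- acos(min(1, abs(sum(va$axis * mesh$frame[, 3L])))) * 180 / pi
  expect_lt(ang, 2)
  expect_gt(sum(va$axis * mesh$frame[, 3L]), 0)  # atrial orientation
})

test_that("collinear vertices are rejected", {
  pts <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(compute_valve_axis(pts), "degenerate|collinear")
})

test_that("SAX stack geometry: spacing, centring, orthonormality", {
  axis <- c(0, 0, 1)
  pls <- define_sax_planes(axis, c(1, 2, 3), n_slices = 5L, spacing_mm = 6)
  expect_length(pls, 5L)
  centres <- t(vapply(pls, function(p) p$origin, numeric(3)))
  gaps <- sqrt(rowSums(diff(centres)^2))
  expect_equal(gaps, rep(6, 4), tolerance = 1e-12)
  expect_equal(colMeans(centres), c(1, 2, 3), tolerance = 1e-12)
  for (p in pls) {
    expect_equal(p$normal, axis, tolerance = 1e-12)
    expect_lt(abs(sum(p$normal * p$u)), 1e-12)
    expect_lt(abs(sum(p$normal * p$v)), 1e-12)
    expect_equal(mvphantom:::cross3(p$u, p$v), p$normal, tolerance = 1e-12)
  }
  single <- define_sax_planes(axis, c(0, 0, 0), n_slices = 1L)
  expect_equal(single[[1L]]$origin, c(0, 0, 0))
})

test_that("rLAX planes share the axis and rotate by 180/n degrees", {
  axis <- mvphantom:::unit3(c(0.2, -0.1, 1))
  ctr <- c(5, -3, 2)
  for (n in c(6L, 9L, 18L)) {
    pls <- define_rlax_planes(axis, ctr, n_planes = n)
    expect_length(pls, n)
    for (p in pls) {
      expect_lt(abs(sum(p$normal * axis)), 1e-12)      # axis in-plane
      expect_lt(abs(sum((ctr - p$origin) * p$normal)), 1e-12)
    }
    inc <- acos(abs(sum(pls[[1L]]$normal * pls[[2L]]$normal))) * 180 / pi
    expect_equal(inc, 180 / n, tolerance = 1e-9)
  }
  expect_length(define_rlax_planes(axis, ctr, n_planes = 1L), 1L)
})

test_that("plane constructor validates its frame", {
  expect_error(plane_geometry(c(0, 0, 0), u = c(1, 0, 0), v = c(0, 1, 0),
                              normal = c(0, 0, -1)), "right-handed")
  expect_error(plane_geometry(c(0, 0, 0), u = c(1, 0, 0), v = c(0, 1, 0),
                              thickness = 0), "thickness")
})
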