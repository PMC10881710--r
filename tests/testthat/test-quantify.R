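test_that("PCA parameters of canonical annuli match closed forms", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circle <- cbind(15 * cos(th), 15 * sin(th), 0)
  p <- annulus_pca_params(circle)
  expect_equal(p$d_max, 30, tolerance = 1e-9)
  expect_equal(p$d_min, 30, tolerance = 1e-9)
  expect_equal(p$height, 0, tolerance = 1e-9)
})

test_that("saddle annulus PCA matches the dense numeric oracle", {
  pts <- generate_annulus(annulus_model(radii = c(20, 15), saddle_height = 3),
                          n_samples = 360L)
  p <- annulus_pca_params(pts)
  # Construction values.
  expect_equal(p$d_max, 40, tolerance = 1e-3)
  expect_equal(p$d_min, 30, tolerance = 1e-3)
  expect_equal(p$height, 6, tolerance = 1e-3)
  # Independent oracle: svd of densely sampled centred points.
  dense <- generate_annulus(annulus_model(radii = c(20, 15), saddle_height = 3),
                            n_samples = 1e5)
  X <- sweep(dense, 2L, colMeans(dense))
  axes <- svd(X, nu = 0)$v
  ext <- apply(X %*% axes, 2L, function(x) max(x) - min(x))
  expect_equal(p$d_max, ext[1L], tolerance = 1e-4)
  expect_equal(p$d_min, ext[2L], tolerance = 1e-4)
  expect_equal(p$height, ext[3L], tolerance = 1e-4)
})

test_that("PCA parameters are invariant under rigid motion", {
  pts <- generate_annulus(annulus_model(), n_samples = 200L)
  p0 <- annulus_pca_params(pts)
  R <- random_rotation(9)
  p1 <- annulus_pca_params(sweep(pts %*% t(R), 2L, c(12, -7, 30), "+"))
  expect_equal(p1$d_max, p0$d_max, tolerance = 1e-9)
  expect_equal(p1$d_min, p0$d_min, tolerance = 1e-9)
  expect_equal(p1$height, p0$height, tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  expect_error(annulus_pca_params(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "geometry error")
  line <- cbind(1:10, 1:10, 1:10)
  expect_error(annulus_pca_params(line), "geometry error")
})

test_that("projected areas match closed forms", {
  th <- seq(0, 2 * pi, length.out = 3601)[-3601]
  circle <- cbind(10 * cos(th), 10 * sin(th), 0)
  frame <- list(center = c(0, 0, 0), axes = diag(3))
  expect_equal(projected_area(circle, frame, ordered = TRUE), pi * 100,
               tolerance = 1e-3 * pi * 100)
  saddle <- generate_annulus(annulus_model(radii = c(20, 15),
                                           saddle_height = 3),
                             n_samples = 3600L)
  pca <- annulus_pca_params(saddle)
  expect_equal(projected_area(saddle, pca$frame, ordered = TRUE), pi * 300,
               tolerance = 0.005 * pi * 300)
  expect_error(projected_area(circle[1:2, ], frame), "geometry error")
})

test_that("unordered points are sorted by angle before the shoelace", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(8 * cos(th), 8 * sin(th), 0)
  shuffled <- circle[sample(nrow(circle)), ]
  frame <- list(center = c(0, 0, 0), axes = diag(3))
  expect_equal(projected_area(shuffled, frame), pi * 64,
               tolerance = 1e-3 * pi * 64)
})

test_that("ground-truth quantification matches the construction", {
  mesh <- generate_valve_mesh()
  qp <- quantify_valve(mesh)
  expect_equal(qp$d_max, 40, tolerance = 0.01 * 40)
  expect_equal(qp$d_min, 30, tolerance = 0.01 * 30)
  expect_equal(qp$height, 6, tolerance = 0.01 * 6)
  expect_equal(qp$annulus_area, pi * 300, tolerance = 0.01 * pi * 300)
  # Orifice oracle: shoelace of the projected free-edge loop.
  ori <- mesh_orifice_curve(mesh)
  expect_equal(qp$orifice_area,
               mvphantom:::polygon_shoelace_area(ori[, 1:2]),
               tolerance = 0.01 * qp$orifice_area)
})

test_that("exact rLAX18 annotations recover the parameters within 2%", {
  mesh <- generate_valve_mesh()
  va <- compute_valve_axis(mesh)
  planes <- define_rlax_planes(va$axis, va$center, n_planes = 18L)
  ann <- simulate_annotators(mesh, planes, noise_sigma_mm = 0, seed = 1L,
                             n_annotators = 1L)
  qp <- quantify_valve(ann, annotator = 1L)
  gt <- quantify_valve(mesh)
  for (p in c("d_max", "d_min", "height", "annulus_area", "orifice_area")) {
    expect_lt(abs(qp[[p]] - gt[[p]]) / gt[[p]], 0.02)
  }
})

test_that("single-plane annotations are insufficient for quantification", {
  mesh <- generate_valve_mesh(target_face_area = 2)
  va <- compute_valve_axis(mesh)
  planes <- define_rlax_planes(va$axis, va$center, n_planes = 6L)[1L]
  ann <- simulate_annotators(mesh, planes, noise_sigma_mm = 0, seed = 1L,
                             n_annotators = 1L)
  expect_error(quantify_valve(ann, annotator = 1L), "insufficient annotation")
})

test_that("bias is the mean signed difference", {
  expect_equal(param_bias(c(5, 5, 5), 5), 0)
  expect_equal(param_bias(5 + c(1, 2, 3), 5), 2)
  set.seed(8)
  v <- rnorm(7)
  expect_equal(param_bias(v, 1.3), sum(v - 1.3) / 7, tolerance = 1e-12)
  expect_error(param_bias(numeric(0), 1), "at least one")
})

test_that("contour distances agree with the brute-force oracle", {
  set.seed(21)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  coarse <- cbind(10 * cos(th), 10 * sin(th), sin(2 * th))
  pts <- cbind(runif(200, -12, 12), runif(200, -12, 12), runif(200, -2, 2))
  rep <- contour_distance(pts, coarse, closed = TRUE)
  oracle <- oracle_points_to_contour(pts, coarse, closed = TRUE)
  expect_equal(rep$distances, oracle, tolerance = 1e-9)
})

test_that("contour distance handles the radial-offset and subset cases", {
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  inner <- cbind(10 * cos(th), 10 * sin(th), 0)
  outer <- cbind(12 * cos(th[seq(1, 2000, 40)]), 12 * sin(th[seq(1, 2000, 40)]), 0)
  rep <- contour_distance(outer, inner)
  expect_true(all(abs(rep$distances - 2) < 0.01))
  sub <- contour_distance(inner[c(3, 100, 500), ], inner)
  expect_true(all(sub$distances < 1e-12))
  expect_error(contour_distance(matrix(numeric(0), 0, 3), inner), "no annotated")
})

test_that("point-to-surface distances agree with the exhaustive oracle", {
  mesh <- generate_valve_mesh(target_face_area = 6)  # few hundred faces
  set.seed(14)
  pts <- cbind(runif(100, -25, 25), runif(100, -20, 20), runif(100, -25, 8))
  rep <- point_to_surface_distance(pts, mesh)
  oracle <- oracle_points_to_mesh(pts, mesh$vertices, mesh$faces)
  expect_equal(rep$distances, oracle, tolerance = 1e-9)
  # Closed-form cases.
  expect_lt(point_to_surface_distance(mesh$vertices[5, , drop = FALSE],
                                      mesh)$distances, 1e-12)
  sq <- flat_square_mesh(20)
  above <- point_to_surface_distance(rbind(c(1, 2, 2)), sq)
  expect_equal(above$distances, 2, tolerance = 1e-12)
  expect_error(point_to_surface_distance(pts,
                                         list(vertices = sq$vertices,
                                              faces = matrix(integer(0), 0, 3))),
               "empty mesh")
})

test_that("distance reports have consistent order statistics and outliers", {
  d <- c(rep(1, 20), 1.2, 0.8, 10)
  rep <- mvphantom:::distance_report(d)
  s <- rep$summary
  expect_true(all(diff(s[c("min", "p25", "p50", "p75", "max")]) >= 0))
  expect_equal(s[["mean"]], mean(d))
  expect_equal(s[["sd"]], sd(d))
  expect_true(10 %in% rep$outliers)
})

test_that("quantification is invariant under rigid motion of the phantom", {
  mesh <- generate_valve_mesh(target_face_area = 2)
  qp0 <- quantify_valve(mesh)
  R <- random_rotation(17)
  moved <- mvphantom:::transform_valve_mesh(mesh, R, c(30, -12, 4))
  qp1 <- quantify_valve(moved)
  for (p in c("d_max", "d_min", "height", "annulus_area", "orifice_area")) {
    expect_lt(abs(qp1[[p]] - qp0[[p]]) / abs(qp0[[p]]), 1e-6)
  }
})

test_that("parameter recovery converges with plane count and low noise", {
  mesh <- generate_valve_mesh(target_face_area = 2)
  va <- compute_valve_axis(mesh)
  gt <- quantify_valve(mesh)
  err <- function(n, sigma) {
    planes <- define_rlax_planes(va$axis, va$center, n_planes = n)
    ann <- simulate_annotators(mesh, planes, noise_sigma_mm = sigma,
                               seed = 1234L, n_annotators = 1L)
    qp <- quantify_valve(ann, annotator = 1L)
    max(vapply(c("d_max", "d_min", "height", "annulus_area"),
               function(p) abs(qp[[p]] - gt[[p]]) / abs(gt[[p]]), 0))
  }
  e0 <- vapply(c(6L, 9L, 18L, 36L), err, 0, sigma = 0)
  expect_lt(e0[4L], 0.02)               # dense planes, no noise: near exact
  expect_lt(e0[4L], e0[1L] + 1e-9)      # error shrinks with plane count
  expect_gt(err(9L, 1.5), e0[2L])       # noise worsens recovery
})
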