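mesh_a <- generate_valve_mesh(target_face_area = 2)  # coarse, fast
va_a <- compute_valve_axis(mesh_a)

radial_plane <- function(phi = 0) {
  define_rlax_planes(va_a$axis, va_a$center, n_planes = 18L)[[round(phi / 10) + 1L]]
}

test_that("a radial plane section has exactly two annulus endpoints", {
  comps <- intersect_valve_plane(mesh_a, radial_plane(30))
  tags <- unlist(lapply(comps, `[[`, "end_tags"))
  expect_equal(sum(tags == "annulus"), 2L)
  expect_equal(sum(tags == "orifice"), 2L)
})

test_that("planes far from the mesh give an empty section", {
  far <- plane_geometry(c(0, 0, 500), u = c(1, 0, 0), v = c(0, 1, 0))
  expect_length(intersect_valve_plane(mesh_a, far), 0L)
})

test_that("section length matches a per-triangle clipping oracle", {
  for (pl in list(radial_plane(0), radial_plane(50),
                  define_sax_planes(va_a$axis, va_a$center, 1L)[[1L]])) {
    comps <- intersect_valve_plane(mesh_a, pl)
    total <- sum(vapply(comps, function(cmp) {
      sum(sqrt(rowSums(diff(cmp$points)^2))) +
        if (cmp$closed) sqrt(sum((cmp$points[1L, ] -
                                    cmp$points[nrow(cmp$points), ])^2)) else 0
    }, 0))
    # Oracle: clip each triangle against the plane independently.
    o <- pl$origin
    n <- pl$normal
    s <- drop(sweep(mesh_a$vertices, 2L, o) %*% n)
    s[s == 0] <- 1e-12
    oracle <- 0
    for (f in seq_len(nrow(mesh_a$faces))) {
      vid <- mesh_a$faces[f, ]
      pts <- NULL
      for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
        i <- vid[e[1]]; j <- vid[e[2]]
        if (s[i] * s[j] < 0) {
          t <- s[i] / (s[i] - s[j])
          pts <- rbind(pts, mesh_a$vertices[i, ] +
                         t * (mesh_a$vertices[j, ] - mesh_a$vertices[i, ]))
        }
      }
      if (!is.null(pts) && nrow(pts) == 2L) {
        oracle <- oracle + sqrt(sum((pts[1L, ] - pts[2L, ])^2))
      }
    }
    expect_equal(total, oracle, tolerance = 1e-9)
  }
})

test_that("noise-free annotators reproduce the ground-truth intersections", {
  planes <- define_rlax_planes(va_a$axis, va_a$center, n_planes = 6L)
  ann <- simulate_annotators(mesh_a, planes, noise_sigma_mm = 0, seed = 1L,
                             n_annotators = 2L)
  gt <- mvphantom:::annotation_ground_truth(mesh_a, planes)
  for (a in 1:2) {
    da <- ann[ann$annotator == a, ]
    expect_equal(da[, c("x", "y", "z")], gt[, c("x", "y", "z")],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # End-to-end identity: downstream distances are all zero.
  d <- point_to_surface_distance(as.matrix(ann[, c("x", "y", "z")]), mesh_a)
  expect_lt(max(d$distances), 1e-9)
})

test_that("mean click displacement follows the Rayleigh law", {
  planes <- define_rlax_planes(va_a$axis, va_a$center, n_planes = 18L)
  sigma <- 1.5
  ann <- simulate_annotators(mesh_a, planes, noise_sigma_mm = sigma,
                             seed = 33L, n_annotators = 3L)
  gt <- mvphantom:::annotation_ground_truth(mesh_a, planes)
  disp <- unlist(lapply(1:3, function(a) {
    da <- ann[ann$annotator == a, ]
    sqrt(rowSums((as.matrix(da[, c("x", "y", "z")]) -
                    as.matrix(gt[, c("x", "y", "z")]))^2))
  }))
  expect_gt(length(disp), 1000L)
  expect_lt(abs(mean(disp) - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)),
            0.1)
})

test_that("every annotated point lies on its plane", {
  planes <- define_rlax_planes(va_a$axis, va_a$center, n_planes = 6L)
  ann <- simulate_annotators(mesh_a, planes, noise_sigma_mm = 2, seed = 2L)
  for (pl in planes) {
    da <- ann[ann$plane_id == pl$id, ]
    d <- abs(drop(sweep(as.matrix(da[, c("x", "y", "z")]), 2L, pl$origin)
                  %*% pl$normal))
    expect_true(all(d <= pl$thickness / 2 + 1e-9))
  }
})

test_that("detection misses thin out landmarks and full miss is an error", {
  planes <- define_rlax_planes(va_a$axis, va_a$center, n_planes = 18L)
  full <- simulate_annotators(mesh_a, planes, noise_sigma_mm = 0, seed = 1L,
                              n_annotators = 1L)
  some <- simulate_annotators(mesh_a, planes, noise_sigma_mm = 0,
                              detection_miss_rate = 0.5, seed = 1L,
                              n_annotators = 1L)
  expect_lt(sum(some$structure == "annulus"), sum(full$structure == "annulus"))
  expect_equal(sum(some$structure == "leaflet"), sum(full$structure == "leaflet"))
  expect_error(simulate_annotators(mesh_a, planes, detection_miss_rate = 1),
               "no annotatable points")
})

test_that("contour error grows monotonically with annotator noise", {
  planes <- define_rlax_planes(va_a$axis, va_a$center, n_planes = 9L)
  gt_curve <- generate_annulus(mesh_a$annulus, 2000L)
  means <- vapply(c(0, 0.5, 1, 1.5), function(sig) {
    ann <- simulate_annotators(mesh_a, planes, noise_sigma_mm = sig,
                               seed = 77L, n_annotators = 3L)
    p <- ann[ann$structure == "annulus", ]
    contour_distance(as.matrix(p[, c("x", "y", "z")]), gt_curve)$summary["mean"]
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("annotations round-trip through JSON and CSV", {
  planes <- define_rlax_planes(va_a$axis, va_a$center, n_planes = 6L)
  ann <- simulate_annotators(mesh_a, planes, seed = 5L, n_annotators = 1L)
  for (ext in c(".json", ".csv")) {
    f <- tempfile(fileext = ext)
    write_annotations(ann, f)
    back <- read_annotations(f)
    expect_equal(back$x, ann$x, tolerance = 1e-9)
    expect_equal(back$structure, ann$structure)
  }
})
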