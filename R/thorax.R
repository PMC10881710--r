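#' Canonical label map for the phantom anatomy
#'
#' Integer codes for every entity of the tissue intensity table plus the
#' valve.  The same names key the default intensity model.
#' @return named integer vector.
#' @export
default_label_map <- function() {
  c(mitral_valve = 1L, la_wall = 2L, la_cavity = 3L, lv_myocardium = 4L,
    lv_cavity = 5L, ra_wall = 6L, ra_cavity = 7L, rv_wall = 8L,
    rv_cavity = 9L, aorta = 10L, bones = 11L, liver = 12L, kidney = 13L,
    lung = 14L, bronchi = 15L)
}

#' Generate the parametric labelled thorax/heart volume
#'
#' Builds a cartoon thorax from ellipsoid and tube primitives: lungs, bronchi,
#' rib arcs and spine, liver, kidney, aorta, and the four heart chambers
#' (walls and blood-pool cavities).  The model lives in a heart-centred
#' coordinate system with the mitral valve orifice at the origin and the
#' atrial direction along +z; the valve itself is burnt in separately with
#' [rasterize_surface()].  Shapes are deliberately schematic: the purpose is
#' a fully known ground truth with the right label inventory and approximate
#' dimensions, not patient-realistic anatomy.
#'
#' @param config list with optional elements `shape` (grid size, default
#'   `c(110, 110, 110)`), `spacing` (voxel size mm, default 2) and `include`
#'   (character vector of entity names; default all entities).
#' @return a [label_volume()] whose `label_map` is [default_label_map()].
#' @export
generate_thorax <- function(config = list()) {
  known <- c("shape", "spacing", "include")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  shape <- as.integer(config$shape %||% c(110L, 110L, 110L))
  spacing <- config$spacing %||% 2
  lm <- default_label_map()
  include <- config$include %||% setdiff(names(lm), "mitral_valve")
  unknown <- setdiff(include, names(lm))
  if (length(unknown) > 0L) {
    stop("unknown entity name(s): ", paste(unknown, collapse = ", "))
  }

  affine <- centered_affine(shape, spacing)
  labels <- array(0L, shape)
  sp <- rep(spacing, length.out = 3L)
  xs <- (seq_len(shape[1L]) - 1) * sp[1L] + affine[1L, 4L]
  ys <- (seq_len(shape[2L]) - 1) * sp[2L] + affine[2L, 4L]
  zs <- (seq_len(shape[3L]) - 1) * sp[3L] + affine[3L, 4L]
  axes <- list(xs, ys, zs)

  paint <- function(entity, fn) {
    if (entity %in% include) labels <<- fn(labels, lm[[entity]])
  }

  ell <- function(center, semi) {
    function(lab, value) paint_ellipsoid(lab, axes, center, semi, value)
  }
  tube <- function(path, radius) {
    function(lab, value) paint_tube(lab, axes, path, radius, value)
  }

  # Painted back-to-front: later entities overwrite earlier ones, so walls
  # are painted as full ellipsoids and hollowed by their cavities.
  paint("lung", ell(c(-70, 5, 0), c(38, 70, 95)))
  paint("lung", ell(c(70, 25, 0), c(38, 70, 95)))
  paint("bronchi", tube(rbind(c(0, 20, 75), c(0, 20, 50), c(-40, 12, 25)), 7))
  paint("bronchi", tube(rbind(c(0, 20, 50), c(40, 18, 25)), 7))
  paint("bones", tube(rbind(c(0, 92, 90), c(0, 92, -90)), 12))  # spine
  for (zr in seq(-70, 70, by = 28)) {                            # rib arcs
    ang <- seq(-60, 240, length.out = 24L) * pi / 180
    arc <- cbind(98 * cos(ang), 60 * sin(ang) + 30, zr + 8 * sin(ang / 3))
    paint("bones", tube(arc, 5))
  }
  paint("liver", ell(c(40, 45, -80), c(55, 45, 35)))
  paint("kidney", ell(c(62, 62, -102), c(20, 16, 28)))
  paint("aorta", tube(aorta_centerline(), 11))
  paint("ra_wall", ell(c(55, 10, 20), c(26, 24, 21)))
  paint("ra_cavity", ell(c(55, 10, 20), c(23, 21, 18)))
  paint("rv_wall", ell(c(50, 5, -25), c(28, 26, 36)))
  paint("rv_cavity", ell(c(50, 5, -25), c(23, 21, 30)))
  paint("la_wall", ell(c(0, 0, 21), c(29, 27, 24)))
  paint("la_cavity", ell(c(0, 0, 20), c(26, 24, 21)))
  paint("lv_myocardium", ell(c(0, 0, -28), c(35, 33, 42)))
  paint("lv_cavity", ell(c(0, 0, -28), c(27, 25, 34)))

  label_volume(labels, affine, lm)
}

aorta_centerline <- function() {
  rbind(c(8, -10, -5), c(14, -12, 15), c(16, -10, 40), c(8, 0, 58),
        c(-6, 6, 60), c(-16, 10, 45), c(-20, 12, 20), c(-22, 14, -20),
        c(-22, 14, -60))
}

#' Default anatomical landmarks of the phantom (model space)
#'
#' Ten landmarks: the four valve centres, the apex, the septum centre and
#' four aorta-centreline markers.
#' @return a [landmark_set()].
#' @export
thorax_landmarks <- function() {
  cl <- aorta_centerline()
  landmark_set(rbind(
    mitral_center = c(0, 0, 0),
    aortic_center = c(12, -10, 5),
    tricuspid_center = c(52, 8, 0),
    pulmonary_center = c(40, -5, 15),
    apex = c(0, 0, -70),
    septum_center = c(25, 0, -25),
    aorta_1 = cl[2L, ], aorta_2 = cl[4L, ],
    aorta_3 = cl[6L, ], aorta_4 = cl[8L, ]),
    c("mitral_center", "aortic_center", "tricuspid_center", "pulmonary_center",
      "apex", "septum_center", "aorta_1", "aorta_2", "aorta_3", "aorta_4"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Paint an axis-aligned ellipsoid into a label array (bbox-limited).
paint_ellipsoid <- function(labels, axes, center, semi, value) {
  rng <- vector("list", 3L)
  for (d in 1:3) {
    rng[[d]] <- which(axes[[d]] >= center[d] - semi[d] &
                        axes[[d]] <= center[d] + semi[d])
    if (length(rng[[d]]) == 0L) return(labels)
  }
  u1 <- ((axes[[1L]][rng[[1L]]] - center[1L]) / semi[1L])^2
  u2 <- ((axes[[2L]][rng[[2L]]] - center[2L]) / semi[2L])^2
  u3 <- ((axes[[3L]][rng[[3L]]] - center[3L]) / semi[3L])^2
  mask <- outer(outer(u1, u2, "+"), u3, "+") <= 1
  sub <- labels[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
  sub[mask] <- as.integer(value)
  labels[rng[[1L]], rng[[2L]], rng[[3L]]] <- sub
  labels
}

# Sphere-swept polyline tube.
paint_tube <- function(labels, axes, path, radius, value) {
  path <- as_points_matrix(path)
  pts <- path[1L, , drop = FALSE]
  for (i in seq_len(nrow(path) - 1L)) {
    seg <- path[i + 1L, ] - path[i, ]
    len <- vnorm(seg)
    n <- max(1L, ceiling(len / (radius / 2)))
    tt <- seq_len(n) / n
    pts <- rbind(pts, matrix(path[i, ], n, 3L, byrow = TRUE) + outer(tt, seg))
  }
  for (i in seq_len(nrow(pts))) {
    labels <- paint_ellipsoid(labels, axes, pts[i, ], rep(radius, 3L), value)
  }
  labels
}
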