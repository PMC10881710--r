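#' Oriented imaging plane / slab
#'
#' @param origin plane centre, world mm.
#' @param u,v orthonormal in-plane axes; `{u, v, normal}` right-handed.
#' @param normal unit plane normal (computed as `u x v` when omitted).
#' @param extent in-plane field of view `(width, height)` mm.
#' @param pixel_spacing in-plane sampling distance, mm.
#' @param thickness slab thickness, mm.
#' @param strategy optional tag (`"SAX"`, `"rLAX6"`, ...).
#' @param id optional plane identifier.
#' @return object of class `plane_geometry`.
#' @export
plane_geometry <- function(origin, u, v, normal = NULL, extent = c(100, 100),
                           pixel_spacing = 0.7, thickness = 6,
                           strategy = NULL, id = NULL) {
  u <- unit3(as.numeric(u))
  v <- as.numeric(v)
  v <- unit3(v - sum(v * u) * u)
  n <- if (is.null(normal)) cross3(u, v) else unit3(as.numeric(normal))
  if (abs(sum(cross3(u, v) * n) - 1) > 1e-8) {
    stop("{u, v, normal} must be right-handed orthonormal")
  }
  if (thickness <= 0 || pixel_spacing <= 0) {
    stop("thickness and pixel_spacing must be > 0")
  }
  structure(list(origin = as.numeric(origin), u = u, v = v, normal = n,
                 extent = as.numeric(extent), pixel_spacing = pixel_spacing,
                 thickness = thickness, strategy = strategy, id = id),
            class = "plane_geometry")
}

#' Valve axis and centre from the valve surface
#'
#' Principal component analysis of the mesh vertices: the eigenvector of the
#' vertex covariance with the smallest eigenvalue is the valve axis (used as
#' SAX plane normal and rLAX rotation axis).  The sign is fixed so the axis
#' points towards the atrial side: towards `atrial_ref` when given, otherwise
#' towards the annulus centroid (which lies atrial of the drooping leaflets);
#' if both are unavailable/degenerate the dominant component is made
#' positive.
#'
#' @param mesh a `valve_mesh`, or a plain n x 3 vertex matrix.
#' @param atrial_ref optional 3-point world reference on the atrial side.
#' @return list with `axis` (unit 3-vector) and `center` (vertex centroid).
#' @export
compute_valve_axis <- function(mesh, atrial_ref = NULL) {
  V <- if (inherits(mesh, "valve_mesh")) mesh$vertices else as_points_matrix(mesh)
  if (nrow(V) < 3L) stop("need at least 3 vertices")
  ctr <- colMeans(V)
  C <- stats::cov(V)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[2L] < 1e-10 * max(eg$values[1L], 1)) {
    stop("degenerate geometry: vertices are collinear")
  }
  axis <- eg$vectors[, 3L]
  ref_dir <- NULL
  if (!is.null(atrial_ref)) {
    ref_dir <- as.numeric(atrial_ref) - ctr
  } else if (inherits(mesh, "valve_mesh") && !is.null(mesh$annulus_vertex_ids)) {
    ref_dir <- colMeans(mesh_annulus_curve(mesh)) - ctr
  }
  if (!is.null(ref_dir) && abs(sum(axis * ref_dir)) > 1e-9) {
    if (sum(axis * ref_dir) < 0) axis <- -axis
  } else if (axis[which.max(abs(axis))] < 0) {
    axis <- -axis
  }
  list(axis = axis, center = ctr)
}

#' Short-axis (SAX) plane stack
#'
#' Parallel planes perpendicular to the valve axis.  Slice centres are spaced
#' `spacing` mm apart (centre-to-centre; with the default 6 mm spacing and
#' 6 mm thickness the slabs are contiguous, the standard cine SAX layout) and
#' the stack is centred on the valve centre.
#'
#' @param axis unit valve axis (stack normal).
#' @param center valve centre, world mm.
#' @param n_slices number of slices (`>= 1`).
#' @param thickness_mm slab thickness, mm.
#' @param spacing_mm centre-to-centre slice distance, mm.
#' @param extent,pixel_spacing in-plane geometry (see [plane_geometry()]).
#' @return list of `plane_geometry`, tagged `"SAX"`.
#' @export
define_sax_planes <- function(axis, center, n_slices = 5L, thickness_mm = 6,
                              spacing_mm = 6, extent = c(100, 100),
                              pixel_spacing = 0.7) {
  axis <- unit3(axis)
  if (n_slices < 1L) stop("n_slices must be >= 1")
  u <- reference_direction(axis)
  v <- cross3(axis, u)   # {u, v, axis} right-handed
  offs <- (seq_len(n_slices) - (n_slices + 1) / 2) * spacing_mm
  lapply(seq_len(n_slices), function(k) {
    plane_geometry(origin = center + offs[k] * axis, u = u, v = v,
                   normal = axis, extent = extent,
                   pixel_spacing = pixel_spacing, thickness = thickness_mm,
                   strategy = "SAX", id = sprintf("SAX_%02d", k))
  })
}

#' Radial long-axis (rLAX) plane family
#'
#' Planes all containing the valve axis and centre, rotated about the axis by
#' a fixed increment of `180 / n_planes` degrees (so 18 planes sample every
#' 10 degrees over the half circle; the other half is covered by the same
#' planes seen from behind).
#'
#' @param axis unit valve axis (in-plane for every returned plane).
#' @param center valve centre, world mm.
#' @param n_planes number of rotations (6, 9 and 18 are the study settings).
#' @param thickness_mm slab thickness, mm.
#' @param extent,pixel_spacing in-plane geometry.
#' @return list of `plane_geometry`, tagged `"rLAX<n>"`.
#' @export
define_rlax_planes <- function(axis, center, n_planes = 18L, thickness_mm = 6,
                               extent = c(100, 100), pixel_spacing = 0.7) {
  axis <- unit3(axis)
  if (n_planes < 1L) stop("n_planes must be >= 1")
  r0 <- reference_direction(axis)
  tag <- sprintf("rLAX%d", n_planes)
  lapply(seq_len(n_planes), function(k) {
    phi <- (k - 1L) * pi / n_planes
    r <- drop(rotation_about(axis, phi) %*% r0)
    # In-plane axes: r (radial) and the valve axis; normal = r x axis.
    plane_geometry(origin = center, u = r, v = axis,
                   extent = extent, pixel_spacing = pixel_spacing,
                   thickness = thickness_mm, strategy = tag,
                   id = sprintf("%s_%02d", tag, k))
  })
}

# Pixel-centre offsets of a plane's sampling grid (centred on the origin).
plane_pixel_grid <- function(plane) {
  npx <- pmax(1L, round(plane$extent / plane$pixel_spacing))
  us <- (seq_len(npx[1L]) - (npx[1L] + 1) / 2) * plane$pixel_spacing
  vs <- (seq_len(npx[2L]) - (npx[2L] + 1) / 2) * plane$pixel_spacing
  list(us = us, vs = vs)
}

#' @export
print.plane_geometry <- function(x, ...) {
  cat(sprintf("Plane %s: origin (%.1f, %.1f, %.1f), %s mm FOV, %.2g mm px, %.1f mm thick\n",
              x$id %||% "", x$origin[1L], x$origin[2L], x$origin[3L],
              paste(x$extent, collapse = " x "), x$pixel_spacing, x$thickness))
  invisible(x)
}
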