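#' Generate a bileaflet valve surface mesh
#'
#' Lofts two leaflet sheets (anterior and posterior) from the two halves of a
#' saddle annulus towards their free edges.  The free edges droop towards the
#' ventricle by `leaflet_depth` and are separated across the coaptation
#' mid-plane by `orifice_gap * (1 - state)`; at `state = 1` the free edges of
#' the two leaflets coincide (closed valve).  The leaflets meet at the two
#' commissures.  Mesh density is chosen so that the mean triangle area matches
#' `target_face_area` (default 0.55 mm^2, the density used for the reference
#' segmented valve model).
#'
#' @param annulus an [annulus_model()].
#' @param leaflet_depth droop of the free edge below the annulus plane, mm.
#' @param orifice_gap open-state separation of the free edges at the valve
#'   centre, mm (measured across the coaptation plane).
#' @param target_face_area requested mean triangle area, mm^2.
#' @param state closure fraction in `[0, 1]`; 0 = open, 1 = closed.
#' @return A `valve_mesh`: list with `vertices` (n x 3 mm), `faces` (m x 3,
#'   1-based), ordered `annulus_vertex_ids`, `free_edge_vertex_ids` (per
#'   leaflet), `leaflet_id` per face, and the construction frame.
#' @export
generate_valve_mesh <- function(annulus = annulus_model(),
                                leaflet_depth = 22,
                                orifice_gap = 16,
                                target_face_area = 0.55,
                                state = 0) {
  if (!inherits(annulus, "annulus_model")) stop("annulus must be an annulus_model")
  if (!is.finite(leaflet_depth) || leaflet_depth <= 0) {
    stop("leaflet_depth must be > 0")
  }
  if (!is.finite(target_face_area) || target_face_area <= 0) {
    stop("parameter error: target_face_area must be > 0")
  }
  if (!is.finite(state) || state < 0 || state > 1) stop("state must be in [0, 1]")
  if (orifice_gap < 0) stop("orifice_gap must be >= 0")

  a <- annulus$radii[1L]
  b <- annulus$radii[2L]
  h <- annulus$saddle_height

  # Characteristic lengths set the grid aspect ratio: along-annulus length of
  # one leaflet vs. mean loft length annulus -> free edge.
  tt <- seq(0, pi, length.out = 512L)
  half_arc <- sum(sqrt(diff(a * cos(tt))^2 + diff(b * sin(tt))^2 +
                         diff(h * cos(2 * tt))^2))
  g <- orifice_gap / 2 * (1 - state)
  loft <- sqrt(((b - g) * sin(tt))^2 +
                 (leaflet_depth * sin(tt) + h * cos(2 * tt))^2)
  mean_loft <- max(mean(loft), 1e-3)

  n_t <- 24L
  n_s <- max(2L, as.integer(round(n_t * mean_loft / half_arc)))
  mesh <- NULL
  for (iter in 1:5) {
    mesh <- build_bileaflet(annulus, leaflet_depth, g, n_t, n_s)
    mean_area <- mean(mesh_face_areas(mesh))
    ratio <- mean_area / target_face_area
    if (abs(ratio - 1) < 0.05) break
    scale <- sqrt(ratio)
    n_t <- max(4L, as.integer(round(n_t * scale)))
    n_s <- max(2L, as.integer(round(n_s * scale)))
  }
  mesh$annulus <- annulus
  mesh$state <- state
  mesh$params <- list(leaflet_depth = leaflet_depth, orifice_gap = orifice_gap,
                      target_face_area = target_face_area,
                      n_t = n_t, n_s = n_s)
  mesh
}

# Build the two lofted leaflet grids.  g is the current free-edge half-gap.
build_bileaflet <- function(annulus, depth, g, n_t, n_s) {
  a <- annulus$radii[1L]
  b <- annulus$radii[2L]
  h <- annulus$saddle_height
  E <- annulus$axis_frame
  ctr <- annulus$center
  t <- seq(0, pi, length.out = n_t + 1L)
  s <- seq(0, 1, length.out = n_s + 1L)

  vertices <- NULL
  faces <- NULL
  leaflet_id <- character(0)
  annulus_ids <- list()
  free_ids <- list()

  for (leaflet in c("anterior", "posterior")) {
    sgn <- if (leaflet == "anterior") 1 else -1
    # Local coordinates (e1, e2, e3): annulus row and free-edge row.
    p <- cbind(a * cos(t), sgn * b * sin(t), h * cos(2 * t))
    f <- cbind(a * cos(t), sgn * g * sin(t), -depth * sin(t))
    nv <- (n_t + 1L) * (n_s + 1L)
    V <- matrix(0, nv, 3L)
    for (j in seq_along(s)) {
      rows <- (j - 1L) * (n_t + 1L) + seq_len(n_t + 1L)
      V[rows, ] <- (1 - s[j]) * p + s[j] * f
    }
    V <- sweep(V %*% t(E), 2L, ctr, "+")
    offset <- if (is.null(vertices)) 0L else nrow(vertices)
    vertices <- rbind(vertices, V)

    idx <- function(i, j) offset + (j - 1L) * (n_t + 1L) + i
    Fq <- matrix(0L, 2L * n_t * n_s, 3L)
    k <- 0L
    for (j in seq_len(n_s)) {
      for (i in seq_len(n_t)) {
        v00 <- idx(i, j); v10 <- idx(i + 1L, j)
        v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
        Fq[k + 1L, ] <- c(v00, v10, v11)
        Fq[k + 2L, ] <- c(v00, v11, v01)
        k <- k + 2L
      }
    }
    faces <- rbind(faces, Fq)
    leaflet_id <- c(leaflet_id, rep(leaflet, nrow(Fq)))
    annulus_ids[[leaflet]] <- idx(seq_len(n_t + 1L), 1L)
    free_ids[[leaflet]] <- idx(seq_len(n_t + 1L), n_s + 1L)
  }

  # Ordered annulus ring: anterior t 0..pi (theta 0..pi), posterior reversed
  # (theta pi..2pi); duplicate commissure corners dropped.
  ring <- c(annulus_ids$anterior, rev(annulus_ids$posterior)[-1L])
  ring <- ring[-length(ring)]

  nv_leaf <- (n_t + 1L) * (n_s + 1L)
  structure(
    list(vertices = vertices, faces = faces,
         leaflet_id = leaflet_id,
         vertex_leaflet = rep(c("anterior", "posterior"), each = nv_leaf),
         annulus_vertex_ids = ring,
         annulus_row_ids = annulus_ids,
         free_edge_vertex_ids = free_ids,
         frame = E, center = ctr),
    class = "valve_mesh")
}

#' Triangle areas of a mesh
#' @param mesh a `valve_mesh` (or any list with `vertices` and `faces`).
#' @return numeric vector of face areas in mm^2.
#' @export
mesh_face_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  e2 <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Edge table with incidence counts; used for manifoldness and boundary checks.
mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  first <- !duplicated(key)
  data.frame(v1 = pmin(e[first, 1L], e[first, 2L]),
             v2 = pmax(e[first, 1L], e[first, 2L]),
             count = as.integer(tab[key[first]]))
}

#' Ordered annulus boundary curve of a valve mesh
#' @param mesh a `valve_mesh`.
#' @return ordered closed polyline (k x 3 mm), closure implicit.
#' @export
mesh_annulus_curve <- function(mesh) {
  mesh$vertices[mesh$annulus_vertex_ids, , drop = FALSE]
}

#' Ordered orifice (free-edge) curve of a valve mesh
#'
#' Anterior free edge followed by the reversed posterior free edge, forming a
#' closed loop through the commissures.
#' @param mesh a `valve_mesh`.
#' @return ordered closed polyline (k x 3 mm).
#' @export
mesh_orifice_curve <- function(mesh) {
  ids <- c(mesh$free_edge_vertex_ids$anterior,
           rev(mesh$free_edge_vertex_ids$posterior)[-1L])
  ids <- ids[-length(ids)]
  mesh$vertices[ids, , drop = FALSE]
}

# Apply a rigid transform to a valve mesh (rotation R then translation t).
transform_valve_mesh <- function(mesh, R, t) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2L, t, "+")
  mesh$frame <- R %*% mesh$frame
  mesh$center <- drop(R %*% mesh$center) + t
  if (!is.null(mesh$annulus)) {
    mesh$annulus$center <- drop(R %*% mesh$annulus$center) + t
    mesh$annulus$axis_frame <- R %*% mesh$annulus$axis_frame
  }
  mesh
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf(
    "Bileaflet valve mesh: %d vertices, %d faces, mean face area %.3f mm^2\n",
    nrow(x$vertices), nrow(x$faces), mean(mesh_face_areas(x))))
  invisible(x)
}
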