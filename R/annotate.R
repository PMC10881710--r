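#' Intersect the valve mesh with an imaging plane
#'
#' Cross-section of the leaflet surface with the plane offset by `offset` mm
#' along its normal.  Triangle-plane segments are chained into polylines per
#' leaflet; polyline endpoints that land on a mesh boundary edge are tagged
#' `"annulus"` (annulus attachment), `"orifice"` (free edge) or `"side"`
#' (commissure seam).
#'
#' @param mesh a `valve_mesh`.
#' @param plane a [plane_geometry()].
#' @param offset signed through-plane offset from the plane origin, mm.
#' @return list of components, each `list(points, leaflet, end_tags, closed)`;
#'   empty list when the plane misses the mesh.
#' @export
intersect_valve_plane <- function(mesh, plane, offset = 0) {
  o <- plane$origin + offset * plane$normal
  n <- plane$normal
  V <- mesh$vertices
  F <- mesh$faces
  s <- drop(sweep(V, 2L, o) %*% n)
  s[s == 0] <- 1e-12

  s1 <- s[F[, 1L]]; s2 <- s[F[, 2L]]; s3 <- s[F[, 3L]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) return(list())

  boundary <- mesh_boundary_classification(mesh)

  segs_p1 <- NULL; segs_p2 <- NULL
  keys1 <- character(0); keys2 <- character(0)
  seg_leaflet <- character(0)
  edge_point <- function(i, j) {
    t <- s[i] / (s[i] - s[j])
    V[i, , drop = FALSE] + (V[j, , drop = FALSE] - V[i, , drop = FALSE]) * t
  }
  for (f in which(crossing)) {
    vid <- F[f, ]
    sv <- s[vid]
    pts <- NULL
    keys <- character(0)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      i <- vid[e[1L]]; j <- vid[e[2L]]
      if (s[i] * s[j] < 0) {
        pts <- rbind(pts, edge_point(i, j))
        keys <- c(keys, paste(min(i, j), max(i, j)))
      }
    }
    if (is.null(pts) || nrow(pts) != 2L) next
    segs_p1 <- rbind(segs_p1, pts[1L, ])
    segs_p2 <- rbind(segs_p2, pts[2L, ])
    keys1 <- c(keys1, keys[1L])
    keys2 <- c(keys2, keys[2L])
    seg_leaflet <- c(seg_leaflet, mesh$leaflet_id[f])
  }
  if (is.null(segs_p1)) return(list())

  out <- list()
  for (leaf in unique(seg_leaflet)) {
    sel <- which(seg_leaflet == leaf)
    comps <- chain_segments(segs_p1[sel, , drop = FALSE],
                            segs_p2[sel, , drop = FALSE],
                            keys1[sel], keys2[sel])
    for (cmp in comps) {
      cmp$leaflet <- leaf
      cmp$end_tags <- c(classify_section_end(cmp$key_start, boundary),
                        classify_section_end(cmp$key_end, boundary))
      cmp$key_start <- cmp$key_end <- NULL
      out[[length(out) + 1L]] <- cmp
    }
  }
  out
}

# Classify every mesh edge: interior, or boundary of type annulus / orifice /
# side, by membership of both endpoints in the marked vertex sets.
mesh_boundary_classification <- function(mesh) {
  et <- mesh_edge_table(mesh$faces)
  bnd <- et[et$count == 1L, , drop = FALSE]
  ann <- unique(unlist(mesh$annulus_row_ids %||% list(mesh$annulus_vertex_ids)))
  fre <- unique(unlist(mesh$free_edge_vertex_ids))
  type <- rep("side", nrow(bnd))
  type[bnd$v1 %in% ann & bnd$v2 %in% ann] <- "annulus"
  type[bnd$v1 %in% fre & bnd$v2 %in% fre] <- "orifice"
  structure(type, names = paste(bnd$v1, bnd$v2))
}

classify_section_end <- function(key, boundary) {
  if (is.na(key) || !key %in% names(boundary)) "none" else boundary[[key]]
}

# Chain segments (p1[i] -- p2[i], with mesh-edge keys) into polylines.
chain_segments <- function(p1, p2, k1, k2) {
  nseg <- nrow(p1)
  used <- rep(FALSE, nseg)
  key_count <- table(c(k1, k2))
  comps <- list()
  seg_at <- function(key) which(!used & (k1 == key | k2 == key))
  repeat {
    # Prefer starting from an open end (edge key used once).
    start <- NA_integer_
    for (i in which(!used)) {
      if (key_count[[k1[i]]] == 1L || key_count[[k2[i]]] == 1L) {
        start <- i
        break
      }
    }
    if (is.na(start)) start <- which(!used)[1L]
    if (is.na(start) || length(start) == 0L) break
    i <- start
    used[i] <- TRUE
    if (key_count[[k1[i]]] == 1L) {
      pts <- rbind(p1[i, ], p2[i, ]); first_key <- k1[i]; lead <- k2[i]
    } else {
      pts <- rbind(p2[i, ], p1[i, ]); first_key <- k2[i]; lead <- k1[i]
    }
    closed <- FALSE
    repeat {
      nxt <- seg_at(lead)
      if (length(nxt) == 0L) break
      j <- nxt[1L]
      used[j] <- TRUE
      if (k1[j] == lead) {
        pts <- rbind(pts, p2[j, ]); lead <- k2[j]
      } else {
        pts <- rbind(pts, p1[j, ]); lead <- k1[j]
      }
      if (lead == first_key) {
        closed <- TRUE
        break
      }
    }
    comps[[length(comps) + 1L]] <- list(points = pts, closed = closed,
                                        key_start = first_key, key_end = lead)
    if (all(used)) break
  }
  comps
}

# Resample a polyline at roughly equal arc-length spacing (keeps endpoints).
resample_polyline <- function(pts, spacing) {
  if (nrow(pts) < 2L) return(pts)
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(d))
  total <- arc[length(arc)]
  if (total < spacing) {
    return(pts[c(1L, nrow(pts)), , drop = FALSE])
  }
  n <- max(2L, ceiling(total / spacing) + 1L)
  at <- seq(0, total, length.out = n)
  cbind(stats::approx(arc, pts[, 1L], xout = at)$y,
        stats::approx(arc, pts[, 2L], xout = at)$y,
        stats::approx(arc, pts[, 3L], xout = at)$y)
}

#' Simulate expert annotators
#'
#' Emulates the manual annotation protocol on the simulated slices: on each
#' radial long-axis plane two annulus points, up to two leaflet-end (orifice)
#' points and a variable number of leaflet contour points; on each short-axis
#' slice spline-like contour control points.  Ground-truth points are the
#' exact plane-valve intersections (SAX points are pooled over sub-planes of
#' the 6 mm slab and projected to the slice centre plane, reproducing the
#' through-plane ambiguity of thick-slice annotation); each annotator then
#' perturbs every point with in-plane Gaussian noise and may miss
#' annulus/orifice points independently.
#'
#' @param mesh a `valve_mesh` (the timeframe being annotated).
#' @param planes list of [plane_geometry()] (one strategy).
#' @param noise_sigma_mm in-plane click noise sigma per axis, mm.
#' @param detection_miss_rate probability of missing an annulus/orifice
#'   point, in `[0, 1)`.
#' @param seed study seed; each annotator draws from a derived substream.
#' @param n_annotators number of simulated annotators.
#' @param leaflet_spacing_mm contour point spacing on rLAX planes, mm.
#' @param sax_control_spacing_mm spline control point spacing on SAX, mm.
#' @param n_sublayers SAX slab sub-planes pooled per slice.
#' @return data.frame (class `mv_annotations`) with columns `annotator`,
#'   `plane_id`, `strategy`, `structure` (annulus/orifice/leaflet), `x`,
#'   `y`, `z` (world mm).
#' @export
simulate_annotators <- function(mesh, planes, noise_sigma_mm = 1.5,
                                detection_miss_rate = 0, seed = 1L,
                                n_annotators = 3L,
                                leaflet_spacing_mm = 2,
                                sax_control_spacing_mm = 3,
                                n_sublayers = 5L) {
  if (noise_sigma_mm < 0) stop("noise_sigma_mm must be >= 0")
  if (detection_miss_rate < 0 || detection_miss_rate >= 1) {
    stop("no annotatable points: detection_miss_rate must be in [0, 1)")
  }
  gt <- annotation_ground_truth(mesh, planes, leaflet_spacing_mm,
                                sax_control_spacing_mm, n_sublayers)
  if (nrow(gt) == 0L) stop("no annotatable points: planes do not intersect the valve")

  out <- vector("list", n_annotators)
  for (a in seq_len(n_annotators)) {
    set.seed(derive_seed(seed, paste0("annotator_", a)))
    df <- gt
    if (noise_sigma_mm > 0) {
      for (pid in unique(df$plane_id)) {
        pl <- planes[[which(vapply(planes, function(p) identical(p$id, pid), NA))]]
        rows <- which(df$plane_id == pid)
        eu <- stats::rnorm(length(rows), 0, noise_sigma_mm)
        ev <- stats::rnorm(length(rows), 0, noise_sigma_mm)
        shift <- outer(eu, pl$u) + outer(ev, pl$v)
        df[rows, c("x", "y", "z")] <- df[rows, c("x", "y", "z")] + shift
      }
    }
    if (detection_miss_rate > 0) {
      landmark <- df$structure %in% c("annulus", "orifice")
      drop <- landmark & stats::runif(nrow(df)) < detection_miss_rate
      df <- df[!drop, , drop = FALSE]
    }
    df$annotator <- a
    out[[a]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mv_annotations", "data.frame")
  res
}

# Exact plane-valve intersection points, structured like the annotations.
annotation_ground_truth <- function(mesh, planes, leaflet_spacing_mm = 2,
                                    sax_control_spacing_mm = 3,
                                    n_sublayers = 5L) {
  rows <- list()
  add <- function(pts, structure, plane) {
    if (is.null(pts) || nrow(pts) == 0L) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      plane_id = plane$id %||% "plane", strategy = plane$strategy %||% "custom",
      structure = structure, x = pts[, 1L], y = pts[, 2L], z = pts[, 3L])
  }
  ann_curve <- mesh_annulus_curve(mesh)
  free_ant <- mesh$vertices[mesh$free_edge_vertex_ids$anterior, , drop = FALSE]
  free_pos <- mesh$vertices[mesh$free_edge_vertex_ids$posterior, , drop = FALSE]

  for (plane in planes) {
    sax <- identical(plane$strategy, "SAX")
    if (!sax) {
      add(polyline_plane_intersections(ann_curve, plane$origin, plane$normal,
                                       closed = TRUE), "annulus", plane)
      ori <- rbind(
        polyline_plane_intersections(free_ant, plane$origin, plane$normal),
        polyline_plane_intersections(free_pos, plane$origin, plane$normal))
      if (nrow(ori) > 2L) ori <- ori[1:2, , drop = FALSE]
      add(ori, "orifice", plane)
      for (cmp in intersect_valve_plane(mesh, plane)) {
        add(resample_polyline(cmp$points, leaflet_spacing_mm), "leaflet", plane)
      }
    } else {
      offs <- if (n_sublayers == 1L) 0 else
        seq(-plane$thickness / 2, plane$thickness / 2,
            length.out = n_sublayers)
      for (o in offs) {
        for (cmp in intersect_valve_plane(mesh, plane, offset = o)) {
          pts <- project_to_plane(cmp$points, plane)
          ctl <- resample_polyline(pts, sax_control_spacing_mm)
          add(ctl, "leaflet", plane)
          if (!cmp$closed) {
            ends <- pts[c(1L, nrow(pts)), , drop = FALSE]
            for (e in 1:2) {
              if (cmp$end_tags[e] %in% c("annulus", "orifice")) {
                add(ends[e, , drop = FALSE], cmp$end_tags[e], plane)
              }
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(plane_id = character(0), strategy = character(0),
                      structure = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0)))
  }
  do.call(rbind, rows)
}

project_to_plane <- function(pts, plane) {
  d <- drop(sweep(pts, 2L, plane$origin) %*% plane$normal)
  pts - outer(d, plane$normal)
}

#' Write / read annotation sets as JSON
#' @param annotations an `mv_annotations` data.frame.
#' @param path output path (`.json`), or `.csv` for a flat point export.
#' @return the path / the annotations, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(annotations, path, row.names = FALSE)
  } else {
    jsonlite::write_json(annotations, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- if (grepl("\\.csv$", path)) {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  class(df) <- c("mv_annotations", "data.frame")
  df
}
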