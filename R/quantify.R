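#' Annulus diameters and height from a PCA of annular points
#'
#' Principal component analysis of the (centred) annulus points.  The maximum
#' diameter is the extent (max minus min) of the projections on the first
#' principal component, the minimum diameter the extent on the second, and
#' the annulus height the extent on the third (the saddle's out-of-plane
#' range).  Components are ordered by descending eigenvalue; on ties the
#' extents are tie-invariant and component signs are canonicalised
#' (largest-magnitude entry positive).
#'
#' @param annulus_points n x 3 matrix (n >= 4, not collinear), world mm.
#' @return list with `d_max`, `d_min`, `height` (mm) and `frame`
#'   (list `center`, `axes` 3x3 with PCs in columns).
#' @export
annulus_pca_params <- function(annulus_points) {
  P <- as_points_matrix(annulus_points)
  if (nrow(P) < 4L) stop("geometry error: need >= 4 annulus points")
  ctr <- colMeans(P)
  X <- sweep(P, 2L, ctr)
  eg <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (eg$values[2L] <= 1e-10 * max(eg$values[1L], 1e-12)) {
    stop("geometry error: annulus points are collinear")
  }
  axes <- eg$vectors
  for (k in 1:3) {
    if (axes[which.max(abs(axes[, k])), k] < 0) axes[, k] <- -axes[, k]
  }
  proj <- X %*% axes
  ext <- apply(proj, 2L, function(p) max(p) - min(p))
  list(d_max = ext[1L], d_min = ext[2L], height = ext[3L],
       frame = list(center = ctr, axes = axes))
}

#' Projected 2D polygon area in the annular plane
#'
#' Points are projected onto the annular plane (the PC3 coordinate is
#' dropped), ordered by angle about their centroid unless already ordered,
#' and the area is the absolute shoelace sum / 2.
#'
#' @param points n x 3 matrix (n >= 3), world mm.
#' @param frame annular frame from [annulus_pca_params()].
#' @param ordered set `TRUE` when `points` already form an ordered contour.
#' @return area in mm^2.
#' @export
projected_area <- function(points, frame, ordered = FALSE) {
  P <- as_points_matrix(points)
  if (nrow(P) < 3L) stop("geometry error: need >= 3 points for an area")
  X <- sweep(P, 2L, frame$center) %*% frame$axes[, 1:2]
  if (!ordered) {
    ctr <- colMeans(X)
    X <- X[order(atan2(X[, 2L] - ctr[2L], X[, 1L] - ctr[1L])), , drop = FALSE]
  }
  if (nrow(X) <= 400L && polygon_self_intersects(X)) {
    warning("projected polygon self-intersects; shoelace value reported")
  }
  polygon_shoelace_area(X)
}

# O(n^2) segment-pair crossing test on a closed 2D polygon.
polygon_self_intersects <- function(X) {
  n <- nrow(X)
  if (n < 4L) return(FALSE)
  A <- X
  B <- X[c(2:n, 1L), , drop = FALSE]
  crosses <- function(i, j) {
    d1 <- B[i, ] - A[i, ]
    d2 <- B[j, ] - A[j, ]
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    r <- A[j, ] - A[i, ]
    t <- (r[1L] * d2[2L] - r[2L] * d2[1L]) / den
    u <- (r[1L] * d1[2L] - r[2L] * d1[1L]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (crosses(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' Clinically established valve parameters
#'
#' Computes Dmax, Dmin, annulus height, and the projected 2D annulus and
#' orifice areas, either from the ground-truth valve mesh (annulus and
#' free-edge boundary curves) or from an annotation set (annulus and
#' leaflet-end points pooled over all planes).
#'
#' @param x a `valve_mesh` or an `mv_annotations` data.frame restricted to
#'   one annotator (use [split()] or the `annotator` argument).
#' @param annotator for annotation input with several annotators: which one.
#' @param ... unused.
#' @return list of class `quant_params`: `d_max`, `d_min`, `height` (mm),
#'   `annulus_area`, `orifice_area` (mm^2).
#' @export
quantify_valve <- function(x, ...) UseMethod("quantify_valve")

#' @rdname quantify_valve
#' @export
quantify_valve.valve_mesh <- function(x, ...) {
  ann <- mesh_annulus_curve(x)
  ori <- mesh_orifice_curve(x)
  pca <- annulus_pca_params(ann)
  structure(list(
    d_max = pca$d_max, d_min = pca$d_min, height = pca$height,
    annulus_area = projected_area(ann, pca$frame, ordered = TRUE),
    orifice_area = projected_area(ori, pca$frame, ordered = TRUE)),
    class = "quant_params")
}

#' @rdname quantify_valve
#' @export
quantify_valve.mv_annotations <- function(x, annotator = NULL, ...) {
  df <- x
  if (!is.null(annotator)) df <- df[df$annotator == annotator, , drop = FALSE]
  if (!is.null(df$annotator) && length(unique(df$annotator)) > 1L) {
    stop("annotations contain several annotators; pick one with `annotator`")
  }
  ann <- df[df$structure == "annulus", , drop = FALSE]
  if (nrow(ann) < 4L || length(unique(ann$plane_id)) < 2L) {
    stop("insufficient annotation: need annulus points from >= 2 planes")
  }
  P <- as.matrix(ann[, c("x", "y", "z")])
  pca <- annulus_pca_params(P)
  ori <- df[df$structure == "orifice", , drop = FALSE]
  orifice_area <- if (nrow(ori) >= 3L) {
    projected_area(as.matrix(ori[, c("x", "y", "z")]), pca$frame)
  } else {
    NA_real_
  }
  structure(list(
    d_max = pca$d_max, d_min = pca$d_min, height = pca$height,
    annulus_area = projected_area(P, pca$frame),
    orifice_area = orifice_area),
    class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat(sprintf(
    "Dmax %.1f mm, Dmin %.1f mm, height %.1f mm, annulus %.0f mm^2, orifice %.0f mm^2\n",
    x$d_max, x$d_min, x$height, x$annulus_area, x$orifice_area))
  invisible(x)
}

#' Annotation bias of a quantitative parameter
#'
#' Arithmetic mean of the signed differences between per-annotator values and
#' the ground truth: `BIAS = sum_i (a_case_i - a_gt) / N`.
#'
#' @param case_values numeric vector, one value per annotator.
#' @param gt_value ground-truth value.
#' @return signed bias, same units as the parameter.
#' @export
param_bias <- function(case_values, gt_value) {
  case_values <- as.numeric(case_values)
  if (length(case_values) < 1L) stop("need at least one case value")
  mean(case_values - gt_value)
}

# Summary statistics used by all distance reports.
distance_report <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) == 0L) stop("no distances to summarise")
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  outliers <- d[d < q[1L] - 1.5 * iqr | d > q[3L] + 1.5 * iqr]
  structure(list(
    distances = d,
    summary = c(min = min(d), p25 = q[1L], p50 = q[2L], p75 = q[3L],
                mean = mean(d), sd = stats::sd(d), max = max(d)),
    outliers = outliers),
    class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "n = %d distances (mm): mean %.2f +/- %.2f, median %.2f [%.2f, %.2f], range %.2f-%.2f, %d outliers\n",
    length(x$distances), s["mean"], s["sd"], s["p50"], s["p25"], s["p75"],
    s["min"], s["max"], length(x$outliers)))
  invisible(x)
}

#' Shortest distances from annotated points to a ground-truth contour
#'
#' Asymmetric point-to-polyline distances (annotation to ground truth): for
#' every annotated point the exact minimum distance over all contour
#' segments.
#'
#' @param annotated n x 3 matrix of annotated points, world mm.
#' @param gt_contour k x 3 ground-truth polyline (k >= 2).
#' @param closed is the ground-truth contour closed?
#' @return a `distance_report` (distances, order statistics, mean, sd,
#'   outliers by the 1.5 IQR rule).
#' @export
contour_distance <- function(annotated, gt_contour, closed = TRUE) {
  P <- as_points_matrix(annotated)
  G <- as_points_matrix(gt_contour)
  if (nrow(P) == 0L) stop("no annotated points")
  if (nrow(G) < 2L) stop("ground-truth contour needs >= 2 points")
  d <- vapply(seq_len(nrow(P)),
              function(i) point_polyline_distance(P[i, ], G, closed = closed),
              0)
  distance_report(d)
}

#' Shortest distances from annotated points to the valve surface
#'
#' Exact point-to-triangle distance minimised over all faces (vertex, edge
#' and interior closest-point cases handled exactly); unsigned.
#'
#' @param points n x 3 matrix of annotated points, world mm.
#' @param mesh ground-truth `valve_mesh`.
#' @return a `distance_report`.
#' @export
point_to_surface_distance <- function(points, mesh) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) stop("empty mesh")
  d <- points_mesh_distance(points, mesh$vertices, mesh$faces)
  distance_report(d)
}
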