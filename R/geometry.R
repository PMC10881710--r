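# Internal linear-algebra and mesh-geometry primitives shared across modules.
# World coordinates are millimetres, right-handed; voxel indices 0-based.

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @noRd
is_orthonormal_frame <- function(m, tol = 1e-8) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) < tol && det(m) > 0
}

# Rodrigues rotation about a (unit) axis by angle radians.
rotation_about <- function(axis, angle) {
  a <- unit3(axis)
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Component of v orthogonal to a unit axis.
perp_component <- function(v, axis) v - sum(v * axis) * axis

# Deterministic in-plane reference direction orthogonal to a unit axis:
# the rejection of the global x axis, falling back to y when near-parallel.
reference_direction <- function(axis) {
  r <- perp_component(c(1, 0, 0), axis)
  if (vnorm(r) < 1e-6) r <- perp_component(c(0, 1, 0), axis)
  unit3(r)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("points must be a 3-vector or an n x 3 matrix")
    points <- matrix(points, 1L, 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z in mm)")
  storage.mode(points) <- "double"
  points
}

# Squared distances from a set of points (n x 3) to one triangle (a, b, c),
# vectorised over points.  Closest-point region logic after the classic
# real-time collision-detection formulation; returns list(dist2, closest).
point_triangle_dist2 <- function(p, a, b, c) {
  p <- as_points_matrix(p)
  n <- nrow(p)
  ab <- b - a
  ac <- c - a
  bc <- c - b
  pa <- p - rep(a, each = n)
  pb <- p - rep(b, each = n)
  pc <- p - rep(c, each = n)
  d1 <- drop(pa %*% ab)
  d2 <- drop(pa %*% ac)
  d3 <- drop(pb %*% ab)
  d4 <- drop(pb %*% ac)
  d5 <- drop(pc %*% ab)
  d6 <- drop(pc %*% ac)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  q <- matrix(0, n, 3L)
  # Face interior (default; guarded denominator, degenerate rows get
  # overwritten by the edge/vertex cases below).
  denom <- va + vb + vc
  denom[abs(denom) < 1e-300] <- 1
  v <- vb / denom
  w <- vc / denom
  q <- rep(a, each = n) + outer(v, ab) + outer(w, ac)

  # Edge BC.
  m <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(m)) {
    t <- (d4[m] - d3[m]) / pmax((d4[m] - d3[m]) + (d5[m] - d6[m]), 1e-300)
    q[m, ] <- rep(b, each = sum(m)) + outer(t, bc)
  }
  # Edge AC.
  m <- vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(m)) {
    t <- d2[m] / pmax(d2[m] - d6[m], 1e-300)
    q[m, ] <- rep(a, each = sum(m)) + outer(t, ac)
  }
  # Edge AB.
  m <- vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(m)) {
    t <- d1[m] / pmax(d1[m] - d3[m], 1e-300)
    q[m, ] <- rep(a, each = sum(m)) + outer(t, ab)
  }
  # Vertex regions take final precedence.
  m <- d6 >= 0 & d5 <= d6
  if (any(m)) q[m, ] <- rep(c, each = sum(m))
  m <- d3 >= 0 & d4 <= d3
  if (any(m)) q[m, ] <- rep(b, each = sum(m))
  m <- d1 <= 0 & d2 <= 0
  if (any(m)) q[m, ] <- rep(a, each = sum(m))

  diff <- p - q
  list(dist2 = rowSums(diff * diff), closest = q)
}

# Minimum distance from each point to a triangle soup (vertices V, faces F).
points_mesh_distance <- function(points, vertices, faces) {
  p <- as_points_matrix(points)
  if (nrow(faces) == 0L) stop("mesh has no faces")
  best <- rep(Inf, nrow(p))
  for (f in seq_len(nrow(faces))) {
    tri <- faces[f, ]
    d2 <- point_triangle_dist2(p, vertices[tri[1L], ], vertices[tri[2L], ],
                               vertices[tri[3L], ])$dist2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Minimum distance from one point to a polyline (k x 3), optionally closed.
point_polyline_distance <- function(p, poly, closed = FALSE) {
  poly <- as_points_matrix(poly)
  k <- nrow(poly)
  if (k < 2L) stop("polyline needs at least 2 points")
  A <- poly[-k, , drop = FALSE]
  B <- poly[-1L, , drop = FALSE]
  if (closed) {
    A <- rbind(A, poly[k, ])
    B <- rbind(B, poly[1L, ])
  }
  ab <- B - A
  ap <- matrix(p, nrow(A), 3L, byrow = TRUE) - A
  t <- rowSums(ap * ab) / pmax(rowSums(ab * ab), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  q <- A + ab * t
  d <- q - matrix(p, nrow(A), 3L, byrow = TRUE)
  sqrt(min(rowSums(d * d)))
}

# Intersections of a plane ((x - o) . n = 0) with a polyline; returns the
# crossing points (m x 3 matrix, possibly 0 rows).
polyline_plane_intersections <- function(poly, origin, normal, closed = FALSE) {
  poly <- as_points_matrix(poly)
  s <- drop((poly - matrix(origin, nrow(poly), 3L, byrow = TRUE)) %*% normal)
  s[s == 0] <- 1e-12
  idx <- seq_len(nrow(poly) - 1L)
  i2 <- idx + 1L
  if (closed) {
    idx <- c(idx, nrow(poly))
    i2 <- c(i2, 1L)
  }
  cross <- s[idx] * s[i2] < 0
  if (!any(cross)) return(matrix(numeric(0), 0L, 3L))
  ia <- idx[cross]
  ib <- i2[cross]
  t <- s[ia] / (s[ia] - s[ib])
  poly[ia, , drop = FALSE] + (poly[ib, , drop = FALSE] - poly[ia, , drop = FALSE]) * t
}

# Deterministic 32-bit sub-seed derived from a study seed and a stage tag, so
# every stochastic stage draws from its own reproducible substream.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h * 104729 + 17) %% 2147483629)
}

polygon_shoelace_area <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
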