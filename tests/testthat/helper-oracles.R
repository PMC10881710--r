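# Independent brute-force oracles used by the distance tests.  These are
# deliberately written from different formulations than the package code.

# Exact point-to-segment distance, scalar.
oracle_point_segment <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab * ab)
  t <- if (denom == 0) 0 else sum((p - a) * ab) / denom
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# Exact point-to-triangle distance via plane projection + edge fallback.
oracle_point_triangle <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nn <- sqrt(sum(n * n))
  best <- min(oracle_point_segment(p, a, b),
              oracle_point_segment(p, b, c),
              oracle_point_segment(p, c, a))
  if (nn > 1e-12) {
    n <- n / nn
    q <- p - sum((p - a) * n) * n
    # Barycentric test of the projection.
    v0 <- c - a; v1 <- b - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= 0 && v >= 0 && u + v <= 1) {
      best <- min(best, abs(sum((p - a) * n)))
    }
  }
  best
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Brute-force min distance from each point to a mesh (loop over everything).
oracle_points_to_mesh <- function(points, vertices, faces) {
  apply(points, 1L, function(p) {
    min(apply(faces, 1L, function(f) {
      oracle_point_triangle(p, vertices[f[1], ], vertices[f[2], ],
                            vertices[f[3], ])
    }))
  })
}

# Brute-force min distance from each point to a closed polyline.
oracle_points_to_contour <- function(points, poly, closed = TRUE) {
  k <- nrow(poly)
  segs <- cbind(seq_len(k - 1L), 2:k)
  if (closed) segs <- rbind(segs, c(k, 1L))
  apply(points, 1L, function(p) {
    min(apply(segs, 1L, function(s) {
      oracle_point_segment(p, poly[s[1], ], poly[s[2], ])
    }))
  })
}

# Small flat square mesh in the z = z0 plane (two triangles, side mm).
flat_square_mesh <- function(side = 20, z0 = 0) {
  h <- side / 2
  list(vertices = rbind(c(-h, -h, z0), c(h, -h, z0), c(h, h, z0), c(-h, h, z0)),
       faces = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# A random proper rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# Tiny label volume: two homogeneous boxes of the given entities.
two_label_volume <- function(n = 20L, entities = c("mitral_valve", "la_cavity")) {
  lm <- default_label_map()
  arr <- array(0L, c(2L * n, n, n))
  arr[seq_len(n), , ] <- lm[[entities[1L]]]
  arr[n + seq_len(n), , ] <- lm[[entities[2L]]]
  label_volume(arr, centered_affine_pub(c(2L * n, n, n), 1), lm)
}

centered_affine_pub <- function(shape, spacing) {
  sp <- rep(spacing, length.out = 3)
  aff <- diag(c(sp, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * sp
  aff
}
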