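#' Named anatomical landmark set
#'
#' Ten landmarks are used by default when fusing the heart/valve model with
#' the thorax: the four valve centres, the apex, the septum centre, and four
#' markers along the aorta centreline.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param names unique landmark names, one per row.
#' @return object of class `landmark_set` (a named-row matrix).
#' @export
landmark_set <- function(points, names) {
  points <- as_points_matrix(points)
  names <- as.character(names)
  if (length(names) != nrow(points)) stop("one name per landmark required")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  rownames(points) <- names
  class(points) <- c("landmark_set", class(points))
  points
}

#' Rigid landmark alignment (orthogonal Procrustes)
#'
#' Finds the proper rigid transform `(R, t)` minimising
#' `sum_i || R m_i + t - f_i ||^2` over landmark pairs matched by name.
#' With known correspondences the iterative closest point problem reduces to
#' this single closed-form step (SVD of the cross-covariance, with the
#' determinant correction that forbids reflections).
#'
#' @param moving,fixed `landmark_set` objects (or named-row matrices); at
#'   least 3 common, non-collinear landmarks are required.
#' @return list with `rotation` (3x3, det +1), `translation` (3-vector),
#'   `rmsd` (root-mean-square residual, mm) and the matched `names`.
#' @export
landmark_align <- function(moving, fixed) {
  moving <- as_points_matrix(moving)
  fixed <- as_points_matrix(fixed)
  common <- intersect(rownames(moving), rownames(fixed))
  if (length(common) < 3L) {
    stop("insufficient landmarks: need >= 3 matched landmark names")
  }
  M <- moving[common, , drop = FALSE]
  F <- fixed[common, , drop = FALSE]
  mc <- colMeans(M)
  fc <- colMeans(F)
  M0 <- sweep(M, 2L, mc)
  F0 <- sweep(F, 2L, fc)
  # Collinear (rank < 2) configurations cannot pin down a rotation.
  if (sum(svd(M0)$d > 1e-8 * max(1, max(abs(M0)))) < 2L) {
    stop("insufficient landmarks: points are collinear")
  }
  H <- crossprod(M0, F0)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- fc - drop(R %*% mc)
  resid <- F - sweep(M %*% t(R), 2L, t, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums(resid^2))), names = common)
}
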