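#' Parametric saddle-shaped mitral annulus model
#'
#' The mitral annulus is modelled as an ellipse with an out-of-plane saddle
#' term: point(theta) = center + a cos(theta) e1 + b sin(theta) e2 +
#' h cos(2 theta) e3.  The cos(2 theta) term is the classic bileaflet saddle
#' descriptor; its peaks sit at the aortic and posterior horns and its valleys
#' at the commissures, giving a nonzero "annulus height" ground truth.
#'
#' @param center 3-vector, annulus centre in world mm.
#' @param radii length-2 numeric `(a, b)`, semi-axes in mm with `a >= b > 0`.
#' @param saddle_height saddle amplitude `h` in mm (`>= 0`); the full
#'   out-of-plane extent of the curve is `2 h`.
#' @param axis_frame orthonormal 3x3 matrix with columns `e1`, `e2`, `e3`
#'   (in-plane axes and annulus axis); must be a proper rotation.
#' @param n_samples number of points used when the curve is sampled.
#' @return An object of class `annulus_model`.
#' @examples
#' ann <- annulus_model(radii = c(20, 15), saddle_height = 3)
#' curve <- generate_annulus(ann)
#' @export
annulus_model <- function(center = c(0, 0, 0), radii = c(20, 15),
                          saddle_height = 3, axis_frame = diag(3),
                          n_samples = 360L) {
  center <- as.numeric(center)
  radii <- as.numeric(radii)
  if (length(center) != 3L) stop("center must be a 3-vector (mm)")
  if (length(radii) != 2L || any(!is.finite(radii)) || radii[2L] <= 0 ||
      radii[1L] < radii[2L]) {
    stop("radii must satisfy a >= b > 0")
  }
  if (!is.finite(saddle_height) || saddle_height < 0) {
    stop("saddle_height must be >= 0")
  }
  if (!is_orthonormal_frame(axis_frame)) {
    stop("invalid frame: axis_frame must be orthonormal with det = +1")
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L) stop("n_samples must be >= 3")
  structure(
    list(center = center, radii = radii, saddle_height = saddle_height,
         axis_frame = axis_frame, n_samples = n_samples),
    class = "annulus_model")
}

#' Sample the annulus curve
#'
#' Returns the saddle annulus as an ordered closed curve.  The first point is
#' not repeated at the end: closure is implicit.  Points are ordered
#' counter-clockwise about the annulus axis `e3`.
#'
#' @param params an [annulus_model()].
#' @param n_samples optional override of the model's sample count.
#' @return `n x 3` matrix of points in world mm.
#' @export
generate_annulus <- function(params, n_samples = NULL) {
  if (!inherits(params, "annulus_model")) stop("params must be an annulus_model")
  n <- if (is.null(n_samples)) params$n_samples else as.integer(n_samples)
  if (n < 3L) stop("n_samples must be >= 3")
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  local <- cbind(params$radii[1L] * cos(theta),
                 params$radii[2L] * sin(theta),
                 params$saddle_height * cos(2 * theta))
  pts <- local %*% t(params$axis_frame)
  sweep(pts, 2L, params$center, "+")
}

# Points on the annulus for arbitrary theta values (internal).
annulus_points_at <- function(params, theta) {
  local <- cbind(params$radii[1L] * cos(theta),
                 params$radii[2L] * sin(theta),
                 params$saddle_height * cos(2 * theta))
  sweep(local %*% t(params$axis_frame), 2L, params$center, "+")
}

#' @export
print.annulus_model <- function(x, ...) {
  cat(sprintf(
    "Saddle annulus: a = %.1f mm, b = %.1f mm, h = %.1f mm, centre (%.1f, %.1f, %.1f)\n",
    x$radii[1L], x$radii[2L], x$saddle_height,
    x$center[1L], x$center[2L], x$center[3L]))
  invisible(x)
}
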