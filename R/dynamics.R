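#' Position-based dynamics configuration for valve closure
#'
#' The closure is simulated with position-based dynamics: every frame the
#' free-edge vertices are driven kinematically towards the coaptation
#' mid-plane (their mid-plane coordinate scales down by a common closing
#' factor), edge-length and cross-edge bending constraints are projected for
#' a fixed number of solver sweeps, and the annulus vertices are re-pinned
#' exactly.  Constraint projection uses vertex-disjoint constraint groups
#' (graph colouring) with immediate Gauss-Seidel updates: deterministic and
#' independent of storage order.
#'
#' @param n_frames number of output frames per valve closure (default 180).
#' @param solver_iterations constraint-projection sweeps per frame.
#' @param stiffness named numeric in `[0, 1]`: `edge` and `bend`.
#' @param closing_drive displacement magnitude towards the mid-plane, mm per
#'   frame, applied to free vertices.
#' @param fixed_vertex_ids pinned vertex indices; default: the annulus ring.
#' @param coaptation_tol mm; at the final frame every free-edge vertex must
#'   be within this distance of the opposing free edge, otherwise a warning
#'   is raised.
#' @param jitter_sigma optional Gaussian position jitter (mm) added to the
#'   prediction step; 0 disables it and makes the solver fully deterministic.
#' @param seed RNG seed, only consumed when `jitter_sigma > 0`.
#' @param trace if `TRUE`, record the RMS edge strain after every solver
#'   sweep (returned as attribute `residuals`).
#' @return a `pbd_config` list.
#' @export
pbd_config <- function(n_frames = 180L, solver_iterations = 20L,
                       stiffness = c(edge = 1, bend = 0.1),
                       closing_drive = 0.05, fixed_vertex_ids = NULL,
                       coaptation_tol = 0.5, jitter_sigma = 0, seed = NULL,
                       trace = FALSE) {
  n_frames <- as.integer(n_frames)
  solver_iterations <- as.integer(solver_iterations)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (solver_iterations < 1L) stop("solver_iterations must be >= 1")
  if (any(stiffness < 0 | stiffness > 1)) stop("stiffness must be in [0, 1]")
  if (closing_drive < 0) stop("closing_drive must be >= 0")
  structure(list(n_frames = n_frames, solver_iterations = solver_iterations,
                 stiffness = stiffness, closing_drive = closing_drive,
                 fixed_vertex_ids = fixed_vertex_ids,
                 coaptation_tol = coaptation_tol,
                 jitter_sigma = jitter_sigma, seed = seed, trace = trace),
            class = "pbd_config")
}

#' Simulate valve closure
#'
#' Runs the position-based dynamics closure and returns the motion as a
#' sequence of vertex-position frames over the fixed mesh topology.  Frame 1
#' is the open input state; the annulus stays exactly fixed; free vertices
#' never cross the coaptation mid-plane (mid-plane barrier) and never retreat
#' from it, which makes the closure monotone.
#'
#' @param mesh a `valve_mesh` (open state).
#' @param config a [pbd_config()].
#' @return a `motion_sequence`: list with `frames` (list of n x 3 matrices),
#'   `frame_times` in `[0, 1]`, and the template `mesh`.
#' @export
simulate_closure <- function(mesh, config = pbd_config()) {
  if (!inherits(mesh, "valve_mesh")) stop("mesh must be a valve_mesh")
  nv <- nrow(mesh$vertices)
  fixed <- config$fixed_vertex_ids %||% unique(unlist(mesh$annulus_row_ids))
  fixed <- as.integer(fixed)
  if (any(fixed < 1L | fixed > nv)) stop("fixed_vertex_ids out of range")

  V0 <- mesh$vertices
  e2 <- mesh$frame[, 2L]
  center <- mesh$center
  sgn <- ifelse(mesh$vertex_leaflet == "anterior", 1, -1)
  free <- setdiff(seq_len(nv), fixed)
  w <- rep(1, nv)
  w[fixed] <- 0

  et <- mesh_edge_table(mesh$faces)
  if (any(et$count > 2L)) stop("mesh has non-manifold edges")
  edges <- cbind(et$v1, et$v2)
  bend <- bending_pairs(mesh$faces, et)
  constraints <- rbind(edges, bend)
  ctype <- c(rep("edge", nrow(edges)), rep("bend", nrow(bend)))
  rest <- sqrt(rowSums((V0[constraints[, 1L], , drop = FALSE] -
                          V0[constraints[, 2L], , drop = FALSE])^2))
  k_iter <- 1 - (1 - config$stiffness)^(1 / config$solver_iterations)
  kvec <- unname(k_iter[ctype])
  # Greedy graph colouring of the constraints: no two constraints in one
  # colour share a vertex, so each colour can be projected vectorised with
  # immediate (Gauss-Seidel) effect between colours.  Deterministic.
  colors <- color_constraints(constraints, nv)

  if (config$jitter_sigma > 0 && !is.null(config$seed)) set.seed(config$seed)

  # The kinematic drive acts on the leading (free) edge only; the leaflet
  # body follows through the constraints, which turns the drive into a
  # rotation about the annulus hinge instead of a flattening squash.
  driven <- setdiff(unique(unlist(mesh$free_edge_vertex_ids)), fixed)
  V <- V0
  s_prev <- pmax(sgn * drop((V - matrix(center, nv, 3L, byrow = TRUE)) %*% e2), 0)
  s0 <- s_prev[driven]
  frames <- vector("list", config$n_frames)
  frames[[1L]] <- V
  residuals <- if (config$trace) vector("list", config$n_frames) else NULL
  i1 <- constraints[, 1L]
  i2 <- constraints[, 2L]
  w1 <- w[i1]
  w2 <- w[i2]
  wsum <- pmax(w1 + w2, 1e-300)

  for (fr in 2:config$n_frames) {
    # Predict: kinematic drive of the free edge towards the coaptation
    # plane.  Each driven vertex scales its initial mid-plane coordinate by
    # a common closing factor, so the free edge keeps its shape while its
    # leading point moves at closing_drive mm/frame; the coordinate is
    # prescribed (re-imposed after every solver sweep) and the constraints
    # shape the remaining degrees of freedom.
    lambda <- max(0, 1 - (fr - 1L) * config$closing_drive / max(s0, 1e-12))
    s_target <- pmin(s0 * lambda, s_prev[driven])
    s <- sgn * drop(sweep(V, 2L, center) %*% e2)
    V[driven, ] <- V[driven, ] +
      ((s_target - s[driven]) * sgn[driven]) * matrix(e2, length(driven), 3L,
                                                      byrow = TRUE)
    if (config$jitter_sigma > 0) {
      J <- matrix(stats::rnorm(3L * length(free), 0, config$jitter_sigma),
                  ncol = 3L)
      V[free, ] <- V[free, ] + J
    }
    res_fr <- numeric(0)
    for (it in seq_len(config$solver_iterations)) {
      for (grp in colors) {
        g1 <- i1[grp]
        g2 <- i2[grp]
        d <- V[g2, , drop = FALSE] - V[g1, , drop = FALSE]
        len <- pmax(sqrt(rowSums(d * d)), 1e-12)
        corr <- (kvec[grp] * (len - rest[grp]) / len) * d
        V[g1, ] <- V[g1, ] + (w1[grp] / wsum[grp]) * corr
        V[g2, ] <- V[g2, ] - (w2[grp] / wsum[grp]) * corr
      }
      # Re-impose the prescribed free-edge coordinate.
      sd_ <- sgn[driven] * drop(sweep(V[driven, , drop = FALSE], 2L, center) %*% e2)
      V[driven, ] <- V[driven, ] +
        ((s_target - sd_) * sgn[driven]) * matrix(e2, length(driven), 3L,
                                                  byrow = TRUE)
      if (config$trace) {
        de <- V[edges[, 2L], , drop = FALSE] - V[edges[, 1L], , drop = FALSE]
        le <- sqrt(rowSums(de * de))
        re <- rest[seq_len(nrow(edges))]
        res_fr <- c(res_fr, sqrt(mean(((le - re) / re)^2)))
      }
    }
    # Mid-plane barrier for every free vertex; monotone approach (no
    # retreat from the plane) for the driven free edge.
    s <- sgn * drop(sweep(V, 2L, center) %*% e2)
    s_cl <- pmax(s, 0)
    s_cl[driven] <- pmin(s_cl[driven], s_prev[driven])
    adj <- s_cl - s
    adj[fixed] <- 0
    V <- V + (adj * sgn) %o% e2
    s_prev[driven] <- pmax(sgn[driven] * drop(sweep(V[driven, , drop = FALSE],
                                                    2L, center) %*% e2), 0)
    V[fixed, ] <- V0[fixed, ]
    if (anyNA(V) || any(!is.finite(V))) {
      stop(sprintf("divergence: non-finite vertex positions at frame %d", fr))
    }
    frames[[fr]] <- V
    if (config$trace) residuals[[fr]] <- res_fr
  }

  # Coaptation check on the last frame.
  gap <- coaptation_gap(mesh, frames[[config$n_frames]])
  if (gap > config$coaptation_tol) {
    warning(sprintf(
      "valve not fully coapted after %d frames (max free-edge gap %.2f mm > %.2f mm)",
      config$n_frames, gap, config$coaptation_tol))
  }

  seq <- structure(list(frames = frames,
                        frame_times = seq(0, 1, length.out = config$n_frames),
                        mesh = mesh, config = config),
                   class = "motion_sequence")
  if (config$trace) attr(seq, "residuals") <- residuals
  seq
}

# Max distance from each free-edge vertex to the opposing free-edge polyline.
coaptation_gap <- function(mesh, V) {
  ant <- V[mesh$free_edge_vertex_ids$anterior, , drop = FALSE]
  pos <- V[mesh$free_edge_vertex_ids$posterior, , drop = FALSE]
  g1 <- max(vapply(seq_len(nrow(ant)),
                   function(i) point_polyline_distance(ant[i, ], pos), 0))
  g2 <- max(vapply(seq_len(nrow(pos)),
                   function(i) point_polyline_distance(pos[i, ], ant), 0))
  max(g1, g2)
}

# Cross-edge bending pairs: for every interior edge, the two opposite
# vertices of the adjacent triangles.
bending_pairs <- function(faces, et = mesh_edge_table(faces)) {
  key_of <- function(a, b) paste(pmin(a, b), pmax(a, b))
  nf <- nrow(faces)
  ekeys <- c(key_of(faces[, 1L], faces[, 2L]),
             key_of(faces[, 2L], faces[, 3L]),
             key_of(faces[, 3L], faces[, 1L]))
  eface <- rep(seq_len(nf), times = 3L)
  interior <- et$count == 2L
  if (!any(interior)) return(matrix(integer(0), 0L, 2L))
  ikeys <- paste(et$v1[interior], et$v2[interior])
  byface <- split(eface, ekeys)[ikeys]
  v1 <- et$v1[interior]
  v2 <- et$v2[interior]
  out <- matrix(0L, length(ikeys), 2L)
  for (i in seq_along(ikeys)) {
    fs <- byface[[i]]
    out[i, 1L] <- setdiff(faces[fs[1L], ], c(v1[i], v2[i]))[1L]
    out[i, 2L] <- setdiff(faces[fs[2L], ], c(v1[i], v2[i]))[1L]
  }
  out
}

# Greedy constraint colouring: returns a list of constraint-index vectors,
# each vertex-disjoint, in deterministic order.
color_constraints <- function(constraints, nv) {
  nc <- nrow(constraints)
  color <- integer(nc)
  used_in <- list()
  for (c in seq_len(nc)) {
    v <- constraints[c, ]
    k <- 1L
    repeat {
      if (k > length(used_in)) {
        used_in[[k]] <- logical(nv)
      }
      if (!used_in[[k]][v[1L]] && !used_in[[k]][v[2L]]) break
      k <- k + 1L
    }
    color[c] <- k
    used_in[[k]][v] <- TRUE
  }
  split(seq_len(nc), color)
}

#' Temporal downsampling of a motion sequence
#'
#' Reduces the closure to the temporal resolution of the imaging experiment
#' (10 timesteps per valve closure by default in the study pipeline).
#' `decimate` keeps frames at evenly spaced indices including both endpoints;
#' `window_average` averages vertex positions over contiguous equal windows,
#' emulating temporal partial-volume blur.
#'
#' @param seq a `motion_sequence`.
#' @param n_out number of output frames, `2 <= n_out <= n_frames`.
#' @param mode `"decimate"` or `"window_average"`.
#' @return a `motion_sequence` with `n_out` frames.
#' @export
temporal_downsample <- function(seq, n_out, mode = c("decimate", "window_average")) {
  mode <- match.arg(mode)
  if (!inherits(seq, "motion_sequence")) stop("seq must be a motion_sequence")
  n <- length(seq$frames)
  n_out <- as.integer(n_out)
  if (n_out < 2L || n_out > n) {
    stop(sprintf("parameter error: n_out must be in [2, %d]", n))
  }
  if (n_out == n) return(seq)
  if (mode == "decimate") {
    idx <- round(seq.int(1L, n, length.out = n_out))
    frames <- seq$frames[idx]
    times <- seq$frame_times[idx]
  } else {
    bounds <- round(seq.int(0L, n, length.out = n_out + 1L))
    frames <- vector("list", n_out)
    times <- numeric(n_out)
    for (k in seq_len(n_out)) {
      win <- (bounds[k] + 1L):bounds[k + 1L]
      frames[[k]] <- Reduce(`+`, seq$frames[win]) / length(win)
      times[k] <- mean(seq$frame_times[win])
    }
  }
  structure(list(frames = frames, frame_times = times, mesh = seq$mesh,
                 config = seq$config),
            class = "motion_sequence")
}

#' Extract the valve mesh at a given frame of a motion sequence
#' @param seq a `motion_sequence`.
#' @param frame frame index (1-based).
#' @return a `valve_mesh` with that frame's vertex positions.
#' @export
mesh_at_frame <- function(seq, frame) {
  mesh <- seq$mesh
  mesh$vertices <- seq$frames[[frame]]
  mesh
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("Motion sequence: %d frames, %d vertices\n",
              length(x$frames), nrow(x$frames[[1L]])))
  invisible(x)
}
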