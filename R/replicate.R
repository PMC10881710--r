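#' Replicate the sampling-strategy comparison end to end
#'
#' Full study loop on one phantom case: anatomy generation, valve closure
#' simulation, optional synthetic image stacks for every strategy, three
#' simulated annotators per strategy, and the complete evaluation: the five
#' quantitative parameters and their bias against ground truth, annulus and
#' orifice contour-distance reports, and point-to-surface distances.
#'
#' @param phantom_config config for [build_phantom()].
#' @param strategies strategies to compare.
#' @param annotator_config list: `noise_sigma_mm` (default 1.5),
#'   `detection_miss_rate` (default 0), `n_annotators` (default 3).
#' @param seed study seed (drives every stochastic stage).
#' @param n_timeframes imaging temporal resolution.
#' @param annotate_frame which downsampled timeframe is annotated
#'   (default 1 = open valve, where the orifice is well defined).
#' @param with_images also run the image synthesis ([simulate_study()]);
#'   the geometric evaluation itself operates on plane-valve intersections.
#' @param pbd a [pbd_config()] for the closure.
#' @param out_dir optional output directory for CSV reports, boxplots and
#'   distance glyphs.
#' @param ... further arguments passed to [simulate_study()].
#' @return `mv_study_report` list: `params` (long data.frame: strategy,
#'   annotator, parameter, value, gt_value), `bias` (strategy, parameter,
#'   bias), `distances` (strategy, annotator, metric, mean, sd, ...),
#'   `reports` (nested distance_report objects), `gt` (ground-truth
#'   `quant_params`), `phantom`, `motion`, and `study` when images were
#'   simulated.
#' @export
replicate_study <- function(phantom_config = list(),
                            strategies = c("SAX", "rLAX6", "rLAX9", "rLAX18"),
                            annotator_config = list(), seed = 1L,
                            n_timeframes = 10L, annotate_frame = 1L,
                            with_images = FALSE, pbd = pbd_config(),
                            out_dir = NULL, ...) {
  noise <- annotator_config$noise_sigma_mm %||% 1.5
  miss <- annotator_config$detection_miss_rate %||% 0
  n_ann <- annotator_config$n_annotators %||% 3L

  phantom <- build_phantom(phantom_config)
  motion <- simulate_closure(phantom$mesh, pbd)
  n_timeframes <- min(n_timeframes, length(motion$frames))
  study <- NULL
  if (with_images) {
    study <- simulate_study(phantom, motion, strategies = strategies,
                            n_timeframes = n_timeframes, seed = seed, ...)
    motion_t <- study$motion
  } else {
    motion_t <- temporal_downsample(motion, n_timeframes, "window_average")
  }
  mesh_t <- mesh_at_frame(motion_t, annotate_frame)
  va <- compute_valve_axis(mesh_t)
  gt <- quantify_valve(mesh_t)
  gt_annulus <- generate_annulus(phantom$annulus, n_samples = 2000L)
  gt_orifice <- mesh_orifice_curve(mesh_t)

  params <- list()
  bias <- list()
  dist_rows <- list()
  reports <- list()
  pnames <- c("d_max", "d_min", "height", "annulus_area", "orifice_area")

  for (st in strategies) {
    planes <- if (st == "SAX") {
      define_sax_planes(va$axis, va$center)
    } else {
      define_rlax_planes(va$axis, va$center,
                         n_planes = as.integer(sub("rLAX", "", st)))
    }
    ann <- simulate_annotators(mesh_t, planes, noise_sigma_mm = noise,
                               detection_miss_rate = miss,
                               seed = derive_seed(seed, st),
                               n_annotators = n_ann)
    reports[[st]] <- list()
    vals <- matrix(NA_real_, n_ann, length(pnames),
                   dimnames = list(NULL, pnames))
    for (a in seq_len(n_ann)) {
      da <- ann[ann$annotator == a, , drop = FALSE]
      qp <- tryCatch(quantify_valve(da), error = function(e) NULL)
      if (!is.null(qp)) vals[a, ] <- unlist(qp[pnames])
      pts <- function(str) as.matrix(da[da$structure == str,
                                        c("x", "y", "z"), drop = FALSE])
      rep_a <- list(
        annulus = contour_distance(pts("annulus"), gt_annulus, closed = TRUE),
        orifice = if (nrow(pts("orifice")) > 0L) {
          contour_distance(pts("orifice"), gt_orifice, closed = TRUE)
        },
        surface = point_to_surface_distance(
          as.matrix(da[, c("x", "y", "z")]), mesh_t))
      reports[[st]][[a]] <- rep_a
      for (metric in names(rep_a)) {
        r <- rep_a[[metric]]
        if (is.null(r)) next
        dist_rows[[length(dist_rows) + 1L]] <- data.frame(
          strategy = st, annotator = a, metric = metric,
          t(r$summary), n = length(r$distances))
      }
      params[[length(params) + 1L]] <- data.frame(
        strategy = st, annotator = a, parameter = pnames,
        value = unname(vals[a, ]), gt_value = unlist(gt[pnames]))
    }
    for (p in pnames) {
      ok <- !is.na(vals[, p])
      bias[[length(bias) + 1L]] <- data.frame(
        strategy = st, parameter = p,
        bias = if (any(ok)) param_bias(vals[ok, p], gt[[p]]) else NA_real_,
        n_annotators = sum(ok))
    }
  }

  report <- structure(
    list(params = do.call(rbind, params), bias = do.call(rbind, bias),
         distances = do.call(rbind, dist_rows), reports = reports,
         gt = gt, phantom = phantom, motion = motion_t, study = study,
         seed = seed),
    class = "mv_study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.mv_study_report <- function(x, ...) {
  cat("Sampling-strategy study report\nGround truth: ")
  print(x$gt)
  agg <- stats::aggregate(mean ~ strategy + metric, data = x$distances, FUN = mean)
  cat("Mean contour / surface distances (mm), averaged over annotators:\n")
  print(stats::reshape(agg, idvar = "metric", timevar = "strategy",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}
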