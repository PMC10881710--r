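#' Write a study report to disk
#'
#' Writes the long-format parameter table, the bias table and the distance
#' summaries as CSV, per-metric boxplots as PNG, and the annotated points as
#' distance-coded PLY glyphs for external viewers.
#'
#' @param report an `mv_study_report` from [replicate_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$params, file.path(out_dir, "params.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bias, file.path(out_dir, "bias.csv"),
                   row.names = FALSE)
  utils::write.csv(report$distances, file.path(out_dir, "distances.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, gt = unclass(report$gt),
         bias = report$bias, package = "mvphantom",
         version = as.character(utils::packageVersion("mvphantom"))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  for (metric in c("annulus", "orifice", "surface")) {
    plot_distance_boxplots(report, metric,
                           file.path(out_dir, sprintf("%s_distances.png", metric)))
  }
  invisible(out_dir)
}

#' Boxplots of contour / surface distances per strategy
#'
#' @param report an `mv_study_report`.
#' @param metric `"annulus"`, `"orifice"` or `"surface"`.
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @return invisibly, the per-strategy distance list.
#' @export
plot_distance_boxplots <- function(report, metric = "annulus", file = NULL) {
  data <- list()
  for (st in names(report$reports)) {
    d <- unlist(lapply(report$reports[[st]], function(r)
      if (!is.null(r[[metric]])) r[[metric]]$distances))
    if (length(d) > 0L) data[[st]] <- d
  }
  if (length(data) == 0L) return(invisible(data))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(data, ylab = "distance to ground truth [mm]",
                    main = sprintf("%s distances by sampling strategy", metric),
                    col = "grey85")
  invisible(data)
}

#' Export distance-coded point glyphs as PLY
#'
#' Writes annotated points with a per-vertex `quality` scalar holding the
#' point's distance, for colour-coded display in external mesh viewers.
#'
#' @param points n x 3 matrix, world mm.
#' @param distances numeric vector of per-point distances.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_distance_glyphs <- function(points, distances, path) {
  P <- as_points_matrix(points)
  if (length(distances) != nrow(P)) stop("one distance per point required")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(P)),
               "property float x", "property float y", "property float z",
               "property float quality",
               "element face 0",
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %.9g", P[, 1L], P[, 2L], P[, 3L],
                     distances), con)
  invisible(path)
}
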