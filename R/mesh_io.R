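#' Write / read a triangle mesh (ASCII PLY or OBJ)
#'
#' Plain-text Stanford PLY or Wavefront OBJ, chosen by file extension.  The
#' valve-specific vertex sets (annulus ring, free edges) travel in a JSON
#' sidecar `<path>.json` with 0-based indices:
#' `{"annulus_vertex_ids": [...], "free_edge_vertex_ids": {"anterior": [...],
#' "posterior": [...]}}`.
#'
#' @param mesh a `valve_mesh` (or list with `vertices`/`faces`).
#' @param path output file ending in `.ply` or `.obj`.
#' @param sidecar write the marker sidecar (default `TRUE` for valve meshes).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, sidecar = inherits(mesh, "valve_mesh")) {
  V <- mesh$vertices
  F <- mesh$faces
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1L], V[, 2L], V[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1L] - 1L, F[, 2L] - 1L, F[, 3L] - 1L),
               con)
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1L], V[, 2L], V[, 3L]), con)
    writeLines(sprintf("f %d %d %d", F[, 1L], F[, 2L], F[, 3L]), con)
  } else {
    stop("unsupported mesh format: ", path)
  }
  if (sidecar) {
    jsonlite::write_json(
      list(annulus_vertex_ids = mesh$annulus_vertex_ids - 1L,
           free_edge_vertex_ids = lapply(mesh$free_edge_vertex_ids,
                                         function(i) i - 1L)),
      paste0(path, ".json"))
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                     lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face",
                                                   lines, value = TRUE)))
    body <- which(lines == "end_header") + 1L
    V <- matrix(scan(text = lines[body:(body + nv - 1L)], quiet = TRUE),
                nv, 3L, byrow = TRUE)
    fl <- matrix(scan(text = lines[(body + nv):(body + nv + nf - 1L)],
                      quiet = TRUE), nf, 4L, byrow = TRUE)
    F <- fl[, 2:4, drop = FALSE] + 1L
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    vl <- grep("^v ", lines, value = TRUE)
    fs <- grep("^f ", lines, value = TRUE)
    V <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
                length(vl), 3L, byrow = TRUE)
    F <- matrix(as.integer(unlist(lapply(strsplit(sub("^f ", "", fs), " "),
                                         function(x) sub("/.*", "", x)))),
                length(fs), 3L, byrow = TRUE)
  } else {
    stop("unsupported mesh format: ", path)
  }
  mesh <- list(vertices = V, faces = matrix(as.integer(F), ncol = 3L))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mesh$annulus_vertex_ids <- as.integer(sc$annulus_vertex_ids) + 1L
    mesh$free_edge_vertex_ids <- lapply(sc$free_edge_vertex_ids,
                                        function(i) as.integer(i) + 1L)
    class(mesh) <- "valve_mesh"
  }
  mesh
}

#' Persist a motion sequence as one PLY per frame plus a JSON manifest
#' @param seq a `motion_sequence`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_motion_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq$frames)
  files <- sprintf("frame_%03d.ply", seq_len(n))
  for (k in seq_len(n)) {
    m <- mesh_at_frame(seq, k)
    write_mesh(m, file.path(dir, files[k]), sidecar = (k == 1L))
  }
  manifest <- list(frames = files, frame_times = seq$frame_times,
                   config_hash = config_hash(seq$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

# Polynomial rolling hash of a serialised R object (provenance fingerprint).
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
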