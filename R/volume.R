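#' Labelled 3D volume
#'
#' Container for a 3D integer label grid plus the voxel-to-world affine
#' (0-based voxel index `(i, j, k, 1)` maps to world mm) and a name-to-integer
#' label map.
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param label_map named integer vector covering every nonzero value.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, affine, label_map) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    stop("affine must be an invertible 4x4 matrix")
  }
  if (any(sqrt(colSums(affine[1:3, 1:3]^2)) <= 0)) stop("voxel size must be positive")
  label_map <- structure(as.integer(label_map), names = names(label_map))
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% label_map)) {
    stop("every nonzero voxel value must exist in label_map")
  }
  structure(list(labels = labels, affine = affine, label_map = label_map),
            class = "label_volume")
}

# Centred axis-aligned affine for a given grid shape and voxel spacing.
centered_affine <- function(shape, spacing) {
  spacing <- rep(spacing, length.out = 3L)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4L] <- -(shape - 1) / 2 * spacing
  aff
}

voxel_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# World coordinates (n x 3) of 0-based voxel indices (n x 3).
voxel_to_world <- function(idx, affine) {
  cbind(idx, 1) %*% t(affine)[, 1:3]
}

world_to_voxel <- function(pts, affine) {
  cbind(as_points_matrix(pts), 1) %*% t(solve(affine))[, 1:3]
}

#' Rasterize a surface mesh into a label volume
#'
#' Voxels whose centre lies within `thickness / 2` of the triangulated
#' surface receive `label`; all other voxels are unchanged.  Distances are
#' exact point-to-triangle distances (correctness over speed at the ~1 mm
#' scale of the valve), evaluated only inside each triangle's dilated
#' bounding box.
#'
#' @param mesh a `valve_mesh` (any list with `vertices`/`faces`).
#' @param template a [label_volume()]; returned with the surface burnt in.
#' @param thickness surface thickness in mm (default 1, the thin-leaflet
#'   voxelization thickness).
#' @param label integer label value (or a name present in the template's
#'   `label_map`).
#' @param overwrite label values that may be overwritten in addition to
#'   background 0.  Default: the blood-pool cavity labels, so the thin valve
#'   is not swallowed by the surrounding cavities but never eats into walls.
#' @return the modified `label_volume`.
#' @export
rasterize_surface <- function(mesh, template, thickness = 1, label = "mitral_valve",
                              overwrite = c("la_cavity", "lv_cavity")) {
  if (!inherits(template, "label_volume")) stop("template must be a label_volume")
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  if (is.character(label)) {
    if (!label %in% names(template$label_map)) {
      stop(sprintf("label '%s' not in template label_map", label))
    }
    label <- template$label_map[[label]]
  }
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) return(template)

  dims <- dim(template$labels)
  vox <- world_to_voxel(mesh$vertices, template$affine)
  out_of_bounds <- which(apply(vox < -0.5 | vox > matrix(dims - 0.5, nrow(vox), 3L,
                                                         byrow = TRUE), 1L, any))
  if (length(out_of_bounds) > 0L) {
    stop(sprintf("mesh outside volume bounds: vertices %s",
                 paste(utils::head(out_of_bounds, 10L), collapse = ", ")))
  }

  allowed <- 0L
  if (length(overwrite) > 0L) {
    ov <- overwrite
    if (is.character(ov)) ov <- template$label_map[intersect(ov, names(template$label_map))]
    allowed <- c(allowed, as.integer(ov))
  }

  half <- thickness / 2
  spacing <- voxel_spacing(template$affine)
  margin <- half + max(spacing)
  hit <- array(FALSE, dims)
  V <- mesh$vertices
  F <- mesh$faces
  for (f in seq_len(nrow(F))) {
    tri <- V[F[f, ], , drop = FALSE]
    lo <- apply(tri, 2L, min) - margin
    hi <- apply(tri, 2L, max) + margin
    corners <- as.matrix(expand.grid(c(lo[1L], hi[1L]), c(lo[2L], hi[2L]),
                                     c(lo[3L], hi[3L])))
    vc <- world_to_voxel(corners, template$affine)
    i0 <- pmax(0L, floor(apply(vc, 2L, min)))
    i1 <- pmin(dims - 1L, ceiling(apply(vc, 2L, max)))
    if (any(i1 < i0)) next
    ii <- seq.int(i0[1L], i1[1L])
    jj <- seq.int(i0[2L], i1[2L])
    kk <- seq.int(i0[3L], i1[3L])
    idx <- as.matrix(expand.grid(ii, jj, kk))
    sub <- hit[idx + 1L]
    todo <- !sub
    if (!any(todo)) next
    pts <- voxel_to_world(idx[todo, , drop = FALSE], template$affine)
    d2 <- point_triangle_dist2(pts, tri[1L, ], tri[2L, ], tri[3L, ])$dist2
    sub[todo] <- d2 <= half^2
    hit[idx + 1L] <- sub
  }
  writable <- hit & array(template$labels %in% allowed, dims)
  template$labels[writable] <- as.integer(label)
  template
}

#' Trilinear sampling of a volume at world points
#'
#' @param volume 3D numeric array.
#' @param affine 4x4 voxel-to-world affine.
#' @param points n x 3 world coordinates (mm).
#' @param fill value for points outside the volume.
#' @return numeric vector of interpolated values.
#' @export
sample_volume <- function(volume, affine, points, fill = 0) {
  dims <- dim(volume)
  v <- world_to_voxel(points, affine)
  x <- v[, 1L]; y <- v[, 2L]; z <- v[, 3L]
  inside <- x >= 0 & x <= dims[1L] - 1 & y >= 0 & y <= dims[2L] - 1 &
    z >= 0 & z <= dims[3L] - 1 & is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(fill, nrow(v))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  i0 <- pmin(floor(x), dims[1L] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(y), dims[2L] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(z), dims[3L] - 2); k0 <- pmax(k0, 0)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  n1 <- dims[1L]; n12 <- dims[1L] * dims[2L]
  base <- i0 + j0 * n1 + k0 * n12 + 1
  v000 <- volume[base]
  v100 <- volume[base + 1]
  v010 <- volume[base + n1]
  v110 <- volume[base + n1 + 1]
  v001 <- volume[base + n12]
  v101 <- volume[base + n12 + 1]
  v011 <- volume[base + n12 + n1]
  v111 <- volume[base + n12 + n1 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Write / read a label volume as NIfTI-1
#'
#' The integer grid is stored in a `.nii`/`.nii.gz` with the affine in the
#' sform; the label map travels in a JSON sidecar (`<path>.labels.json`).
#'
#' @param volume a [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$labels, datatype = "int16")
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(volume$label_map),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  sidecar <- paste0(path, ".labels.json")
  if (!file.exists(sidecar)) stop("label map sidecar not found: ", sidecar)
  lm <- unlist(jsonlite::read_json(sidecar))
  label_volume(array(as.integer(img), dim(img)), aff,
               structure(as.integer(lm), names = names(lm)))
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume %s, spacing %s mm, %d labels\n",
              paste(dim(x$labels), collapse = " x "),
              paste(signif(voxel_spacing(x$affine), 3), collapse = " x "),
              length(x$label_map)))
  invisible(x)
}
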