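#' Tissue intensity model
#'
#' Per-entity Gaussian intensity distributions (mean, sd) used to turn the
#' label volume into an MR-style intensity volume.  The default table holds
#' the cine-MRI values observed for each anatomical entity; a Rician noise
#' model was considered for the source data but the per-tissue distributions
#' are modelled as Gaussian (the fitted difference is negligible at these
#' signal levels), and Gaussian is what this package samples.
#'
#' @param table data.frame with columns `entity`, `mean`, `sd`.
#' @param background intensity assigned to unlabelled voxels, `c(mean, sd)`.
#' @return object of class `intensity_model`.
#' @export
intensity_model <- function(table = default_intensity_table(),
                            background = c(0, 0)) {
  req <- c("entity", "mean", "sd")
  if (!all(req %in% names(table))) stop("table needs columns entity, mean, sd")
  if (any(table$sd < 0) || background[2L] < 0) stop("sd must be >= 0")
  if (anyDuplicated(table$entity)) stop("duplicate entity in intensity table")
  structure(list(table = table, background = as.numeric(background)),
            class = "intensity_model")
}

#' Default tissue intensity table
#'
#' Mean and standard deviation of the observed cine-MRI signal for every
#' entity of the anatomical model.
#' @return data.frame with columns `entity`, `mean`, `sd`.
#' @export
default_intensity_table <- function() {
  data.frame(
    entity = c("mitral_valve", "la_wall", "la_cavity", "lv_myocardium",
               "lv_cavity", "ra_wall", "ra_cavity", "rv_wall", "rv_cavity",
               "aorta", "bones", "liver", "kidney", "lung", "bronchi"),
    mean = c(266, 100, 357, 75, 344, 88, 405, 71, 356,
             330, 157, 119, 126, 8, 389),
    sd = c(25, 38, 14, 8, 23, 32, 26, 25, 15,
           22, 72, 47, 14, 4, 42))
}

#' Read / write an intensity model as CSV or JSON
#' @param path file ending in `.csv` or `.json`.
#' @param model an [intensity_model()] (for writing).
#' @return an `intensity_model` / the path, invisibly.
#' @export
read_intensity_model <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    intensity_model(as.data.frame(obj$table),
                    background = obj$background %||% c(0, 0))
  } else {
    intensity_model(utils::read.csv(path))
  }
}

#' @rdname read_intensity_model
#' @export
write_intensity_model <- function(model, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(table = model$table,
                              background = model$background),
                         path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(model$table, path, row.names = FALSE)
  }
  invisible(path)
}

#' Assign tissue intensities to a label volume
#'
#' Every voxel draws independently from `Normal(mean_label, sd_label)`.
#' With `sd = 0` the output is exactly piecewise constant at the label means.
#'
#' @param labels a [label_volume()].
#' @param model an [intensity_model()]; must cover every label present.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `data` (3D numeric array) and `affine` (class
#'   `mv_volume`).
#' @export
assign_intensities <- function(labels, model = intensity_model(), seed = NULL) {
  if (!inherits(labels, "label_volume")) stop("labels must be a label_volume")
  if (!inherits(model, "intensity_model")) stop("model must be an intensity_model")
  if (!is.null(seed)) set.seed(seed)
  present <- setdiff(unique(as.vector(labels$labels)), 0L)
  lm <- labels$label_map
  entities <- names(lm)[match(present, lm)]
  missing <- entities[!entities %in% model$table$entity]
  if (length(missing) > 0L) {
    stop("intensity model has no entry for label(s): ",
         paste(missing, collapse = ", "))
  }
  vol <- array(0, dim(labels$labels))
  bg <- labels$labels == 0L
  nbg <- sum(bg)
  if (nbg > 0L && model$background[2L] > 0) {
    vol[bg] <- stats::rnorm(nbg, model$background[1L], model$background[2L])
  } else if (nbg > 0L) {
    vol[bg] <- model$background[1L]
  }
  for (i in seq_along(present)) {
    row <- model$table[model$table$entity == entities[i], ]
    m <- labels$labels == present[i]
    nm <- sum(m)
    vol[m] <- if (row$sd > 0) stats::rnorm(nm, row$mean, row$sd) else row$mean
  }
  structure(list(data = vol, affine = labels$affine), class = "mv_volume")
}

#' Additive Gaussian image noise
#'
#' Adds independent zero-mean Gaussian noise to every voxel.  The default
#' `sigma = 38` is the maximum standard deviation among the heart-entity
#' intensity distributions.
#'
#' @param volume an `mv_volume` (from [assign_intensities()]) or 3D array.
#' @param sigma noise standard deviation in intensity units (`>= 0`).
#' @param seed optional RNG seed.
#' @return same type as `volume`.
#' @export
add_noise <- function(volume, sigma = 38, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("parameter error: sigma must be >= 0")
  if (sigma == 0) return(volume)
  if (!is.null(seed)) set.seed(seed)
  arr <- if (inherits(volume, "mv_volume")) volume$data else volume
  arr <- arr + stats::rnorm(length(arr), 0, sigma)
  if (inherits(volume, "mv_volume")) {
    volume$data <- arr
    volume
  } else {
    arr
  }
}

#' Gaussian reconstruction smoothing
#'
#' Separable Gaussian convolution emulating the filtering applied during MR
#' image reconstruction.  The kernel width is given in millimetres and
#' converted per axis to voxels, so anisotropic voxel sizes are honoured.
#' Kernel weights are renormalised at the borders, making constant volumes
#' exact fixed points.
#'
#' @param volume an `mv_volume` or 3D array.
#' @param kernel_sigma_mm Gaussian sigma in mm (`>= 0`; 0 is the identity).
#' @param spacing voxel spacing in mm (scalar or length 3); taken from the
#'   affine when `volume` is an `mv_volume`.
#' @return same type as `volume`.
#' @export
smooth_volume <- function(volume, kernel_sigma_mm = 0.7, spacing = NULL) {
  if (!is.finite(kernel_sigma_mm) || kernel_sigma_mm < 0) {
    stop("kernel_sigma_mm must be >= 0")
  }
  if (kernel_sigma_mm == 0) return(volume)
  is_mv <- inherits(volume, "mv_volume")
  arr <- if (is_mv) volume$data else volume
  sp <- if (is_mv) voxel_spacing(volume$affine) else
    rep(spacing %||% 1, length.out = 3L)
  dims <- dim(arr)
  for (ax in 1:3) {
    sig <- kernel_sigma_mm / sp[ax]
    if (sig <= 0) next
    K <- gaussian_operator(dims[ax], sig)
    arr <- apply_axis_operator(arr, K, ax)
  }
  if (is_mv) {
    volume$data <- arr
    volume
  } else {
    arr
  }
}

# Dense banded Gaussian convolution operator with row renormalisation.
gaussian_operator <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  i <- matrix(seq_len(n), n, n)
  d <- i - t(i)
  K <- exp(-d^2 / (2 * sigma_vox^2))
  K[abs(d) > r] <- 0
  K / rowSums(K)
}

# Multiply a 3D array by a matrix operator along one axis.
apply_axis_operator <- function(arr, K, axis) {
  dims <- dim(arr)
  perm <- list(c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))[[axis]]
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- K %*% matrix(a, da[1L], da[2L] * da[3L])
  dim(m) <- da
  aperm(m, order(perm))
}
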