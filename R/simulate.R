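#' Simulate the multi-slice imaging study
#'
#' Runs the synthetic image generation workflow on a phantom and its valve
#' motion: temporal sampling of the closure to the imaging frame rate,
#' per-timeframe rasterization of the moving valve into the labelled
#' anatomy, intensity assignment, additive Gaussian noise, reconstruction
#' smoothing, slice-plane definition per sampling strategy, slab sampling
#' with through-plane averaging, and the two-step in-plane resampling
#' (acquired then reconstructed resolution).
#'
#' @param phantom an `mv_phantom` from [build_phantom()].
#' @param motion a `motion_sequence` from [simulate_closure()].
#' @param intensity an [intensity_model()].
#' @param strategies subset of `c("SAX", "rLAX6", "rLAX9", "rLAX18")`.
#' @param n_timeframes output temporal resolution (timesteps per closure).
#' @param temporal_mode `"window_average"` (temporal partial volume,
#'   default) or `"decimate"`.
#' @param noise_sigma additive noise sd (intensity units).
#' @param smooth_sigma_mm reconstruction smoothing kernel sigma, mm.
#' @param thickness_mm slice thickness (and SAX centre-to-centre spacing).
#' @param sax_n_slices number of SAX slices.
#' @param extent in-plane field of view, mm.
#' @param native_spacing fine sampling used for slab extraction, mm.
#' @param acquired_spacing,reconstructed_spacing in-plane resampling chain.
#' @param n_sublayers odd number of sub-planes averaged across the slab.
#' @param seed study seed; all stage streams derive from it.
#' @return `mv_study`: list with `stacks[[strategy]][[timeframe]]` (each a
#'   `slice_stack`: `slices` array nu x nv x nslices, `planes`, `strategy`,
#'   `timeframe`, `pixel_spacing`), `planes`, `motion` (downsampled) and the
#'   call parameters.
#' @export
simulate_study <- function(phantom, motion,
                           intensity = intensity_model(),
                           strategies = c("SAX", "rLAX6", "rLAX9", "rLAX18"),
                           n_timeframes = 10L,
                           temporal_mode = "window_average",
                           noise_sigma = 38, smooth_sigma_mm = 0.7,
                           thickness_mm = 6, sax_n_slices = 5L,
                           extent = c(100, 100), native_spacing = 0.7,
                           acquired_spacing = 1.4,
                           reconstructed_spacing = 0.87,
                           n_sublayers = 5L, seed = 1L) {
  if (!inherits(phantom, "mv_phantom")) stop("phantom must be an mv_phantom")
  if (!inherits(motion, "motion_sequence")) stop("motion must be a motion_sequence")
  strategies <- match.arg(strategies, c("SAX", "rLAX6", "rLAX9", "rLAX18"),
                          several.ok = TRUE)
  motion <- temporal_downsample(motion, n_timeframes, temporal_mode)

  va <- compute_valve_axis(mesh_at_frame(motion, 1L))
  planes <- list()
  for (st in strategies) {
    planes[[st]] <- if (st == "SAX") {
      define_sax_planes(va$axis, va$center, n_slices = sax_n_slices,
                        thickness_mm = thickness_mm, spacing_mm = thickness_mm,
                        extent = extent, pixel_spacing = native_spacing)
    } else {
      define_rlax_planes(va$axis, va$center,
                         n_planes = as.integer(sub("rLAX", "", st)),
                         thickness_mm = thickness_mm, extent = extent,
                         pixel_spacing = native_spacing)
    }
  }

  stacks <- lapply(strategies, function(st) vector("list", n_timeframes))
  names(stacks) <- strategies
  for (tf in seq_len(n_timeframes)) {
    labels_t <- rasterize_surface(mesh_at_frame(motion, tf), phantom$volume,
                                  thickness = 1, label = "mitral_valve")
    vol <- assign_intensities(labels_t, intensity,
                              seed = derive_seed(seed, paste0("intensity_", tf)))
    vol <- add_noise(vol, noise_sigma,
                     seed = derive_seed(seed, paste0("noise_", tf)))
    vol <- smooth_volume(vol, smooth_sigma_mm)
    for (st in strategies) {
      imgs <- lapply(planes[[st]], function(pl) {
        raw <- sample_slab(vol, pl, n_sublayers = n_sublayers)
        resample_inplane(raw, from_spacing = native_spacing,
                         to_spacing_acquired = acquired_spacing,
                         to_spacing_reconstructed = reconstructed_spacing)
      })
      arr <- array(0, c(dim(imgs[[1L]]), length(imgs)))
      for (k in seq_along(imgs)) arr[, , k] <- imgs[[k]]
      stacks[[st]][[tf]] <- structure(
        list(slices = arr, planes = planes[[st]], strategy = st,
             timeframe = tf, pixel_spacing = reconstructed_spacing,
             thickness = thickness_mm),
        class = "slice_stack")
    }
  }
  structure(list(stacks = stacks, planes = planes, motion = motion,
                 valve_axis = va,
                 params = list(n_timeframes = n_timeframes,
                               temporal_mode = temporal_mode,
                               noise_sigma = noise_sigma,
                               smooth_sigma_mm = smooth_sigma_mm,
                               thickness_mm = thickness_mm,
                               native_spacing = native_spacing,
                               acquired_spacing = acquired_spacing,
                               reconstructed_spacing = reconstructed_spacing,
                               n_sublayers = n_sublayers, seed = seed)),
            class = "mv_study")
}

#' Write a slice stack to disk as NIfTI
#'
#' SAX stacks (parallel slices) are written as a single oblique NIfTI whose
#' affine encodes the plane geometry; radial stacks, whose slices are not
#' parallel, are written one NIfTI per slice.  A JSON sidecar records the
#' strategy, thickness and timeframe.
#'
#' @param stack a `slice_stack`.
#' @param path output path without extension.
#' @return character vector of files written, invisibly.
#' @export
write_slice_stack <- function(stack, path) {
  sp <- stack$pixel_spacing
  planes <- stack$planes
  files <- character(0)
  write_one <- function(arr, plane, file, step = stack$thickness) {
    aff <- diag(4)
    aff[1:3, 1L] <- plane$u * sp
    aff[1:3, 2L] <- plane$v * sp
    aff[1:3, 3L] <- plane$normal * step
    d <- dim(arr)
    corner <- plane$origin -
      ((d[1L] - 1) / 2 * sp) * plane$u - ((d[2L] - 1) / 2 * sp) * plane$v -
      (if (length(d) > 2L) (d[3L] - 1) / 2 * step else 0) * plane$normal
    aff[1:3, 4L] <- corner
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, file)
    file
  }
  parallel <- length(planes) == 1L ||
    all(vapply(planes, function(p)
      max(abs(p$normal - planes[[1L]]$normal)) < 1e-9, NA))
  if (parallel) {
    step <- if (length(planes) > 1L) {
      vnorm(planes[[2L]]$origin - planes[[1L]]$origin)
    } else {
      stack$thickness
    }
    mid <- planes[[(length(planes) + 1L) %/% 2L]]
    files <- write_one(stack$slices, mid, paste0(path, ".nii.gz"), step)
  } else {
    for (k in seq_along(planes)) {
      files <- c(files, write_one(stack$slices[, , k], planes[[k]],
                                  sprintf("%s_%02d.nii.gz", path, k)))
    }
  }
  jsonlite::write_json(list(strategy = stack$strategy,
                            thickness = stack$thickness,
                            timeframe = stack$timeframe,
                            pixel_spacing = sp),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(files)
}
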