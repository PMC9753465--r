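#' Write a calibrated stack to multi-page TIFF with a JSON sidecar
#'
#' Voxels are stored as 32-bit TIFF pages (one page per z-slice and
#' channel, channel-major order), scaled into `[0, 1]` by an intensity
#' scale recorded in the metadata; storage quantisation is one part in
#' 2^32. Calibration, layout and the intensity scale are written to a JSON
#' sidecar (`<path>.json`) so the pair round-trips without external
#' information.
#'
#' @param stack a [calibrated_stack()].
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default `TRUE`; without it the
#'   file reads back only with explicit calibration overrides).
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$voxels)
  scale <- max(1, max(stack$voxels))
  meta <- list(format = "amisquant-calibrated-stack", version = 1L,
               shape = d, channel_names = stack$channel_names,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               axis3 = stack$axis3, intensity_scale = scale,
               page_order = "channel_major")
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- stack$voxels[, , z, ch] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  if (sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' Calibration is taken from the JSON sidecar written by
#' [write_calibrated_tiff()], or from the explicit overrides. A plain TIFF
#' without any calibration source raises a format error.
#'
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um calibration overrides (used when the file
#'   carries none, and taking precedence over file values when given).
#' @param channel_names override channel names.
#' @return A [calibrated_stack()].
#' @export
read_calibrated_tiff <- function(path, pixel_size_um = NULL,
                                 z_step_um = NULL, channel_names = NULL) {
  if (!file.exists(path))
    stop_amis("amisquant_format_error", "no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                     error = function(e) NULL)
  if (!is.null(meta) && identical(meta$format, "amisquant-calibrated-stack")) {
    d <- as.integer(meta$shape)
    vox <- array(0, d)
    k <- 0L
    for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
      k <- k + 1L
      vox[, , z, ch] <- pages[[k]] * meta$intensity_scale
    }
    return(calibrated_stack(
      vox,
      pixel_size_um = pixel_size_um %||% meta$pixel_size_um,
      z_step_um = z_step_um %||% (meta$z_step_um %||% NA_real_),
      channel_names = channel_names %||% meta$channel_names,
      frame_interval_s = meta$frame_interval_s,
      axis3 = meta$axis3 %||% "z"))
  }
  ## plain TIFF: every page becomes a z-slice of a single channel
  if (is.null(pixel_size_um))
    stop_amis("amisquant_format_error",
              "%s carries no calibration metadata and no pixel_size_um override was given",
              path)
  nz <- length(pages)
  if (nz > 1L && is.null(z_step_um))
    stop_amis("amisquant_format_error",
              "%s is a multi-page TIFF without z-step metadata; give z_step_um",
              path)
  vox <- array(0, c(dim(pages[[1]])[1:2], nz, 1L))
  for (z in seq_len(nz)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # first sample of RGB pages
    vox[, , z, 1L] <- pg
  }
  calibrated_stack(vox, pixel_size_um = pixel_size_um,
                   z_step_um = z_step_um %||% 1,
                   channel_names = channel_names %||% "ch1")
}

#' Write and read scene ground truth as JSON
#'
#' Serialises the measurement-relevant part of a `scene_truth` (geometry,
#' enrichment factor, masks as run-length-free index lists are omitted;
#' masks are recomputable from the reference but stored here as compact
#' integer indices) alongside a scene TIFF.
#'
#' @param truth a `scene_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  out <- list(
    cell_centres = truth$cell_centres,
    interface_chord_endpoints = truth$interface_chord_endpoints,
    interface_midpoint = truth$interface_midpoint,
    long_axis_endpoints = truth$long_axis_endpoints,
    centrosome_positions = truth$centrosome_positions,
    enrichment_factor = truth$enrichment_factor,
    mask_dim = dim(truth$membrane_mask),
    membrane_mask_idx = which(truth$membrane_mask),
    interface_band_idx = which(truth$interface_band_mask),
    matrix_band_idx = which(truth$matrix_band_mask))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @param json_path JSON path to read.
#' @return For `read_truth_json`: a list mirroring the stored fields, with
#'   masks reconstituted as logical matrices.
#' @export
read_truth_json <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  d <- as.integer(x$mask_dim)
  unmask <- function(idx) {
    m <- matrix(FALSE, d[1], d[2]); m[as.integer(idx)] <- TRUE; m
  }
  x$membrane_mask <- unmask(x$membrane_mask_idx)
  x$interface_band_mask <- unmask(x$interface_band_idx)
  x$matrix_band_mask <- unmask(x$matrix_band_idx)
  for (f in c("cell_centres", "interface_chord_endpoints",
              "long_axis_endpoints", "centrosome_positions"))
    if (!is.null(x[[f]])) x[[f]] <- as.matrix(x[[f]])
  x
}
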