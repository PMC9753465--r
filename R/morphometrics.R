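#' Centrosome separation normalised to the doublet long axis
#'
#' Euclidean distance between the two centrosomes divided by the length of
#' the doublet's long axis; dimensionless and scale-invariant. Values near
#' 0 indicate centrally clustered centrosomes (a polarised configuration),
#' values near 1 centrosomes at opposite poles.
#'
#' @param centrosomes 2 x d matrix (d = 2 or 3) of centrosome positions in
#'   micrometres.
#' @param long_axis 2 x d matrix of the doublet long-axis endpoints.
#' @return Scalar ratio.
#' @export
centrosome_separation <- function(centrosomes, long_axis) {
  centrosomes <- as.matrix(centrosomes); long_axis <- as.matrix(long_axis)
  if (nrow(centrosomes) != 2L || nrow(long_axis) != 2L ||
      ncol(centrosomes) != ncol(long_axis))
    stop_amis("amisquant_geometry_error",
              "need two centrosome positions and two axis endpoints of equal dimension")
  axis_len <- sqrt(sum((long_axis[2, ] - long_axis[1, ])^2))
  if (axis_len <= 0)
    stop_amis("amisquant_geometry_error", "long axis has zero length")
  sqrt(sum((centrosomes[2, ] - centrosomes[1, ])^2)) / axis_len
}

#' Long axis of a doublet mask
#'
#' Endpoints of the maximal-extent chord (Feret diameter) of a binary
#' region: the pair of boundary pixel centres at maximal Euclidean
#' distance, computed exactly via the convex hull.
#'
#' @param mask logical matrix (`[y, x]`).
#' @param pixel_size_um pixel size in micrometres.
#' @return 2 x 2 matrix of endpoint `(x, y)` coordinates in micrometres,
#'   with the axis length (um) as attribute `"length_um"`.
#' @export
long_axis_from_mask <- function(mask, pixel_size_um = 1) {
  if (!is.logical(mask) || !any(mask))
    stop_amis("amisquant_mask_error", "mask must be a non-empty logical matrix")
  check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L)
    stop_amis("amisquant_geometry_error", "single-pixel mask has no axis")
  pts <- cbind(x = (idx[, 2] - 0.5) * pixel_size_um,
               y = (idx[, 1] - 0.5) * pixel_size_um)
  hull <- pts[chull(pts), , drop = FALSE]
  d2 <- as.matrix(dist(hull))^2
  best <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  ends <- hull[c(best[1], best[2]), , drop = FALSE]
  structure(ends, length_um = sqrt(max(d2)))
}

#' Kymograph along a path in a time-lapse
#'
#' For each frame, intensities are sampled along the path (width-averaged,
#' as in [sample_path_intensity()]) and partitioned into contiguous
#' fixed-length sections (default 0.2 um; remainders go to the earliest
#' sections, mirroring interface binning); each kymograph pixel is the mean
#' over one section. Rows are ordered by time.
#'
#' @param timelapse a time-lapse [calibrated_stack()] (`axis3 = "t"`).
#' @param path a [polyline_path()].
#' @param section_um section length along the path (default 0.2).
#' @param channel channel name or index.
#' @return A `kymograph`: `values` (frames x sections), section centre
#'   positions (um), times (s).
#' @export
compute_kymograph <- function(timelapse, path, section_um = 0.2,
                              channel = 1L) {
  stopifnot(inherits(timelapse, "calibrated_stack"))
  if (timelapse$axis3 != "t")
    stop_amis("amisquant_format_error", "compute_kymograph needs a time-lapse stack")
  check_number(section_um, "section_um", 0, strict_min = TRUE)
  ch <- channel_index(timelapse, channel)
  n_frames <- dim(timelapse$voxels)[3L]
  if (n_frames < 2L)
    stop_amis("amisquant_precondition_error", "need >= 2 frames")
  total <- path_length(path)
  n_sections <- max(1L, round(total / section_um))
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- projected_image(timelapse$voxels[, , f, ch],
                           timelapse$pixel_size_um, timelapse$channel_names[ch])
    prof <- sample_path_intensity(img, path)
    bins <- partition_index(length(prof$values), n_sections)
    rows[[f]] <- as.numeric(tapply(prof$values, bins, mean))
  }
  dt <- timelapse$frame_interval_s %||% 1
  structure(list(values = do.call(rbind, rows),
                 section_um = section_um,
                 positions_um = (seq_len(n_sections) - 0.5) * total / n_sections,
                 times_s = (seq_len(n_frames) - 1) * dt,
                 path = path),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d sections (%.3g um each)\n",
              nrow(x$values), ncol(x$values), x$section_um))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  image(x$positions_um, x$times_s, t(x$values[rev(seq_len(nrow(x$values))), ]),
        col = hcl.colors(64, "inferno"), xlab = "position (um)",
        ylab = "time (s)", ...)
  invisible(x)
}

#' Ridge of a kymograph
#'
#' Per-frame position of maximal intensity (argmax over sections), the
#' trajectory of a moving focus.
#'
#' @param kymo a `kymograph`.
#' @return Data frame with `frame`, `section` (1-based) and `position_um`.
#' @export
kymograph_ridge <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  sec <- apply(kymo$values, 1L, which.max)
  data.frame(frame = seq_len(nrow(kymo$values)), section = sec,
             position_um = kymo$positions_um[sec])
}

#' Classify a cluster as having a polarised marker centre
#'
#' Automatic surrogate for manual scoring of polarised-centre clusters,
#' intended for synthetic benchmarks only: a cluster is called positive iff
#' its central-versus-surround enrichment ratio is at or above the
#' threshold (`>=`, so a ratio exactly at threshold is positive). The
#' threshold used is recorded in the result.
#'
#' @param ratio a `region_ratio_result` (or bare numeric ratio).
#' @param threshold decision threshold (default 1.5).
#' @return Logical scalar with attribute `"threshold"`.
#' @export
classify_polarized_centre <- function(ratio, threshold = 1.5) {
  r <- if (inherits(ratio, "region_ratio_result")) ratio$ratio else
    check_number(ratio, "ratio")
  if (!is.finite(r))
    stop_amis("amisquant_undefined_ratio_error", "ratio is not finite")
  check_number(threshold, "threshold", 0)
  structure(r >= threshold, threshold = threshold)
}
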