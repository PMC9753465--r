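#' Calibrated multi-channel image volume
#'
#' The raw substrate of every measurement in the package: an intensity array
#' indexed `[y, x, z, channel]` (or `[y, x, frame, channel]` for a
#' time-lapse) together with its physical calibration.
#'
#' @param voxels numeric array, either 4-d `[y, x, z, channel]`, 3-d
#'   `[y, x, z]` (one channel) or a 2-d matrix (one slice, one channel).
#'   Intensities must be finite and non-negative.
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param z_step_um axial step in micrometres (> 0); ignored (may be `NA`)
#'   when `axis3 = "t"`.
#' @param channel_names character vector naming the channels.
#' @param frame_interval_s frame interval in seconds for time-lapses,
#'   or `NULL`.
#' @param axis3 what the third array axis means: `"z"` (a z-stack) or
#'   `"t"` (a time-lapse of single-plane frames).
#'
#' @return An object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(voxels, pixel_size_um, z_step_um = NA_real_,
                             channel_names = NULL, frame_interval_s = NULL,
                             axis3 = c("z", "t")) {
  axis3 <- match.arg(axis3)
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop_amis("amisquant_format_error", "voxels must be a 2-, 3- or 4-d array")
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop_amis("amisquant_format_error", "intensities must be finite and >= 0")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  if (axis3 == "z") {
    check_number(z_step_um, "z_step_um", min = 0, strict_min = TRUE)
  }
  nc <- dim(voxels)[4L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop_amis("amisquant_format_error",
              "channel_names length %d != %d channels", length(channel_names), nc)
  dimnames(voxels) <- list(NULL, NULL, NULL, channel_names)
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, channel_names = channel_names,
         frame_interval_s = frame_interval_s, axis3 = axis3),
    class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<calibrated_stack> %d x %d px, %d %s, %d channel(s): %s\n",
              d[2], d[1], d[3], if (x$axis3 == "z") "z-slices" else "frames",
              d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel %.4g um%s%s\n", x$pixel_size_um,
              if (x$axis3 == "z") sprintf(", z-step %.4g um", x$z_step_um) else "",
              if (!is.null(x$frame_interval_s))
                sprintf(", frame interval %.4g s", x$frame_interval_s) else ""))
  invisible(x)
}

#' @export
dim.calibrated_stack <- function(x) dim(x$voxels)

## resolve a channel name or index to an index; lookup error if unknown
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(stack$channel_names))
      stop_amis("amisquant_lookup_error", "channel index %d out of range", ch)
    return(ch)
  }
  ch <- match(channel, stack$channel_names)
  if (is.na(ch))
    stop_amis("amisquant_lookup_error", "unknown channel '%s' (have: %s)",
              channel, paste(stack$channel_names, collapse = ", "))
  ch
}

#' 2-d projected image with inherited calibration
#'
#' @param pixels numeric matrix `[y, x]`.
#' @param pixel_size_um pixel size in micrometres.
#' @param channel channel label the projection came from.
#' @param provenance list describing which slices were projected.
#' @return An object of class `projected_image`.
#' @export
projected_image <- function(pixels, pixel_size_um, channel = "ch1",
                            provenance = list()) {
  stopifnot(is.matrix(pixels))
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel, provenance = provenance),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  cat(sprintf("<projected_image> %d x %d px, channel '%s', pixel %.4g um (%s)\n",
              ncol(x$pixels), nrow(x$pixels), x$channel, x$pixel_size_um,
              x$provenance$method %||% "unknown projection"))
  invisible(x)
}

## accept either a projected_image or a bare matrix + pixel size
as_projected <- function(image, pixel_size_um = NULL) {
  if (inherits(image, "projected_image")) return(image)
  if (is.matrix(image)) {
    if (is.null(pixel_size_um))
      stop_amis("amisquant_config_error",
                "a bare matrix needs an explicit pixel_size_um")
    return(projected_image(image, pixel_size_um))
  }
  stop_amis("amisquant_format_error", "expected a projected_image or matrix")
}
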