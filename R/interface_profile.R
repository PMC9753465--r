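#' Polyline annotation path on a projected image
#'
#' An ordered set of 2-d vertices (micrometres) along which intensity is
#' sampled, with the perpendicular width over which samples are averaged.
#' Interface paths are drawn along the cell-cell contact using the F-actin
#' or E-cadherin signal as a guide; the default width (0.8 um) matches the
#' interface line-scan convention.
#'
#' @param vertices numeric matrix with >= 2 rows of `(x, y)` coordinates in
#'   micrometres; consecutive vertices must be distinct.
#' @param width_um width of the perpendicular averaging band (> 0).
#' @return An object of class `polyline_path`.
#' @export
polyline_path <- function(vertices, width_um = 0.8) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    stop_amis("amisquant_config_error", "path needs >= 2 (x, y) vertices")
  seg <- diff(vertices)
  if (any(rowSums(seg^2) == 0))
    stop_amis("amisquant_config_error", "consecutive path vertices must be distinct")
  check_number(width_um, "width_um", 0, strict_min = TRUE)
  structure(list(vertices = unname(vertices), width_um = width_um),
            class = "polyline_path")
}

#' @export
print.polyline_path <- function(x, ...) {
  cat(sprintf("<polyline_path> %d vertices, length %.3g um, width %.3g um\n",
              nrow(x$vertices), path_length(x), x$width_um))
  invisible(x)
}

path_length <- function(path) sum(sqrt(rowSums(diff(path$vertices)^2)))

## equally spaced positions along the polyline (arc-length), with the local
## unit tangent at each position
path_samples <- function(path, spacing) {
  v <- path$vertices
  seg <- diff(v)
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  arcs <- seq(0, total, by = spacing)
  cum <- c(0, cumsum(len))
  idx <- findInterval(arcs, cum, rightmost.closed = TRUE)
  idx[idx > nrow(seg)] <- nrow(seg)
  frac <- (arcs - cum[idx]) / len[idx]
  pts <- v[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / len[idx]
  list(arc = arcs, points = pts, tangents = tang)
}

#' Width-averaged intensity samples along a path
#'
#' Samples the image along the path at arc-length steps of one pixel size;
#' each sample is the mean of bilinear interpolations taken along the
#' perpendicular segment of length `width_um` centred on the path. The
#' number of perpendicular sub-samples is `ceiling(width_um / pixel_size)`
#' forced odd, so a 0.8 um band at 0.2 um pixels uses 5 sub-samples.
#'
#' @param image a [projected_image()] (or matrix, with `pixel_size_um`).
#' @param path a [polyline_path()].
#' @param pixel_size_um required only when `image` is a bare matrix.
#' @return An `interface_profile` object: arc positions (um), one value
#'   column per channel (here the single sampled channel), endpoints unset
#'   until [detect_interface_ends()] is applied.
#' @export
sample_path_intensity <- function(image, path, pixel_size_um = NULL) {
  image <- as_projected(image, pixel_size_um)
  stopifnot(inherits(path, "polyline_path"))
  px <- image$pixel_size_um
  s <- path_samples(path, spacing = px)
  n_perp <- as.integer(ceiling(path$width_um / px))
  if (n_perp %% 2L == 0L) n_perp <- n_perp + 1L
  ## midpoint-rule quadrature: one sub-sample at the centre of each of
  ## n_perp equal sub-strips of the band (a 3-pixel band samples the three
  ## pixel centres)
  offsets <- (seq_len(n_perp) - (n_perp + 1) / 2) * path$width_um / n_perp
  normals <- cbind(-s$tangents[, 2], s$tangents[, 1])
  vals <- matrix(0, length(s$arc), n_perp)
  for (k in seq_len(n_perp)) {
    pts <- s$points + offsets[k] * normals
    vals[, k] <- bilinear_sample(image$pixels, pts[, 1], pts[, 2], px)
  }
  structure(list(
    arc_positions_um = s$arc,
    values = rowMeans(vals),
    channel = image$channel,
    n_perpendicular = n_perp,
    width_um = path$width_um,
    interface_start_idx = NA_integer_,
    interface_end_idx = NA_integer_,
    path = path, pixel_size_um = px), class = "interface_profile")
}

#' @export
print.interface_profile <- function(x, ...) {
  cat(sprintf("<interface_profile> %d samples over %.3g um, channel '%s'",
              length(x$arc_positions_um), max(x$arc_positions_um), x$channel))
  if (!is.na(x$interface_start_idx))
    cat(sprintf(", interface samples %d..%d", x$interface_start_idx,
                x$interface_end_idx))
  cat("\n")
  invisible(x)
}

#' Delimit the cell-cell interface from the two cortical actin peaks
#'
#' The interface runs between the two F-actin peaks at the ends of the
#' drawn path: the start index is the argmax of the actin values over the
#' first half of the samples and the end index the argmax over the second
#' half. A half whose dynamic range is below `min_prominence` times the
#' whole profile's range has no distinguishable peak and raises a
#' detection error.
#'
#' @param actin_values numeric vector of actin intensities along the path,
#'   or an `interface_profile` sampled on the actin channel.
#' @param min_prominence minimum per-half dynamic range as a fraction of
#'   the profile's full range (default 0.05).
#' @return Integer vector `c(start_idx, end_idx)` (1-based sample indices).
#' @export
detect_interface_ends <- function(actin_values, min_prominence = 0.05) {
  v <- if (inherits(actin_values, "interface_profile"))
    actin_values$values else as.numeric(actin_values)
  n <- length(v)
  if (n < 5L)
    stop_amis("amisquant_precondition_error",
              "need >= 5 samples to delimit an interface, got %d", n)
  rng <- max(v) - min(v)
  if (rng <= 0)
    stop_amis("amisquant_detection_error",
              "flat actin profile: no interface peaks detectable")
  half <- n %/% 2L
  first <- v[seq_len(half)]
  second <- v[(half + 1L):n]
  if (max(first) - min(first) < min_prominence * rng ||
      max(second) - min(second) < min_prominence * rng)
    stop_amis("amisquant_detection_error",
              "no distinguishable actin peak in one half of the path")
  start_idx <- which.max(first)
  end_idx <- half + which.max(second)
  c(start_idx = start_idx, end_idx = end_idx)
}

#' Attach detected interface endpoints to a profile
#'
#' Convenience wrapper: detects the interface span on an actin profile and
#' copies it onto a (possibly different-channel) profile sampled along the
#' same path.
#'
#' @param profile the `interface_profile` to annotate.
#' @param actin_profile profile of the actin channel along the same path
#'   (defaults to `profile` itself).
#' @param min_prominence passed to [detect_interface_ends()].
#' @return `profile` with `interface_start_idx` / `interface_end_idx` set.
#' @export
set_interface_ends <- function(profile, actin_profile = profile,
                               min_prominence = 0.05) {
  ends <- detect_interface_ends(actin_profile, min_prominence)
  if (length(profile$values) != length(actin_profile$values))
    stop_amis("amisquant_precondition_error",
              "profiles were not sampled along the same path")
  profile$interface_start_idx <- unname(ends[1])
  profile$interface_end_idx <- unname(ends[2])
  profile
}

#' Average a profile into 20 interface sections
#'
#' Partitions the sample span between the detected interface endpoints into
#' `n_bins` contiguous near-equal index ranges (any remainder going to the
#' earliest bins) and averages the values in each, yielding the normalised
#' "per 5% of interface length" profile.
#'
#' @param profile an `interface_profile` with endpoints set (or supply
#'   `start_idx` / `end_idx`).
#' @param n_bins number of sections (default 20).
#' @param start_idx,end_idx optional explicit 1-based endpoints overriding
#'   the ones stored in the profile.
#' @return A `binned_profile`: `bin_means` (length `n_bins`), `n_samples`
#'   per bin, bin centres as arc fractions of the interface, channel label.
#' @export
bin_profile <- function(profile, n_bins = 20L, start_idx = NULL,
                        end_idx = NULL) {
  stopifnot(inherits(profile, "interface_profile"))
  n_bins <- check_count(n_bins, "n_bins", min = 1L)
  s <- start_idx %||% profile$interface_start_idx
  e <- end_idx %||% profile$interface_end_idx
  if (is.na(s) || is.na(e))
    stop_amis("amisquant_precondition_error",
              "interface endpoints unset; run set_interface_ends() first")
  if (s >= e || s < 1L || e > length(profile$values))
    stop_amis("amisquant_precondition_error", "invalid endpoint indices")
  span <- profile$values[s:e]
  if (length(span) < n_bins)
    stop_amis("amisquant_precondition_error",
              "interface span of %d samples is shorter than %d bins",
              length(span), n_bins)
  bins <- partition_index(length(span), n_bins)
  means <- as.numeric(tapply(span, bins, mean))
  counts <- as.integer(tabulate(bins, n_bins))
  structure(list(bin_means = means, n_samples = counts,
                 arc_fraction = (seq_len(n_bins) - 0.5) / n_bins,
                 n_bins = n_bins, channel = profile$channel),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("<binned_profile> %d bins, channel '%s', mean %.4g\n",
              x$n_bins, x$channel, mean(x$bin_means)))
  invisible(x)
}

#' Average several binned profiles bin-wise
#'
#' @param profiles a list of `binned_profile` objects with equal bin count.
#' @param dispersion `"sem"` (default) or `"sd"` per-bin dispersion.
#' @return A `binned_profile` with extra fields `dispersion` (per bin) and
#'   `n_profiles`.
#' @export
average_binned_profiles <- function(profiles, dispersion = c("sem", "sd")) {
  dispersion <- match.arg(dispersion)
  if (length(profiles) < 1L)
    stop_amis("amisquant_precondition_error", "need >= 1 profile to average")
  nb <- vapply(profiles, function(p) p$n_bins, integer(1))
  if (length(unique(nb)) != 1L)
    stop_amis("amisquant_precondition_error", "profiles have differing bin counts")
  m <- do.call(rbind, lapply(profiles, function(p) p$bin_means))
  disp <- if (nrow(m) == 1L) rep(0, ncol(m)) else apply(m, 2, sd)
  if (dispersion == "sem") disp <- disp / sqrt(nrow(m))
  out <- profiles[[1]]
  out$bin_means <- colMeans(m)
  out$n_samples <- rep(NA_integer_, nb[1])
  out$dispersion <- disp
  out$dispersion_type <- dispersion
  out$n_profiles <- length(profiles)
  out
}

#' Centre and side line-scans across an interface, with areas under the
#' curves
#'
#' Takes three width-averaged scans perpendicular to the interface: one at
#' the centre-most region and one at each flanking side region, placed
#' symmetrically about the interface midpoint at centre-to-centre offsets
#' of `scan_width_um` so the three bands tile without overlap. The two side
#' scans are averaged into one, and the area under each curve (trapezoidal,
#' over the scan length) is returned for comparison.
#'
#' @param image a [projected_image()].
#' @param midpoint_um interface midpoint `(x, y)` in micrometres.
#' @param direction_um unit-free vector along the interface; scans run
#'   perpendicular to it.
#' @param interface_length_um usable interface length; must be at least
#'   `3 * scan_width_um`.
#' @param scan_width_um width of each scan band along the interface
#'   (default 3).
#' @param scan_length_um extent of each scan across the interface
#'   (default 4).
#' @return A list with `centre` and `side` (each an `interface_profile`),
#'   `auc_centre`, `auc_side` and their ratio `auc_ratio`.
#' @export
centre_side_linescans <- function(image, midpoint_um, direction_um,
                                  interface_length_um,
                                  scan_width_um = 3, scan_length_um = 4) {
  image <- as_projected(image)
  check_number(interface_length_um, "interface_length_um", 0, strict_min = TRUE)
  if (interface_length_um < 3 * scan_width_um)
    stop_amis("amisquant_geometry_error",
              "interface (%.3g um) too short for three %.3g um scan bands",
              interface_length_um, scan_width_um)
  u <- direction_um / sqrt(sum(direction_um^2))   # along the interface
  v <- c(-u[2], u[1])                             # across the interface
  scan_at <- function(offset) {
    c0 <- midpoint_um + offset * u
    p <- polyline_path(rbind(c0 - scan_length_um / 2 * v,
                             c0 + scan_length_um / 2 * v),
                       width_um = scan_width_um)
    sample_path_intensity(image, p)
  }
  centre <- scan_at(0)
  side1 <- scan_at(-scan_width_um)
  side2 <- scan_at(scan_width_um)
  side <- side1
  side$values <- (side1$values + side2$values) / 2
  auc <- function(pr) {
    x <- pr$arc_positions_um; y <- pr$values
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  list(centre = centre, side = side,
       auc_centre = auc(centre), auc_side = auc(side),
       auc_ratio = auc(centre) / auc(side))
}
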