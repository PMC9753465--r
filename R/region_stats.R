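#' Rasterise a circular region of interest
#'
#' A pixel belongs to the disc iff its centre lies within the circle
#' (voxel-centre convention), the deterministic rasterisation used by all
#' circle-based ratios.
#'
#' @param image a [projected_image()] (or matrix with `pixel_size_um`)
#'   giving the target raster and calibration.
#' @param centre_um circle centre `(x, y)` in micrometres.
#' @param diameter_um circle diameter in micrometres.
#' @param pixel_size_um required only for bare matrices.
#' @return A logical matrix of the image's shape.
#' @export
disc_mask <- function(image, centre_um, diameter_um, pixel_size_um = NULL) {
  image <- as_projected(image, pixel_size_um)
  check_number(diameter_um, "diameter_um", 0, strict_min = TRUE)
  px <- image$pixel_size_um
  ny <- nrow(image$pixels); nx <- ncol(image$pixels)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  r2 <- (diameter_um / 2)^2
  outer((ys - centre_um[2])^2, (xs - centre_um[1])^2, `+`) <= r2
}

region_ratio_result <- function(mean_central, mean_surround, ratio,
                                area_central_um2, area_surround_um2,
                                channel, kind) {
  structure(list(mean_central = mean_central, mean_surround = mean_surround,
                 ratio = ratio, area_central_um2 = area_central_um2,
                 area_surround_um2 = area_surround_um2, channel = channel,
                 kind = kind), class = "region_ratio_result")
}

#' @export
print.region_ratio_result <- function(x, ...) {
  cat(sprintf("<region_ratio_result> %s: %.4g / %.4g = %.4g (channel '%s')\n",
              x$kind, x$mean_central, x$mean_surround, x$ratio, x$channel))
  invisible(x)
}

masked_mean <- function(pixels, mask, what) {
  n <- sum(mask)
  if (n == 0L)
    stop_amis("amisquant_mask_error", "%s region is empty", what)
  mean(pixels[mask])
}

#' Central-versus-surround enrichment ratio
#'
#' The polarisation enrichment statistic for multi-cell clusters: the mean
#' intensity inside a fixed-diameter disc placed over the multi-cellular
#' junction, divided by the mean over the remainder of the annotated
#' cluster region (the "outer" region). A ratio of 1 is the unpolarised
#' null; enrichment of the marker at the junction drives it above 1.
#'
#' @param image a [projected_image()].
#' @param cluster_mask logical matrix delimiting the cluster region
#'   (annotated boundary, or the synthetic truth's membrane mask).
#' @param centre_um disc centre `(x, y)` in micrometres (the junction).
#' @param disc_diameter_um disc diameter (default 4).
#' @return A `region_ratio_result`.
#' @export
central_vs_surround_ratio <- function(image, cluster_mask, centre_um,
                                      disc_diameter_um = 4) {
  image <- as_projected(image)
  if (!is.logical(cluster_mask) || !identical(dim(cluster_mask), dim(image$pixels)))
    stop_amis("amisquant_mask_error", "cluster_mask must be a logical matrix of the image's shape")
  disc <- disc_mask(image, centre_um, disc_diameter_um)
  central <- disc & cluster_mask
  surround <- cluster_mask & !disc
  if (!any(central))
    stop_amis("amisquant_geometry_error", "disc does not intersect the cluster region")
  m_c <- masked_mean(image$pixels, central, "central")
  m_s <- masked_mean(image$pixels, surround, "surround")
  if (m_s <= 0)
    stop_amis("amisquant_undefined_ratio_error",
              "surround mean is %g; ratio undefined", m_s)
  px2 <- image$pixel_size_um^2
  region_ratio_result(m_c, m_s, m_c / m_s, sum(central) * px2,
                      sum(surround) * px2, image$channel, "central_vs_surround")
}

#' Core-versus-whole-cell enrichment ratio
#'
#' For single cells (e.g. cultured on glass): the mean intensity in a
#' circular core area divided by the mean over the whole annotated cell
#' region (the denominator includes the core, unlike
#' [central_vs_surround_ratio()]). The core diameter must be given
#' explicitly: different experimental layouts use different core sizes
#' (e.g. 6 um for a glass-culture marker core, 2.5 um for a central core
#' compared to the whole cell surface), so no default is safe.
#'
#' @param image a [projected_image()].
#' @param cell_mask logical matrix delimiting the cell.
#' @param core_centre_um core centre `(x, y)` in micrometres.
#' @param core_diameter_um core diameter in micrometres (required).
#' @return A `region_ratio_result`.
#' @export
core_vs_cell_ratio <- function(image, cell_mask, core_centre_um,
                               core_diameter_um) {
  if (missing(core_diameter_um))
    stop_amis("amisquant_config_error",
              "core_diameter_um must be given explicitly")
  image <- as_projected(image)
  if (!is.logical(cell_mask) || !identical(dim(cell_mask), dim(image$pixels)))
    stop_amis("amisquant_mask_error", "cell_mask must be a logical matrix of the image's shape")
  disc <- disc_mask(image, core_centre_um, core_diameter_um)
  core <- disc & cell_mask
  if (!any(core))
    stop_amis("amisquant_geometry_error", "core disc does not intersect the cell region")
  m_core <- masked_mean(image$pixels, core, "core")
  m_cell <- masked_mean(image$pixels, cell_mask, "cell")
  if (m_cell <= 0)
    stop_amis("amisquant_undefined_ratio_error",
              "whole-cell mean is %g; ratio undefined", m_cell)
  px2 <- image$pixel_size_um^2
  region_ratio_result(m_core, m_cell, m_core / m_cell, sum(core) * px2,
                      sum(cell_mask) * px2, image$channel, "core_vs_cell")
}

#' Cell-cell versus cell-matrix interface intensity
#'
#' Compares the mean intensity of a junctional marker (e.g. E-cadherin)
#' between an annotated cell-cell interface band and a cell-matrix contact
#' band. The bands must be disjoint and non-empty.
#'
#' @param image a [projected_image()].
#' @param interface_band logical matrix: the cell-cell interface band.
#' @param matrix_band logical matrix: the cell-matrix contact band.
#' @return A `region_ratio_result` (`mean_central` is the cell-cell band).
#' @export
interface_vs_matrix_intensity <- function(image, interface_band, matrix_band) {
  image <- as_projected(image)
  for (m in list(interface_band, matrix_band))
    if (!is.logical(m) || !identical(dim(m), dim(image$pixels)))
      stop_amis("amisquant_mask_error", "bands must be logical matrices of the image's shape")
  if (any(interface_band & matrix_band))
    stop_amis("amisquant_mask_error", "interface and matrix bands overlap")
  m_i <- masked_mean(image$pixels, interface_band, "interface band")
  m_m <- masked_mean(image$pixels, matrix_band, "matrix band")
  if (m_m <= 0)
    stop_amis("amisquant_undefined_ratio_error",
              "matrix-band mean is %g; ratio undefined", m_m)
  px2 <- image$pixel_size_um^2
  region_ratio_result(m_i, m_m, m_i / m_m, sum(interface_band) * px2,
                      sum(matrix_band) * px2, image$channel,
                      "interface_vs_matrix")
}

#' 10 x 10 per-cell intensity heatmap
#'
#' Averages the intensity within a square region of interest fitted to the
#' main body of one cell into a 10 x 10 unit matrix: the ROI's pixel rows
#' and columns are partitioned into 10 contiguous near-equal runs each
#' (every unit covers ~10% of each axis; remainders go to the earliest
#' rows/columns) and each unit is the mean over its pixel block.
#'
#' @param image a [projected_image()].
#' @param roi square ROI as a list with `centre_um` (`(x, y)`, micrometres)
#'   and `side_um`, or `corner_um` (lower x/y corner) and `side_um`.
#' @param n_units grid size per axis (default 10).
#' @return A `heatmap_matrix`: `units` (`n_units` x `n_units`), the pixel
#'   ROI used, `n_cells = 1`.
#' @export
build_cell_heatmap <- function(image, roi, n_units = 10L) {
  image <- as_projected(image)
  n_units <- check_count(n_units, "n_units", min = 1L)
  px <- image$pixel_size_um
  if (!is.null(roi$centre_um))
    corner <- roi$centre_um - roi$side_um / 2
  else corner <- roi$corner_um
  side_px <- round(roi$side_um / px)
  c0 <- round(corner[1] / px); r0 <- round(corner[2] / px)
  if (side_px < n_units)
    stop_amis("amisquant_precondition_error",
              "ROI side of %d px is smaller than the %d-unit grid", side_px, n_units)
  if (r0 < 0 || c0 < 0 || r0 + side_px > nrow(image$pixels) ||
      c0 + side_px > ncol(image$pixels))
    stop_amis("amisquant_geometry_error", "square ROI exceeds the image")
  block <- image$pixels[r0 + seq_len(side_px), c0 + seq_len(side_px)]
  rows <- partition_index(side_px, n_units)
  cols <- partition_index(side_px, n_units)
  units <- matrix(0, n_units, n_units)
  for (i in seq_len(n_units))
    for (j in seq_len(n_units))
      units[i, j] <- mean(block[rows == i, cols == j])
  structure(list(units = units, n_units = n_units,
                 roi_px = c(row0 = r0, col0 = c0, side = side_px),
                 side_um = side_px * px, n_cells = 1L),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d x %d units over %.3g um, %d cell(s)\n",
              x$n_units, x$n_units, x$side_um, x$n_cells))
  invisible(x)
}

#' Average a set of per-cell heatmaps unit-wise
#'
#' Stacks the heatmaps of all cells from one condition and averages each
#' unit position, producing the condition-level heatmap.
#'
#' @param maps list of `heatmap_matrix` objects of equal grid size.
#' @return A `heatmap_matrix` with `n_cells` the total over the inputs.
#' @export
stack_heatmaps <- function(maps) {
  if (length(maps) < 1L)
    stop_amis("amisquant_precondition_error", "need >= 1 heatmap to stack")
  nu <- vapply(maps, function(m) m$n_units, integer(1))
  if (length(unique(nu)) != 1L)
    stop_amis("amisquant_precondition_error", "heatmaps have differing grid sizes")
  out <- maps[[1]]
  out$units <- Reduce(`+`, lapply(maps, function(m) m$units)) / length(maps)
  out$n_cells <- sum(vapply(maps, function(m) m$n_cells, integer(1)))
  out
}

#' Mean level of the central 20% of a heatmap
#'
#' The "central 20%" is read as the central block covering 20% of each
#' axis: for the default 10 x 10 grid, units (5, 5), (5, 6), (6, 5), (6, 6)
#' (1-based). The covered fraction per axis is configurable because the 2-d
#' construction is a convention, not a measurement.
#'
#' @param map a `heatmap_matrix`.
#' @param central_fraction fraction of each axis covered (default 0.2).
#' @return The mean intensity of the central block (scalar).
#' @export
heatmap_central_level <- function(map, central_fraction = 0.2) {
  stopifnot(inherits(map, "heatmap_matrix"))
  check_number(central_fraction, "central_fraction", 0, 1, strict_min = TRUE)
  n <- map$n_units
  k <- max(1L, round(central_fraction * n))
  lo <- (n - k) %/% 2L + 1L
  idx <- lo:(lo + k - 1L)
  mean(map$units[idx, idx])
}

#' Plot a heatmap matrix
#'
#' @param x a `heatmap_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.heatmap_matrix <- function(x, ...) {
  image(t(x$units[rev(seq_len(x$n_units)), ]),
        col = hcl.colors(64, "viridis"), axes = FALSE,
        main = sprintf("heatmap (%d cells)", x$n_cells), ...)
  invisible(x)
}
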