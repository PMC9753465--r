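#' Parameters of a synthetic cluster scene
#'
#' Defines the geometry, optics and noise of a rendered stem-cell doublet or
#' cluster scene. Cell bodies are spheres truncated by the bisector planes
#' towards their neighbours, so adjacent cells share a flat interface facet.
#' Membranes are rendered as a shell of uniform amplitude and fixed
#' thickness around each cell boundary, which keeps the noiseless scene
#' exactly two-valued (background / membrane) and makes null-calibration
#' checks exact; optional Gaussian blur softens the edges.
#'
#' Channels rendered: `"actin"` (sum of per-cell shells, so the shared
#' interface carries twice the outer-membrane amplitude, plus
#' junctional-vertex enrichment spots at the interface rim that give the
#' two-peak profile interface-end detection relies on), `"cadherin"` (sum of
#' shells, no vertex spots) and `"par3"` (union of shells at uniform
#' amplitude, plus a polarity focus at the interface midpoint and optional
#' peripheral puncta).
#'
#' @param n_cells number of cells (>= 1).
#' @param cell_radius_um sphere radius in micrometres.
#' @param fov_um lateral field of view (square), micrometres.
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param z_slices number of z-slices.
#' @param z_step_um axial step, micrometres.
#' @param membrane_width_um full thickness of the membrane shell.
#' @param membrane_amplitude membrane intensity (arbitrary units).
#' @param par3_enrichment enrichment factor E >= 0: peak PAR-3 intensity at
#'   the interface midpoint relative to the membrane baseline. E = 1 is the
#'   unpolarised null; the focus adds `(E - 1) * membrane_amplitude` at its
#'   centre.
#' @param par3_spot_sigma_um Gaussian sigma of the polarity focus.
#' @param puncta_density number of peripheral PAR-3 puncta per cell
#'   (default 0; puncta amplitude and size are fixed at
#'   `0.5 * membrane_amplitude` and 0.3 um sigma).
#' @param vertex_amplitude extra actin amplitude (relative to
#'   `membrane_amplitude`) of the junctional spots at the interface rim.
#' @param centre_spacing_factor centre-to-centre distance of adjacent cells
#'   relative to `cell_radius_um` (doublet) or distance of each centre from
#'   the common junction relative to `cell_radius_um` (cluster).
#' @param noise_gaussian_sigma additive Gaussian read-noise sigma.
#' @param noise_poisson_scale photon scale s of Poisson shot noise: the
#'   noisy value is `rpois(s * v) / s`; 0 disables shot noise.
#' @param blur_sigma_um Gaussian blur sigma applied per slice before noise;
#'   0 disables blur.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical scenes.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_cells = 2L,
                         cell_radius_um = 6,
                         fov_um = 30,
                         pixel_size_um = 0.2,
                         z_slices = 7L,
                         z_step_um = 2,
                         membrane_width_um = 0.6,
                         membrane_amplitude = 100,
                         par3_enrichment = 1,
                         par3_spot_sigma_um = 1,
                         puncta_density = 0L,
                         vertex_amplitude = 1,
                         centre_spacing_factor = NULL,
                         noise_gaussian_sigma = 0,
                         noise_poisson_scale = 0,
                         blur_sigma_um = 0,
                         seed = 1L) {
  p <- list(
    n_cells = check_count(n_cells, "n_cells", min = 1L),
    cell_radius_um = check_number(cell_radius_um, "cell_radius_um", 0, strict_min = TRUE),
    fov_um = check_number(fov_um, "fov_um", 0, strict_min = TRUE),
    pixel_size_um = check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE),
    z_slices = check_count(z_slices, "z_slices", min = 1L),
    z_step_um = check_number(z_step_um, "z_step_um", 0, strict_min = TRUE),
    membrane_width_um = check_number(membrane_width_um, "membrane_width_um", 0, strict_min = TRUE),
    membrane_amplitude = check_number(membrane_amplitude, "membrane_amplitude", 0, strict_min = TRUE),
    par3_enrichment = check_number(par3_enrichment, "par3_enrichment", 0),
    par3_spot_sigma_um = check_number(par3_spot_sigma_um, "par3_spot_sigma_um", 0, strict_min = TRUE),
    puncta_density = check_count(puncta_density, "puncta_density"),
    vertex_amplitude = check_number(vertex_amplitude, "vertex_amplitude", 0),
    centre_spacing_factor = centre_spacing_factor,
    noise_gaussian_sigma = check_number(noise_gaussian_sigma, "noise_gaussian_sigma", 0),
    noise_poisson_scale = check_number(noise_poisson_scale, "noise_poisson_scale", 0),
    blur_sigma_um = check_number(blur_sigma_um, "blur_sigma_um", 0),
    seed = check_count(seed, "seed"))
  class(p) <- "scene_params"
  p
}

## voxel-centre coordinate grids for a scene
scene_grid <- function(params) {
  n_xy <- round(params$fov_um / params$pixel_size_um)
  list(
    n_xy = n_xy, nz = params$z_slices,
    x = (seq_len(n_xy) - 0.5) * params$pixel_size_um,
    y = (seq_len(n_xy) - 0.5) * params$pixel_size_um,
    z = (seq_len(params$z_slices) - 0.5) * params$z_step_um)
}

## signed distance of every voxel to the boundary of a truncated sphere:
## max over (sphere surface distance, bisector-plane distances).
## centres: matrix n_cells x 3 (x, y, z); i: which cell.
cell_sdf <- function(grid, centres, i, radius) {
  nx <- grid$n_xy; ny <- grid$n_xy; nz <- grid$nz
  X <- array(rep(grid$x, each = ny), c(ny, nx, nz))
  Y <- array(rep(grid$y, times = nx * nz), c(ny, nx, nz))
  Z <- array(rep(grid$z, each = ny * nx), c(ny, nx, nz))
  ci <- centres[i, ]
  sdf <- sqrt((X - ci[1])^2 + (Y - ci[2])^2 + (Z - ci[3])^2) - radius
  for (j in seq_len(nrow(centres))) {
    if (j == i) next
    u <- centres[j, ] - ci
    un <- sqrt(sum(u^2))
    if (un == 0) next
    u <- u / un
    m <- (centres[j, ] + ci) / 2
    b <- (X - m[1]) * u[1] + (Y - m[2]) * u[2] + (Z - m[3]) * u[3]
    sdf <- pmax(sdf, b)
  }
  sdf
}

## render an isotropic 3-d Gaussian spot onto a volume
render_spot <- function(grid, centre, amplitude, sigma) {
  nx <- grid$n_xy; ny <- grid$n_xy; nz <- grid$nz
  gx <- exp(-(grid$x - centre[1])^2 / (2 * sigma^2))
  gy <- exp(-(grid$y - centre[2])^2 / (2 * sigma^2))
  gz <- exp(-(grid$z - centre[3])^2 / (2 * sigma^2))
  amplitude * outer(gy, gx) %o% gz
}

apply_noise_blur <- function(vol, params) {
  if (params$blur_sigma_um > 0) {
    sp <- params$blur_sigma_um / params$pixel_size_um
    for (k in seq_len(dim(vol)[3]))
      vol[, , k] <- EBImage::gblur(vol[, , k], sigma = sp)
  }
  if (params$noise_poisson_scale > 0) {
    s <- params$noise_poisson_scale
    vol[] <- rpois(length(vol), pmax(vol, 0) * s) / s
  }
  if (params$noise_gaussian_sigma > 0)
    vol[] <- vol + rnorm(length(vol), 0, params$noise_gaussian_sigma)
  vol[vol < 0] <- 0
  vol
}

## shared renderer for doublet and cluster scenes
render_scene <- function(params, centres, junction) {
  grid <- scene_grid(params)
  A <- params$membrane_amplitude
  w2 <- params$membrane_width_um / 2
  r <- params$cell_radius_um
  nc <- nrow(centres)

  shells <- vector("list", nc)
  for (i in seq_len(nc)) {
    sdf <- cell_sdf(grid, centres, i, r)
    shells[[i]] <- abs(sdf) <= w2
  }
  shell_sum <- Reduce(`+`, shells)           # integer: 0, 1, 2, ...
  shell_any <- shell_sum > 0

  actin <- A * shell_sum
  cadherin <- A * shell_sum
  par3 <- A * shell_any

  ## junctional-vertex actin spots at the interface rim (doublet: facet rim
  ## in the central focal plane; cluster: cluster-boundary points where two
  ## adjacent facets meet the outer surface)
  rim <- interface_rim_points(centres, r, junction)
  if (params$vertex_amplitude > 0) {
    for (k in seq_len(nrow(rim)))
      actin <- actin + render_spot(grid, rim[k, ],
                                   params$vertex_amplitude * A,
                                   max(params$membrane_width_um, 0.4))
  }

  ## polarity focus: total PAR-3 at the interface midpoint is E * A
  if (params$par3_enrichment != 1)
    par3 <- par3 + render_spot(grid, junction,
                               (params$par3_enrichment - 1) * A,
                               params$par3_spot_sigma_um)

  ## peripheral puncta: random points on each cell's outer surface, away
  ## from the interface facets
  puncta <- NULL
  if (params$puncta_density > 0) {
    puncta <- matrix(0, 0, 3)
    for (i in seq_len(nc)) {
      got <- 0; tries <- 0
      while (got < params$puncta_density && (tries <- tries + 1) < 1e4) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p <- centres[i, ] + r * u
        ## reject points past any bisector plane (not peripheral) or
        ## outside the imaged volume
        ok <- TRUE
        for (j in seq_len(nc)) {
          if (j == i) next
          d <- centres[j, ] - centres[i, ]
          if (sum((p - (centres[i, ] + centres[j, ]) / 2) * d) > -0.5 * sqrt(sum(d^2)) * 0.2)
            ok <- FALSE
        }
        if (p[3] < 0 || p[3] > grid$nz * params$z_step_um ||
            any(p[1:2] < 0) || any(p[1:2] > params$fov_um)) ok <- FALSE
        if (ok) {
          par3 <- par3 + render_spot(grid, p, 0.5 * A, 0.3)
          puncta <- rbind(puncta, p)
          got <- got + 1
        }
      }
    }
  }

  reference <- list(actin = actin, cadherin = cadherin, par3 = par3)

  vox <- array(0, c(grid$n_xy, grid$n_xy, grid$nz, 3L))
  vox[, , , 1L] <- apply_noise_blur(actin, params)
  vox[, , , 2L] <- apply_noise_blur(cadherin, params)
  vox[, , , 3L] <- apply_noise_blur(par3, params)
  stack <- calibrated_stack(vox, params$pixel_size_um, params$z_step_um,
                            channel_names = c("actin", "cadherin", "par3"))
  list(stack = stack, reference = reference, shell_sum = shell_sum,
       grid = grid, rim = rim)
}

## rim points where adjacent-cell facets meet the outer surface, in the
## central focal plane (z = junction z). For a doublet these are the two
## ends of the interface chord seen in projection.
interface_rim_points <- function(centres, r, junction) {
  nc <- nrow(centres)
  out <- matrix(0, 0, 3)
  pairs <- if (nc == 2) matrix(c(1, 2), 1) else
    cbind(seq_len(nc), c(2:nc, 1))          # adjacent cells on the ring
  for (k in seq_len(nrow(pairs))) {
    ci <- centres[pairs[k, 1], ]; cj <- centres[pairs[k, 2], ]
    m <- (ci + cj) / 2
    d <- sqrt(sum((cj - ci)^2))
    rho <- sqrt(max(r^2 - (d / 2)^2, 0))    # facet radius
    ## in-plane direction perpendicular to the centre line
    u <- (cj - ci) / d
    v <- c(-u[2], u[1], 0)
    vn <- sqrt(sum(v^2))
    if (vn == 0) next
    v <- v / vn
    out <- rbind(out, m + rho * v, m - rho * v)
  }
  ## de-duplicate coincident rim points (cluster facets share the junction)
  out[!duplicated(round(out, 6)), , drop = FALSE]
}

#' Generate a synthetic two-cell (doublet) scene with ground truth
#'
#' Renders a calibrated three-channel z-stack of a cell doublet (see
#' [scene_params()] for the imaging model) and returns it with the
#' generator's ground truth: cell centres, interface chord endpoints and
#' midpoint, long-axis endpoints, centrosome positions, the noiseless
#' per-channel reference volumes, and 2-d masks (projected membrane support,
#' interface band, matrix-contact band) for downstream region statistics.
#'
#' @param params a [scene_params()] with `n_cells = 2`.
#' @return A list with elements `stack` (a [calibrated_stack()]) and
#'   `truth` (class `scene_truth`).
#' @export
generate_doublet_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  if (params$n_cells != 2L)
    stop_amis("amisquant_config_error",
              "generate_doublet_scene needs n_cells = 2, got %d", params$n_cells)
  r <- params$cell_radius_um
  f <- params$centre_spacing_factor %||% 1.2
  d <- f * r
  if (d >= 2 * r)
    stop_amis("amisquant_geometry_error",
              "cells at spacing %.3g um do not overlap (need < %.3g)", d, 2 * r)
  cx <- params$fov_um / 2; cy <- params$fov_um / 2
  cz <- params$z_slices * params$z_step_um / 2
  centres <- rbind(c(cx - d / 2, cy, cz), c(cx + d / 2, cy, cz))
  junction <- c(cx, cy, cz)
  if (cx + d / 2 + r > params$fov_um || cx - d / 2 - r < 0)
    stop_amis("amisquant_geometry_error", "doublet does not fit the field of view")

  res <- with_seed(params$seed, render_scene(params, centres, junction))

  rho <- sqrt(r^2 - (d / 2)^2)
  long_axis <- rbind(c(cx - d / 2 - r, cy, cz), c(cx + d / 2 + r, cy, cz))
  ## centrosomes: polarised configuration, between nucleus and interface
  centrosomes <- rbind(centres[1, ] + c(0.5 * (d / 2), 0, 0),
                       centres[2, ] - c(0.5 * (d / 2), 0, 0))
  truth <- scene_truth(params, centres, junction,
                       chord = rbind(c(cx, cy - rho, cz), c(cx, cy + rho, cz)),
                       long_axis = long_axis, centrosomes = centrosomes,
                       res = res)
  list(stack = res$stack, truth = truth)
}

#' Generate a synthetic multi-cell cluster scene with ground truth
#'
#' Cells are arranged symmetrically around a common junction point in the
#' central focal plane; the PAR-3 polarity focus sits at the junction, the
#' geometry the central-versus-surround enrichment ratio is designed for.
#' With `n_cells = 2` this delegates to [generate_doublet_scene()].
#'
#' @param params a [scene_params()] with `n_cells >= 2`.
#' @inherit generate_doublet_scene return
#' @export
generate_cluster_scene <- function(params = scene_params(n_cells = 4L)) {
  stopifnot(inherits(params, "scene_params"))
  if (params$n_cells == 2L) return(generate_doublet_scene(params))
  if (params$n_cells < 2L)
    stop_amis("amisquant_config_error", "a cluster needs >= 2 cells")
  n <- params$n_cells
  r <- params$cell_radius_um
  rho <- (params$centre_spacing_factor %||% 0.75) * r  # centre-to-junction
  if (2 * rho * sin(pi / n) >= 2 * r)
    stop_amis("amisquant_geometry_error",
              "adjacent cells do not overlap at this spacing")
  cx <- params$fov_um / 2; cy <- params$fov_um / 2
  cz <- params$z_slices * params$z_step_um / 2
  th <- 2 * pi * (seq_len(n) - 1) / n
  centres <- cbind(cx + rho * cos(th), cy + rho * sin(th), cz)
  if (any(centres[, 1] + r > params$fov_um | centres[, 1] - r < 0 |
          centres[, 2] + r > params$fov_um | centres[, 2] - r < 0))
    stop_amis("amisquant_geometry_error", "cluster does not fit the field of view")
  junction <- c(cx, cy, cz)
  res <- with_seed(params$seed, render_scene(params, centres, junction))
  truth <- scene_truth(params, centres, junction,
                       chord = rbind(junction - c(0, 0, r - rho),
                                     junction + c(0, 0, r - rho)),
                       long_axis = NULL, centrosomes = NULL, res = res)
  list(stack = res$stack, truth = truth)
}

## assemble the ground-truth object shared by both scene generators
scene_truth <- function(params, centres, junction, chord, long_axis,
                        centrosomes, res) {
  A <- params$membrane_amplitude
  ## 2-d masks from the noiseless reference, using the central-section
  ## projection convention (the one region measurements are made on):
  ## membrane support (PAR-3 baseline), interface band (shared membrane,
  ## cadherin = 2A) and matrix-contact band (single membrane, cadherin = A)
  nz <- dim(res$shell_sum)[3]
  slices <- if (nz >= 3L) central_slice_set(nz) else seq_len(nz)
  proj_par3_base <- apply(A * (res$shell_sum[, , slices, drop = FALSE] > 0),
                          c(1, 2), max)
  proj_cad <- apply(A * res$shell_sum[, , slices, drop = FALSE], c(1, 2), max)
  membrane_mask <- proj_par3_base > 0
  interface_band <- proj_cad >= 1.5 * A
  matrix_band <- proj_cad > 0 & proj_cad < 1.5 * A
  structure(list(
    cell_centres = centres,
    interface_chord_endpoints = chord,
    interface_midpoint = junction,
    long_axis_endpoints = long_axis,
    centrosome_positions = centrosomes,
    enrichment_factor = params$par3_enrichment,
    reference = res$reference,
    membrane_mask = membrane_mask,
    interface_band_mask = interface_band,
    matrix_band_mask = matrix_band,
    rim_points = res$rim,
    params = params), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d cell(s), E = %g, midpoint (%.2f, %.2f, %.2f) um\n",
              nrow(x$cell_centres), x$enrichment_factor,
              x$interface_midpoint[1], x$interface_midpoint[2],
              x$interface_midpoint[3]))
  invisible(x)
}

#' Parameters of a simulated FRAP experiment
#'
#' @param mobile_fraction fraction of fluorescence that recovers, in
#'   `[0, 1]`.
#' @param rate_k association rate constant, 1/s.
#' @param bleach_depth fraction of the pre-bleach signal removed by the
#'   bleach, in `(0, 1]`.
#' @param pre_frames number of pre-bleach frames (default 3).
#' @param post_frames number of post-bleach frames (default 30).
#' @param frame_interval_s frame interval in seconds (default 10).
#' @param baseline pre-bleach intensity (arbitrary units).
#' @param noise_sigma additive Gaussian noise sigma on intensities.
#' @param seed integer RNG seed.
#' @return A list of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mobile_fraction = 0.6, rate_k = 0.02,
                            bleach_depth = 0.85, pre_frames = 3L,
                            post_frames = 30L, frame_interval_s = 10,
                            baseline = 100, noise_sigma = 0, seed = 1L) {
  p <- list(
    mobile_fraction = check_number(mobile_fraction, "mobile_fraction", 0, 1),
    rate_k = check_number(rate_k, "rate_k", 0),
    bleach_depth = check_number(bleach_depth, "bleach_depth", 0, 1, strict_min = TRUE),
    pre_frames = check_count(pre_frames, "pre_frames", min = 1L),
    post_frames = check_count(post_frames, "post_frames", min = 2L),
    frame_interval_s = check_number(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE),
    baseline = check_number(baseline, "baseline", 0, strict_min = TRUE),
    noise_sigma = check_number(noise_sigma, "noise_sigma", 0),
    seed = check_count(seed, "seed"))
  class(p) <- "frap_sim_params"
  p
}

#' Simulate a FRAP recovery trace
#'
#' Pre-bleach frames sit at the baseline; the first post-bleach frame drops
#' to `baseline * (1 - bleach_depth)`; subsequent frames follow the
#' one-phase association model
#' `F(t) = F0 + (Fi - F0) * mobile_fraction * (1 - exp(-k t))`
#' with `t` measured from the first post-bleach frame, plus additive
#' Gaussian noise.
#'
#' @param params a [frap_sim_params()].
#' @return A [frap_trace()]; the true parameters are attached as
#'   attribute `"truth"`.
#' @export
simulate_frap_trace <- function(params = frap_sim_params()) {
  stopifnot(inherits(params, "frap_sim_params"))
  dt <- params$frame_interval_s
  n_pre <- params$pre_frames; n_post <- params$post_frames
  t_pre <- seq(-n_pre, -1) * dt
  t_post <- seq(0, n_post - 1) * dt
  Fi <- params$baseline
  F0 <- Fi * (1 - params$bleach_depth)
  recovery <- F0 + (Fi - F0) * params$mobile_fraction *
    (1 - exp(-params$rate_k * t_post))
  intens <- c(rep(Fi, n_pre), recovery)
  if (params$noise_sigma > 0)
    intens <- with_seed(params$seed,
                        intens + rnorm(length(intens), 0, params$noise_sigma))
  tr <- frap_trace(times_s = c(t_pre, t_post), intensities = intens,
                   n_pre = n_pre)
  attr(tr, "truth") <- params
  tr
}

#' Simulate a time-lapse with a moving intensity focus
#'
#' A bright Gaussian focus translates at constant speed along a straight
#' path in an otherwise dim field; used to benchmark kymograph extraction.
#'
#' @param path_length_um length of the path, micrometres.
#' @param speed_um_per_frame focus displacement per frame.
#' @param n_frames number of frames (>= 2).
#' @param pixel_size_um pixel size, micrometres.
#' @param frame_interval_s frame interval, seconds.
#' @param focus_sigma_um Gaussian sigma of the focus.
#' @param amplitude focus peak intensity over the background.
#' @param background background intensity.
#' @param noise_sigma additive Gaussian noise sigma.
#' @param seed integer RNG seed.
#' @return A list with `stack` (a time-lapse [calibrated_stack()]), `path`
#'   (a [polyline_path()] along the focus trajectory) and `truth` (data
#'   frame of per-frame focus positions, micrometres along the path).
#' @export
generate_kymograph_stack <- function(path_length_um = 8,
                                     speed_um_per_frame = 0.4,
                                     n_frames = 10L,
                                     pixel_size_um = 0.2,
                                     frame_interval_s = 30,
                                     focus_sigma_um = 0.5,
                                     amplitude = 100,
                                     background = 5,
                                     noise_sigma = 0,
                                     seed = 1L) {
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_number(path_length_um, "path_length_um", 0, strict_min = TRUE)
  margin <- 4 * focus_sigma_um + 1
  fov <- path_length_um + 2 * margin
  n_xy <- ceiling(fov / pixel_size_um)
  xs <- (seq_len(n_xy) - 0.5) * pixel_size_um
  y0 <- n_xy * pixel_size_um / 2
  gy <- exp(-(xs - y0)^2 / (2 * focus_sigma_um^2))
  vox <- array(background, c(n_xy, n_xy, n_frames, 1L))
  pos <- pmin(pmax((seq_len(n_frames) - 1) * speed_um_per_frame, 0),
              path_length_um)
  for (f in seq_len(n_frames)) {
    fx <- margin + pos[f]
    gx <- exp(-(xs - fx)^2 / (2 * focus_sigma_um^2))
    vox[, , f, 1L] <- background + amplitude * outer(gy, gx)
  }
  if (noise_sigma > 0)
    vox[] <- with_seed(seed, pmax(vox + rnorm(length(vox), 0, noise_sigma), 0))
  stack <- calibrated_stack(vox, pixel_size_um, channel_names = "focus",
                            frame_interval_s = frame_interval_s, axis3 = "t")
  path <- polyline_path(rbind(c(margin, y0), c(margin + path_length_um, y0)),
                        width_um = 0.8)
  list(stack = stack, path = path,
       truth = data.frame(frame = seq_len(n_frames), position_um = pos))
}
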