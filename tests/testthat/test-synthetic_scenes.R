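test_that("doublet generator is deterministic and geometrically faithful", {
  p <- scene_params(par3_enrichment = 4, noise_gaussian_sigma = 10,
                    puncta_density = 3L, seed = 42L)
  a <- generate_doublet_scene(p)
  b <- generate_doublet_scene(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$cell_centres, b$truth$cell_centres)

  ## midpoint lies on the chord segment
  tr <- a$truth
  chord <- tr$interface_chord_endpoints
  mid <- (chord[1, ] + chord[2, ]) / 2
  expect_equal(unname(tr$interface_midpoint), unname(mid))

  ## long axis passes through both cell centres (collinearity in xy)
  ax <- tr$long_axis_endpoints
  d <- ax[2, 1:2] - ax[1, 1:2]
  for (i in 1:2) {
    u <- tr$cell_centres[i, 1:2] - ax[1, 1:2]
    expect_equal(abs(u[1] * d[2] - u[2] * d[1]), 0, tolerance = 1e-9)
  }

  ## geometry error when the cells cannot overlap
  expect_error(
    generate_doublet_scene(scene_params(centre_spacing_factor = 2.5)),
    class = "amisquant_geometry_error")
})

test_that("PAR-3 focus encodes the enrichment factor at the interface midpoint", {
  ## E = 1: the noiseless PAR-3 reference is flat along the membrane
  d1 <- generate_doublet_scene(scene_params(par3_enrichment = 1))
  ref1 <- d1$truth$reference$par3
  A <- d1$truth$params$membrane_amplitude
  expect_setequal(unique(as.vector(ref1)), c(0, A))

  ## E = 4: the brightest voxel of the noiseless reference lies within one
  ## spot sigma of the true midpoint (brute-force argmax)
  d4 <- generate_doublet_scene(scene_params(par3_enrichment = 4))
  ref4 <- d4$truth$reference$par3
  mx <- which(ref4 == max(ref4), arr.ind = TRUE)[1, ]
  pos <- c((mx[2] - 0.5) * 0.2, (mx[1] - 0.5) * 0.2, (mx[3] - 0.5) * 2)
  expect_lt(sqrt(sum((pos - d4$truth$interface_midpoint)^2)),
            d4$truth$params$par3_spot_sigma_um)

  ## monotone encoding: midpoint intensity strictly increases with E
  at_mid <- vapply(c(1, 2, 4), function(E) {
    d <- generate_doublet_scene(scene_params(par3_enrichment = E))
    max(d$truth$reference$par3)
  }, numeric(1))
  expect_true(all(diff(at_mid) > 0))
})

test_that("cluster generator handles the multi-cell junction and delegates doublets", {
  p2 <- scene_params(n_cells = 2L, seed = 7L)
  expect_identical(generate_cluster_scene(p2)$stack$voxels,
                   generate_doublet_scene(p2)$stack$voxels)

  cl <- generate_cluster_scene(scene_params(n_cells = 4L, par3_enrichment = 1))
  ## null case: the PAR-3 central-section projection is two-valued, so any
  ## junction disc mean equals the membrane level elsewhere
  proj <- central_section_project(cl$stack, "par3")
  A <- cl$truth$params$membrane_amplitude
  expect_setequal(unique(as.vector(proj$pixels)), c(0, A))
  rr <- scene_ratio(cl)
  expect_equal(rr$ratio, 1, tolerance = 1e-12)

  ## enrichment at the junction raises the measured ratio
  cl3 <- generate_cluster_scene(scene_params(n_cells = 4L, par3_enrichment = 3))
  expect_gt(scene_ratio(cl3)$ratio, scene_ratio(cl)$ratio)
})

test_that("simulated FRAP traces follow the association model exactly", {
  ## immobile limit: all post-bleach frames stay at F(0)
  tr0 <- simulate_frap_trace(frap_sim_params(mobile_fraction = 0, noise_sigma = 0))
  post <- tr0$intensities[-(1:3)]
  expect_true(all(post == post[1]))

  ## full recovery limit: fast kinetics converge to the baseline
  tr1 <- simulate_frap_trace(frap_sim_params(mobile_fraction = 1, rate_k = 5,
                                             noise_sigma = 0, baseline = 100))
  expect_equal(tail(tr1$intensities, 1), 100, tolerance = 1e-6)

  ## closed form: normalised value at t = 300 s for m = 0.6, k = 0.02
  tr <- simulate_frap_trace(frap_sim_params(mobile_fraction = 0.6, rate_k = 0.02,
                                            noise_sigma = 0, post_frames = 31L))
  nz <- normalize_frap(tr)
  expect_equal(nz$values[nz$times_s == 300], 0.6 * (1 - exp(-6)),
               tolerance = 1e-12)

  ## noiseless traces match the association formula pointwise
  expect_equal(nz$values, oracle_association(nz$times_s, 0.6, 0.02),
               tolerance = 1e-9)

  ## determinism under a fixed seed, difference under another
  a <- simulate_frap_trace(frap_sim_params(noise_sigma = 2, seed = 5L))
  b <- simulate_frap_trace(frap_sim_params(noise_sigma = 2, seed = 5L))
  c <- simulate_frap_trace(frap_sim_params(noise_sigma = 2, seed = 6L))
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("moving-focus time-lapse records its trajectory truthfully", {
  ## zero speed: constant position
  still <- generate_kymograph_stack(speed_um_per_frame = 0, n_frames = 5L)
  expect_true(all(still$truth$position_um == 0))
  expect_identical(still$stack$voxels[, , 1, 1], still$stack$voxels[, , 5, 1])

  ## constant speed: position = speed * (frame - 1)
  mv <- generate_kymograph_stack(speed_um_per_frame = 0.4, n_frames = 8L)
  expect_equal(mv$truth$position_um, 0.4 * (0:7))
})

test_that("scene parameters are validated", {
  expect_error(scene_params(cell_radius_um = -1), class = "amisquant_config_error")
  expect_error(scene_params(n_cells = 0), class = "amisquant_config_error")
  expect_error(scene_params(pixel_size_um = 0), class = "amisquant_config_error")
  expect_error(frap_sim_params(mobile_fraction = 1.2), class = "amisquant_config_error")
  expect_error(frap_sim_params(bleach_depth = 0), class = "amisquant_config_error")
})
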