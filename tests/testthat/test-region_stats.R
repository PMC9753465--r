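test_that("central-versus-surround ratio matches the pixelwise mask oracle", {
  ## uniform image inside any mask: ratio 1
  img <- projected_image(matrix(13, 60, 60), 0.5)
  mask <- matrix(TRUE, 60, 60)
  rr <- central_vs_surround_ratio(img, mask, c(15, 15), 4)
  expect_equal(rr$ratio, 1)

  ## synthetic cluster with enrichment: ratio equals brute-force masked
  ## means and exceeds 1
  cl <- generate_cluster_scene(scene_params(n_cells = 4L, par3_enrichment = 3))
  proj <- central_section_project(cl$stack, "par3")
  rr <- scene_ratio(cl)
  disc <- disc_mask(proj, cl$truth$interface_midpoint[1:2], 4)
  m_c <- mean(proj$pixels[disc & cl$truth$membrane_mask])
  m_s <- mean(proj$pixels[cl$truth$membrane_mask & !disc])
  expect_equal(rr$mean_central, m_c)
  expect_equal(rr$mean_surround, m_s)
  expect_equal(rr$ratio, m_c / m_s)
  expect_gt(rr$ratio, 1)

  ## zero image: undefined-ratio error
  z <- projected_image(matrix(0, 30, 30), 0.5)
  expect_error(central_vs_surround_ratio(z, matrix(TRUE, 30, 30), c(7, 7), 4),
               class = "amisquant_undefined_ratio_error")
  ## disc outside the cluster: geometry error
  off <- matrix(FALSE, 60, 60); off[1:10, 1:10] <- TRUE
  expect_error(central_vs_surround_ratio(img, off, c(25, 25), 4),
               class = "amisquant_geometry_error")
})

test_that("ratios are invariant under multiplicative gain", {
  cl <- generate_cluster_scene(scene_params(n_cells = 4L, par3_enrichment = 2))
  proj <- central_section_project(cl$stack, "par3")
  scaled <- projected_image(proj$pixels * 11.3, proj$pixel_size_um, proj$channel)
  r1 <- central_vs_surround_ratio(proj, cl$truth$membrane_mask,
                                  cl$truth$interface_midpoint[1:2])
  r2 <- central_vs_surround_ratio(scaled, cl$truth$membrane_mask,
                                  cl$truth$interface_midpoint[1:2])
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("disc rasterisation is centre-in-circle with near-analytic area", {
  img <- projected_image(matrix(0, 200, 200), 0.1)
  for (dia in c(2.5, 4, 6)) {
    m <- disc_mask(img, c(10, 10), dia)
    expect_equal(sum(m) * 0.1^2, pi * (dia / 2)^2,
                 tolerance = 4 * dia * 0.1 / (pi * (dia / 2)^2))
  }
})

test_that("core-versus-whole-cell ratio uses the whole cell as denominator", {
  ## core diameter is mandatory
  img <- projected_image(matrix(1, 50, 50), 0.5)
  mask <- matrix(TRUE, 50, 50)
  expect_error(core_vs_cell_ratio(img, mask, c(12, 12)),
               class = "amisquant_config_error")

  ## uniform cell: ratio 1
  expect_equal(core_vs_cell_ratio(img, mask, c(12, 12), 6)$ratio, 1)

  ## central Gaussian core: matches the pixelwise oracle
  px <- 0.2
  xs <- (1:100 - 0.5) * px
  g <- outer(exp(-(xs - 10)^2 / 4), exp(-(xs - 10)^2 / 4)) * 50 + 5
  gi <- projected_image(g, px)
  cmask <- disc_mask(gi, c(10, 10), 16)
  rr <- core_vs_cell_ratio(gi, cmask, c(10, 10), 6)
  core <- disc_mask(gi, c(10, 10), 6) & cmask
  expect_equal(rr$ratio, mean(g[core]) / mean(g[cmask]), tolerance = 1e-12)
  expect_gt(rr$ratio, 1)

  ## core disc fully outside the cell: geometry error
  side <- matrix(FALSE, 100, 100); side[1:20, 1:20] <- TRUE
  expect_error(core_vs_cell_ratio(gi, side, c(15, 15), 2),
               class = "amisquant_geometry_error")
})

test_that("interface-versus-matrix intensity compares the two bands", {
  ## uniform image: ratio 1
  img <- projected_image(matrix(3, 40, 40), 0.5)
  b1 <- matrix(FALSE, 40, 40); b1[, 20] <- TRUE
  b2 <- matrix(FALSE, 40, 40); b2[, 5] <- TRUE
  expect_equal(interface_vs_matrix_intensity(img, b1, b2)$ratio, 1)

  ## doublet scene: shared interface carries twice the outer membrane
  d <- generate_doublet_scene(scene_params())
  proj <- central_section_project(d$stack, "cadherin")
  rr <- interface_vs_matrix_intensity(proj, d$truth$interface_band_mask,
                                      d$truth$matrix_band_mask)
  expect_equal(rr$ratio, 2, tolerance = 1e-9)

  ## overlapping bands: mask error; empty band: mask error
  expect_error(interface_vs_matrix_intensity(img, b1, b1),
               class = "amisquant_mask_error")
  expect_error(interface_vs_matrix_intensity(img, b1, matrix(FALSE, 40, 40)),
               class = "amisquant_mask_error")
})

test_that("heatmaps are block means with remainder to the earliest rows", {
  ## uniform ROI: all 100 units equal
  img <- projected_image(matrix(2.5, 80, 80), 0.5)
  hm <- build_cell_heatmap(img, list(corner_um = c(5, 5), side_um = 20))
  expect_true(all(hm$units == 2.5))

  ## 20 x 20 ROI with a linear x-gradient: 2 x 2 block means, strictly
  ## increasing column means
  m <- matrix(rep(1:20, each = 20), 20, 20)  # value = column index
  gi <- projected_image(m, 1)
  hm2 <- build_cell_heatmap(gi, list(corner_um = c(0, 0), side_um = 20))
  expect_equal(hm2$units, oracle_block_means(m, 10))
  expect_true(all(diff(colMeans(hm2$units)) > 0))

  ## non-divisible ROI side still matches the oracle
  set.seed(31)
  m2 <- matrix(runif(23 * 23), 23, 23)
  hm3 <- build_cell_heatmap(projected_image(m2, 1),
                            list(corner_um = c(0, 0), side_um = 23))
  expect_equal(hm3$units, oracle_block_means(m2, 10), tolerance = 1e-12)

  ## ROI smaller than the grid: precondition error
  expect_error(build_cell_heatmap(gi, list(corner_um = c(0, 0), side_um = 8)),
               class = "amisquant_precondition_error")
})

test_that("heatmap stacking and central level follow their index contracts", {
  set.seed(32)
  mk <- function() {
    img <- projected_image(matrix(runif(400), 20, 20), 1)
    build_cell_heatmap(img, list(corner_um = c(0, 0), side_um = 20))
  }
  maps <- replicate(15, mk(), simplify = FALSE)
  st <- stack_heatmaps(maps)
  expect_equal(st$units,
               Reduce(`+`, lapply(maps, `[[`, "units")) / 15, tolerance = 1e-12)
  expect_identical(st$n_cells, 15L)

  ## N identical maps: average equals each; two maps: unit-wise mean
  same <- stack_heatmaps(maps[c(1, 1, 1)])
  expect_equal(same$units, maps[[1]]$units)
  expect_equal(stack_heatmaps(maps[1:2])$units,
               (maps[[1]]$units + maps[[2]]$units) / 2)
  expect_error(stack_heatmaps(list()), class = "amisquant_precondition_error")

  ## central level: mean of units (5,5),(5,6),(6,5),(6,6)
  u <- maps[[1]]
  expect_equal(heatmap_central_level(u),
               mean(u$units[5:6, 5:6]), tolerance = 1e-12)
  flat <- u; flat$units <- matrix(4.2, 10, 10)
  expect_equal(heatmap_central_level(flat), 4.2)
  one <- u; one$units <- matrix(0, 10, 10); one$units[5, 5] <- 4
  expect_equal(heatmap_central_level(one), 1)
})
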