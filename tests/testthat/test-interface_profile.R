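test_that("path sampling averages the perpendicular band correctly", {
  ## uniform image: every sample equals the constant
  img <- projected_image(matrix(7, 40, 40), 0.2)
  p <- polyline_path(rbind(c(1, 1), c(6, 5)), width_um = 0.8)
  prof <- sample_path_intensity(img, p)
  expect_true(all(abs(prof$values - 7) < 1e-12))
  expect_identical(prof$n_perpendicular, 5L)  # 0.8 um band at 0.2 um pixels

  ## straight axis-aligned path: samples equal column-wise 3-pixel means
  set.seed(21)
  m <- matrix(runif(20 * 30, 0, 100), 20, 30)
  px <- 1
  ## path along row 10 (y centre = 9.5), width 3 px -> rows 9:11
  path <- polyline_path(rbind(c(0.5, 9.5), c(29.5, 9.5)), width_um = 3)
  prof <- sample_path_intensity(projected_image(m, px), path)
  oracle <- colMeans(m[9:11, ])
  expect_equal(prof$values, oracle, tolerance = 1e-12)

  ## a path leaving the image raises a geometry error
  bad <- polyline_path(rbind(c(-5, 2), c(2, 2)), width_um = 1)
  expect_error(sample_path_intensity(projected_image(m, px), bad),
               class = "amisquant_geometry_error")
})

test_that("interface ends are the per-half actin argmaxes", {
  v <- two_peak_profile(100, 10, 90)
  expect_identical(unname(detect_interface_ends(v)), c(10L, 90L))

  ## mirror-symmetric profile: endpoints symmetric about the midpoint
  v2 <- two_peak_profile(101, 21, 81)
  ends <- detect_interface_ends(v2)
  expect_equal(unname(ends[1] - 1 + ends[2] - 1), 100)

  ## flat profile: detection error
  expect_error(detect_interface_ends(rep(3, 50)),
               class = "amisquant_detection_error")
  ## one flat half (below prominence): detection error
  flat_half <- c(rep(0.5, 50), two_peak_profile(50, 10, 40)[1:50] * 10)
  expect_error(detect_interface_ends(flat_half),
               class = "amisquant_detection_error")
  ## too few samples: precondition error
  expect_error(detect_interface_ends(c(1, 2, 1)),
               class = "amisquant_precondition_error")
})

test_that("20-bin sectioning matches direct index-range averaging", {
  ## worked case: 100 samples valued 1..100 -> bin 1 mean 3, bin 20 mean 98
  prof <- make_profile(1:100)
  bp <- bin_profile(prof, start_idx = 1L, end_idx = 100L)
  expect_equal(bp$bin_means[1], 3)
  expect_equal(bp$bin_means[20], 98)
  expect_equal(bp$bin_means, oracle_bin_means(1:100, 20))
  expect_identical(bp$n_bins, 20L)

  ## constant span: all bins equal
  bpc <- bin_profile(make_profile(rep(4.5, 60)), start_idx = 11L, end_idx = 50L)
  expect_true(all(bpc$bin_means == 4.5))

  ## conservation when 20 divides the span: mean of bins = mean of samples
  v <- runif(80)
  bpv <- bin_profile(make_profile(v), start_idx = 1L, end_idx = 80L)
  expect_equal(mean(bpv$bin_means), mean(v), tolerance = 1e-12)

  ## randomised oracle equivalence, non-divisible spans included
  set.seed(22)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    v <- runif(n, 0, 1000)
    s <- sample(1:(n - 20), 1)
    e <- sample((s + 19):n, 1)
    bp <- bin_profile(make_profile(v), start_idx = s, end_idx = e)
    expect_identical(bp$bin_means, oracle_bin_means(v[s:e], 20))
  }

  ## spans shorter than the bin count are rejected
  expect_error(bin_profile(make_profile(1:30), start_idx = 1L, end_idx = 15L),
               class = "amisquant_precondition_error")
  ## unset endpoints are rejected
  expect_error(bin_profile(make_profile(1:30)),
               class = "amisquant_precondition_error")
})

test_that("binning is gain-invariant in shape", {
  set.seed(23)
  v <- runif(120, 10, 50)
  a <- bin_profile(make_profile(v), start_idx = 7L, end_idx = 113L)
  b <- bin_profile(make_profile(3.7 * v), start_idx = 7L, end_idx = 113L)
  expect_equal(b$bin_means, 3.7 * a$bin_means, tolerance = 1e-12)
  expect_equal(b$bin_means / b$bin_means[1], a$bin_means / a$bin_means[1],
               tolerance = 1e-12)
})

test_that("profile averaging is the elementwise mean with dispersion", {
  set.seed(24)
  mk <- function() bin_profile(make_profile(runif(100)), start_idx = 1L,
                               end_idx = 100L)
  one <- mk()
  expect_equal(average_binned_profiles(list(one))$bin_means, one$bin_means)

  ps <- replicate(15, mk(), simplify = FALSE)
  avg <- average_binned_profiles(ps)
  m <- do.call(rbind, lapply(ps, `[[`, "bin_means"))
  expect_equal(avg$bin_means, colMeans(m), tolerance = 1e-12)
  expect_equal(avg$dispersion, apply(m, 2, sd) / sqrt(15), tolerance = 1e-12)

  two <- average_binned_profiles(ps[1:2])
  expect_equal(two$bin_means, (ps[[1]]$bin_means + ps[[2]]$bin_means) / 2)
  expect_error(average_binned_profiles(list()),
               class = "amisquant_precondition_error")
})

test_that("interface recovery on noiseless doublets peaks centrally", {
  for (E in c(2, 4)) {
    d <- generate_doublet_scene(scene_params(par3_enrichment = E))
    chord <- d$truth$interface_chord_endpoints[, 1:2]
    v <- chord[2, ] - chord[1, ]; v <- v / sqrt(sum(v^2))
    path <- polyline_path(rbind(chord[1, ] - 2 * v, chord[2, ] + 2 * v), 0.8)
    actin <- sample_path_intensity(central_section_project(d$stack, "actin"), path)
    par3 <- sample_path_intensity(central_section_project(d$stack, "par3"), path)
    par3 <- set_interface_ends(par3, actin)
    bp <- bin_profile(par3)
    expect_true(which.max(bp$bin_means) %in% 9:12)
  }
})

test_that("centre and side scans tile the interface symmetrically", {
  ## uniform image: equal areas under centre and side curves
  img <- projected_image(matrix(5, 120, 120), 0.2)
  cs <- centre_side_linescans(img, midpoint_um = c(12, 12),
                              direction_um = c(0, 1),
                              interface_length_um = 10)
  expect_equal(cs$auc_ratio, 1, tolerance = 1e-9)

  ## synthetic doublet, uniform cadherin along the interface: ratio ~ 1
  d <- generate_doublet_scene(scene_params())
  proj <- central_section_project(d$stack, "cadherin")
  tr <- d$truth
  dirv <- tr$interface_chord_endpoints[2, 1:2] - tr$interface_chord_endpoints[1, 1:2]
  len <- sqrt(sum(dirv^2))
  cs2 <- centre_side_linescans(proj, tr$interface_midpoint[1:2], dirv, len)
  expect_equal(cs2$auc_ratio, 1, tolerance = 0.05)

  ## too-short interface: geometry error
  expect_error(centre_side_linescans(img, c(12, 12), c(0, 1),
                                     interface_length_um = 5),
               class = "amisquant_geometry_error")
})
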