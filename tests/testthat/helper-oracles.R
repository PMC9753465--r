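## Independent brute-force oracles used across tests. These deliberately
## re-derive quantities with the most literal possible computation and must
## stay independent of the package's internals.

## mean over explicit near-equal index ranges, remainder to earliest bins
oracle_bin_means <- function(values, n_bins) {
  n <- length(values)
  base <- n %/% n_bins; rem <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) sizes[1:rem] <- base + 1
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  vapply(seq_len(n_bins), function(i) mean(values[starts[i]:stops[i]]),
         numeric(1))
}

## elementwise max over z-slices of a [y, x, z] array, by explicit loop
oracle_max_project <- function(vol, slices = seq_len(dim(vol)[3])) {
  out <- vol[, , slices[1]]
  for (k in slices[-1]) out <- pmax(out, vol[, , k])
  out
}

## block means of a square matrix partitioned into k x k near-equal blocks
oracle_block_means <- function(m, k) {
  n <- nrow(m)
  base <- n %/% k; rem <- n %% k
  sizes <- rep(base, k); if (rem > 0) sizes[1:rem] <- base + 1
  stops <- cumsum(sizes); starts <- c(1, head(stops, -1) + 1)
  out <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k)
    out[i, j] <- mean(m[starts[i]:stops[i], starts[j]:stops[j]])
  out
}

## closed-form one-phase association curve
oracle_association <- function(t, plateau, k) plateau * (1 - exp(-k * t))

## two-Gaussian actin profile with peaks at given sample indices
two_peak_profile <- function(n, p1, p2, sigma = 2.5, noise_sd = 0) {
  i <- seq_len(n)
  v <- exp(-(i - p1)^2 / (2 * sigma^2)) + exp(-(i - p2)^2 / (2 * sigma^2))
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  v
}

## wrap a numeric vector as an interface_profile without going through
## image sampling (unit spacing)
make_profile <- function(values, channel = "test") {
  structure(list(
    arc_positions_um = seq_along(values) - 1,
    values = as.numeric(values), channel = channel,
    n_perpendicular = 1L, width_um = 1,
    interface_start_idx = NA_integer_, interface_end_idx = NA_integer_,
    path = NULL, pixel_size_um = 1), class = "interface_profile")
}

## small wrapper: measured central/surround PAR-3 ratio of a scene, using
## the central-section projection and the truth membrane mask
scene_ratio <- function(scene, disc_diameter_um = 4) {
  proj <- central_section_project(scene$stack, "par3")
  central_vs_surround_ratio(proj, scene$truth$membrane_mask,
                            scene$truth$interface_midpoint[1:2],
                            disc_diameter_um = disc_diameter_um)
}
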