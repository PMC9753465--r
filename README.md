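# amisquant

Quantification of apical membrane initiation site (AMIS) polarity in small
embryonic stem-cell clusters from multi-channel fluorescence z-stacks.

When mouse embryonic stem cells form small clusters in 3D culture, polarity
proteins such as PAR-3 concentrate at the centre of the cell–cell interface
— the AMIS, where the future lumen opens. Quantifying that process from
confocal stacks requires a set of small, precise measurements that are
usually done ad hoc in Fiji: line-scans along interfaces, enrichment ratios
over hand-placed circles, per-cell heatmaps, FRAP recovery fits. This
package implements those procedures as tested, reusable R functions, and
pairs them with a synthetic-scene generator whose ground truth lets every
stage be verified quantitatively.

It is intended for cell biologists and image analysts quantifying
apical–basal polarity in doublets and small clusters, and for anyone who
needs a benchmarked reference implementation of these measurements.

## What it computes

- **Projections** — maximum-value projection of the whole stack
  (`max_project_full()`) or of the three central slices
  (`central_section_project()`), the two conventions used for counting
  clusters and for intensity measurements respectively.
- **Interface line-scans** — width-averaged intensity sampling along an
  annotated path (default width 0.8 µm), delimitation of the interface by
  the two cortical F-actin peaks (argmax per half-path with a prominence
  guard), and normalisation of the span into 20 bins of 5% interface
  length each (`sample_path_intensity()`, `detect_interface_ends()`,
  `bin_profile()`). Centre-versus-side 3 µm scans with area-under-curve
  comparison are provided by `centre_side_linescans()`.
- **Enrichment ratios** — mean intensity in a 4 µm disc at the
  multi-cellular junction over the mean of the remaining cluster region
  (`central_vs_surround_ratio()`); core-versus-whole-cell ratio with an
  explicit core diameter (`core_vs_cell_ratio()`); cell–cell versus
  cell–matrix band intensity (`interface_vs_matrix_intensity()`).
- **Heatmaps** — square per-cell ROI averaged into a 10 × 10 unit matrix,
  stacked across cells, with the central-20% level
  (`build_cell_heatmap()`, `stack_heatmaps()`, `heatmap_central_level()`).
- **FRAP kinetics** — normalisation FRAP(t) = (F(t) − F(0)) / (F(i) − F(0))
  with F(i) the mean of the pre-bleach frames and F(0) the first
  post-bleach frame, followed by a least-squares fit of the one-phase
  association model Y(t) = plateau · (1 − e^(−kt)) with Y(0) = 0; the
  plateau is the mobile fraction (`normalize_frap()`,
  `fit_one_phase_association()`, `bleach_depth()`).
- **Morphometrics** — centrosome separation normalised to the doublet long
  axis (`centrosome_separation()`, `long_axis_from_mask()`), kymographs
  averaged over 0.2 µm path sections (`compute_kymograph()`), and a
  threshold classifier for polarised centres on synthetic benchmarks
  (`classify_polarized_centre()`).
- **Synthetic scenes** — calibrated doublet/cluster stacks with a tunable
  PAR-3 enrichment factor E at the interface midpoint, FRAP traces with
  known mobile fraction and rate, and moving-focus time-lapses — all with
  ground truth (`generate_doublet_scene()`, `generate_cluster_scene()`,
  `simulate_frap_trace()`, `generate_kymograph_stack()`).

## Worked example

```r
library(amisquant)

## a noisy doublet with 4x PAR-3 enrichment at the interface midpoint
scene <- generate_doublet_scene(scene_params(par3_enrichment = 4,
                                             noise_gaussian_sigma = 10,
                                             seed = 11))
proj_actin <- central_section_project(scene$stack, "actin")
proj_par3  <- central_section_project(scene$stack, "par3")

## line-scan along the interface chord, extended 2 um past each end
chord <- scene$truth$interface_chord_endpoints[, 1:2]
v <- chord[2, ] - chord[1, ]; v <- v / sqrt(sum(v^2))
path <- polyline_path(rbind(chord[1, ] - 2 * v, chord[2, ] + 2 * v),
                      width_um = 0.8)
par3 <- set_interface_ends(sample_path_intensity(proj_par3, path),
                           sample_path_intensity(proj_actin, path))
par3
#> <interface_profile> 69 samples over 13.6 um, channel 'par3', interface samples 11..59

round(bin_profile(par3)$bin_means, 1)
#>  [1] 107.6  84.7  80.4  84.7 100.7 156.6 249.4 339.8 358.7 298.9 229.0 169.6
#> [13] 119.0  99.1  83.9  81.7  81.4  84.4 102.6 110.8

central_vs_surround_ratio(proj_par3, scene$truth$membrane_mask,
                          scene$truth$interface_midpoint[1:2])
#> <region_ratio_result> central_vs_surround: 278.1 / 105.3 = 2.641 (channel 'par3')
```

The F-actin peaks delimit the interface (samples 11–59, i.e. exactly the
9.6 µm chord), the 20-bin profile peaks in the central bins — the AMIS
signature — and the junction disc carries 2.6× the PAR-3 of the rest of
the membrane, classified as a polarised centre at the default 1.5
threshold.

```r
tr  <- simulate_frap_trace(frap_sim_params(mobile_fraction = 0.6,
                                           rate_k = 0.02,
                                           noise_sigma = 2, seed = 5))
summary(fit_one_phase_association(tr))
#> One-phase association fit, Y(t) = plateau * (1 - exp(-k t)), Y(0) = 0
#>   mobile fraction (plateau): 0.618
#>   rate k: 0.01813 /s   half-time: 38.23 s
#>   n = 30, RSS = 0.01449, residual sigma = 0.02275, converged: TRUE
```

A 33-frame trace (3 pre-bleach + 30 post-bleach, 10 s interval) simulated
with a true mobile fraction of 0.6 and k = 0.02 s⁻¹ is recovered as
0.618 and 0.018 s⁻¹ under noise.

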