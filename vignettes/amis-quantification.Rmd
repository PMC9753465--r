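---
title: "Quantifying AMIS polarity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AMIS polarity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amisquant)
```

# The measurement problem

In 3D culture, small clusters of mouse embryonic stem cells polarise
towards a shared apical membrane initiation site (AMIS): PAR-3 and other
apical determinants concentrate at the centre of the cell–cell interface
(doublets) or at the multi-cellular junction (larger clusters), and a
lumen later opens there. The quantities that describe this process are
simple but easy to get subtly wrong: intensity profiles along annotated
interface paths, ratios of mean intensities over hand-placed regions,
per-cell intensity heatmaps, and recovery kinetics from photobleaching.
This vignette documents how `amisquant` defines each measurement, the
parameters that matter, and the choices made where the procedure was
genuinely open.

# Coordinate and projection conventions

Image arrays are indexed `[y, x, z, channel]` (column-major, as is natural
in R); all physical quantities are micrometres. The centre of the voxel
with 1-based index `i` along an axis with spacing `s` lies at
`(i − 0.5)·s`, so a volume of `n` voxels spans `[0, n·s]`. All geometry
(paths, disc centres, scene truth) is expressed in these physical
coordinates and converted to pixels at sampling time; sub-pixel reads use
bilinear interpolation.

Two projections are used. `max_project_full()` takes the per-pixel maximum
over all slices and is the overview convention (counting clusters).
`central_section_project()` takes the maximum over exactly the three
central slices and is the measurement convention (line-scans, region
ratios, heatmaps): it restricts the signal to the cluster's equatorial
plane, where the interface is seen edge-on. For an even slice count the
centre is ambiguous; we use 1-based slices
`{⌊n/2⌋, ⌊n/2⌋+1, ⌊n/2⌋+2}` and record the slice set in the projection's
provenance. Projections preserve the input intensity scale — no rescaling
— because every downstream statistic must be gain-faithful.

# Interface line-scans

A line-scan is defined by a polyline path (drawn along the interface using
the F-actin or E-cadherin channel as a guide) and a perpendicular
averaging width, default **0.8 µm**. Samples are taken at arc-length steps
of one pixel; at each position the value is the mean of bilinear reads
along the perpendicular segment. The number of perpendicular sub-samples
is `ceiling(width / pixel)` forced odd (5 sub-samples for 0.8 µm at
0.2 µm pixels), each at the centre of an equal sub-strip — a midpoint rule
that makes a 3-pixel-wide band average exactly the three pixel centres.

The interface itself is delimited by the two cortical F-actin peaks at the
ends of the path: the start is the argmax over the first half of the
samples and the end the argmax over the second half, the split being at
the sample midpoint (the procedure is stated in terms of the two terminal
peaks; an exact split point is a convention we fix here). A half whose
dynamic range is below 5% of the profile's full range has no
distinguishable peak and raises a detection error rather than returning a
spurious index — a guard needed once peak-reading is automated rather than
manual.

The span between the detected endpoints is partitioned into **20
contiguous bins of near-equal sample count** — each covering 5% of the
interface length — and averaged per bin. When 20 does not divide the span,
the remainder goes to the earliest bins; this is deterministic and
order-independent, and the error it introduces is bounded by one sample
per bin. Bin means are linear in image gain, so bin *ratios* are
acquisition-independent.

Centre-versus-side comparisons use three width-averaged scans taken
perpendicular across the interface: one centred at the interface midpoint
and one at each side, at centre-to-centre offsets of one scan width
(default **3 µm**) so the bands tile without overlap; the two side scans
are averaged and the comparison statistic is the area under each curve
(trapezoidal rule).

# Region statistics

`central_vs_surround_ratio()` implements the cluster polarisation
statistic: the mean intensity inside a disc (default diameter **4 µm**)
placed over the multi-cellular junction, divided by the mean over the
remainder of the annotated cluster region. `core_vs_cell_ratio()` is the
single-cell variant whose denominator is the *whole* cell region
(including the core). Its core diameter is deliberately a required
argument with no default: published layouts use different core sizes for
different comparisons (a 6 µm circle for marker cores of glass-cultured
cells, 2.5 µm for a central core against the whole cell surface), and a
silent default would invite cross-condition mistakes.

Discs are rasterised by the centre-in-circle rule (a pixel belongs iff its
centre lies inside), which is deterministic and keeps the pixel area
within a one-pixel-row band of the analytic `π(d/2)²`. Ratios are
undefined when the denominator mean is non-positive and raise a typed
error; they are never returned as `NaN`.

Per-cell heatmaps average a square ROI fitted to the cell body into a
**10 × 10** matrix: rows and columns are partitioned into 10 near-equal
runs (remainder to the earliest, mirroring interface binning) and each
unit is its block mean. Heatmaps from all cells of a condition are stacked
by unit-wise averaging. The "central 20%" summary is the mean of the
central 2 × 2 unit block — central 20% *of each axis*; reading it instead
as the central 20% of units by distance would be a different statistic,
so the axis fraction is an explicit parameter.

# FRAP kinetics

Traces carry the mean intensity of the bleached region per frame, with
`n_pre` pre-bleach frames (default 3, then 30 post-bleach frames at 10 s,
matching common acquisition). Normalisation is

FRAP(t) = (F(t) − F(0)) / (F(i) − F(0)),

with F(i) the mean of the pre-bleach frames and F(0) the first
post-bleach frame; time is rebased to 0 at the F(0) frame. The formula is
invariant under affine intensity transforms `aF + b` (a > 0), which the
test suite asserts end-to-end through the fit. A trace with F(i) = F(0)
carries no bleach and is rejected as degenerate. The companion QC
statistic is the bleach depth `1 − F(0)/F(i)`.

The recovery is fitted by least squares to the one-phase association
model with the intercept pinned at zero,

Y(t) = plateau · (1 − e^(−kt)),

whose plateau is the **mobile fraction**. Fitting uses
Levenberg–Marquardt (via `minpack.lm`), initialised at plateau₀ = mean of
the last five normalised points and k₀ = ln 2 / (half-rise time), bounded
to plateau ∈ [0, 2] and k ∈ [0, 10] s⁻¹, with a fixed schedule of three
seeded random restarts on failure. The initialisation is deliberately
data-driven: short noisy traces (30 points) fit reliably from it, and the
bounds exclude only physically meaningless solutions. An all-zero
normalised trace short-circuits to plateau = 0 (the model gradient is
singular there). Fits can be made per trace and pooled afterwards — the
default, since pooling fits loses per-trace variability — or on averaged
traces by averaging `frap_trace` intensities first.

# Morphometrics

Centrosome separation is the Euclidean distance between the two
centrosomes divided by the doublet long-axis length — dimensionless,
scale-invariant, in [0, 1] for centrosomes inside the doublet. When no
axis annotation exists, `long_axis_from_mask()` computes the Feret
diameter of the doublet mask exactly (maximal pairwise distance over
convex-hull boundary pixel centres).

Kymographs sample each frame along the path and average contiguous
**0.2 µm** sections (remainder handling as in interface binning), one row
per frame. The ridge (per-row argmax) tracks a moving focus to within one
section on simulated data.

`classify_polarized_centre()` is an explicit surrogate for manual
polarised-centre scoring, intended for synthetic benchmarks only: positive
iff the central-versus-surround ratio is ≥ a threshold (default 1.5, tie
counts as positive, threshold recorded in the output). No claim is made
that any fixed threshold reproduces human scoring of real images; the
default separates enriched (E = 3) from null synthetic scenes with ≥ 95%
agreement at SNR 5, which is what the benchmark requires.

# The synthetic-scene generator

The generator exists so that every measurement above can be verified
against known truth. A scene is a calibrated three-channel z-stack
(default 30 × 30 µm field, 0.2 µm pixels, 7 slices at 2 µm — the live-
imaging regime; fixed-sample work uses finer z-steps, which the container
supports) of spherical cells truncated by the bisector planes towards
their neighbours, so adjacent cells share a flat interface facet. Default
cell radius is 6 µm, with doublet centres 1.2 radii apart and cluster
centres 0.75 radii from the common junction — deep overlaps that produce
the wide interfaces these clusters show.

Channels: *actin* and *cadherin* are the sum of per-cell membrane shells,
so the shared facet carries twice the outer-membrane amplitude; *actin*
additionally carries junctional-vertex spots at the interface rim, giving
the two terminal peaks the interface detector requires (cortical actin is
enriched where contacts meet the free surface). *PAR-3* is the union of
shells at uniform amplitude plus a Gaussian polarity focus at the
interface midpoint whose peak brings the total there to E × the membrane
baseline; E = 1 is the unpolarised null, and midpoint intensity is
strictly increasing in E. Optional peripheral puncta (off by default) add
surface-localised PAR-3 clusters outside the interface.

The membrane cross-section is a top-hat of fixed thickness (0.6 µm)
rather than a Gaussian profile. This is a deliberate choice: it makes the
noiseless scene exactly two-valued, so the null calibration — every
enrichment statistic exactly 1 at E = 1 — holds to machine precision
rather than approximately, and any deviation measured downstream is
attributable to the measurement code, not to the phantom. Optional
Gaussian blur (`blur_sigma_um`) restores soft edges when realism matters
more than exactness. Noise follows the standard fluorescence-camera
model: Poisson on the scaled signal (photon shot noise), then additive
Gaussian (read noise), applied after blur; negative values are clamped at
zero to respect the non-negativity invariant of calibrated stacks.

Ground truth records cell centres, interface chord endpoints and midpoint,
long-axis endpoints, a polarised centrosome configuration, the noiseless
per-channel reference volumes, and 2-D masks (membrane support, interface
band, matrix-contact band) derived from the central-section projection —
the same convention the measurements use, so truth masks and measured
projections are commensurable.

FRAP simulation draws pre-bleach frames at the baseline, drops to
`baseline × (1 − bleach_depth)` at the first post-bleach frame and follows
the association model with the given mobile fraction and rate, plus
additive Gaussian noise; noiseless traces match the closed form pointwise.
The moving-focus time-lapse translates a Gaussian spot at constant speed
along a recorded path for kymograph benchmarking.

**What passing these benchmarks shows — and what it does not.** The
phantom reproduces the *statistical structure* the measurements assume:
membrane-localised signal, a central enrichment focus, two-peak interface
profiles, one-phase recovery. It does not model realistic point-spread
optics, depth-dependent attenuation, cell shape irregularity, mitotic
cells, or lumen-stage morphologies. Tests passing on these scenes
establish that the measurement code is correct, not that the biological
conclusions from any particular real dataset are.

# Determinism and reproducibility

Every generator takes an explicit integer seed and restores the caller's
RNG state, so identical parameters and seed give bit-identical outputs.
`run_pipeline()` derives all stage seeds from the single config seed and
writes a manifest echoing the full configuration; rerunning a config
reproduces every CSV byte-for-byte. Scene TIFFs are written as 32-bit
pages with a JSON sidecar carrying calibration and intensity scale;
storage quantisation is one part in 2³², the only step in the pipeline
that is not exact.

# Problem sizes

The test and acceptance suites run at deliberately modest sizes — 150 ×
150 × 7 voxel scenes, 100–200 random profiles per oracle comparison, 15
traces per FRAP condition, 100 scenes for the classifier benchmark —
chosen so the full suite verifies every stage in a few minutes on a single
core while keeping Monte-Carlo standard errors well inside the asserted
tolerances.

# Known limitations

- Interfaces are annotated (or taken from synthetic truth), never
  auto-traced; segmentation is out of scope.
- The FRAP model is the one-phase association only — no
  diffusion-reaction kinetics, no double normalisation against a
  reference region.
- The polarised-centre classifier is a synthetic-benchmark surrogate, not
  a replacement for expert scoring of real images.
- TIFF metadata is carried in a JSON sidecar; resolution tags of
  third-party TIFFs are not parsed, so plain files need explicit
  calibration overrides.
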