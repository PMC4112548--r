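---
title: "Quantifying spindle orientation, astral censuses and cortical profiles in neural progenitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spindle orientation, astral censuses and cortical profiles in neural progenitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitospindle)
```

## The measurement problem

Apical progenitors (APs) of the developing mouse neocortex divide at the
ventricular surface with their mitotic spindle — reported by the
metaphase chromosome plate — normally aligned with the apico-basal
tissue axis. The switch from symmetric proliferative to asymmetric
neurogenic division is accompanied by only subtle changes in spindle
orientation, so quantification has to be careful about conventions:
which axis is zero, what counts as an astral microtubule "reaching" the
cortex, which cortical region an astral belongs to, and how a per-cell
summary statistic is defined.

`mitospindle` implements this measurement chain:

1. **Plate orientation** — segment the chromosome plate in the DNA
   channel, take the principal axis of its second-order moments on the
   coronal projection, and report the signed deviation from the local
   apico-basal axis (the normal to the nearest segment of the annotated
   ventricular surface). 0° is "vertical" (plate along the apico-basal
   axis), ±90° is parallel to the surface, positive tilts the basal end
   toward +x.
2. **Amplitude statistic** — per cell, the range (max − min) of the
   signed deviations from metaphase to anaphase onset
   (`track_amplitude()`); prometaphase samples are ignored. Tracks are
   also categorized into six colour-coded angular ranges
   (`classify_track()`); range edges at 0°, ±15°, ±30° belong to the bin
   closer to 0° (and 0° itself to `"green"`), a convention the source
   figure legend leaves open.
3. **Astral census** — the soma is partitioned into apical, central and
   basal regions by the planes through the apical-most and basal-most
   peri/centromeric heterochromatin foci, the brightest DNA puncta
   (`detect_centromeric_foci()`, `partition_regions()`). Cortex-reaching
   astral microtubules are counted per region (`detect_astrals()`,
   `count_census()`), with the central count only assessed in "Side"
   view cells (`classify_view()`); basal progenitors, which lack apical
   surface contact, instead get orientation classes by sectors around
   the ventricle direction (`bp_orient_census()`).
4. **Cortical profile** — marker (LGN) intensity along the one-pixel
   soma contour, cytoplasm-subtracted, resampled to 100 equidistant
   positions of the normalized perimeter starting at the apical midpoint
   and running clockwise (`extract_contour()`, `subtract_cytoplasm()`,
   `resample_profile()`, `region_means()`).
5. **Spindle metrics** — the main spindle region (soma clipped to the
   foci band, extended by pole discs), its area, normalized mean
   intensity, normalized per-pixel SD, and the soma diameter at the
   spindle plane.
6. **Division symmetry** — whether the prospective cleavage plane
   (practically identical to the plate axis at anaphase onset) bisects
   or bypasses the apical membrane domain (`classify_division()`,
   `percent_asymmetric()`).
7. **Tissue censuses** — marker fractions by cortical zone (VZ/SVZ/CP),
   mitoses per 100 µm apical surface, neurons per 100 µm pial surface,
   apoptotic cells per 10,000 µm².
8. **Statistics** — mean ± SEM, Kruskal–Wallis with Dunn's multiple
   comparison, Student's t / Mann–Whitney U, one-way ANOVA with Tukey
   HSD (`mean_sem()`, `kw_dunn()`, `two_sample_tests()`,
   `anova_tukey()`).

Because no raw imaging data are deposited with the study this package
accompanies conceptually, every operation is validated against a
**ground-truthed synthetic microscopy generator** rather than against
archived micrographs. The generator is first-class, tested code: its
output records every generative parameter, and the tests demand that
the measurement chain recovers them.

## The synthetic cell

`random_cell_spec()` + `make_mitotic_cell()` render a metaphase AP as a
three-channel stack (`dna`, `tubulin`, `cortical`) with, by default, the
acquisition geometry used for microtubule analysis in this field:
0.09 × 0.09 µm pixels (0.75 µm optical sections for 3D stacks).

```{r, eval = FALSE}
spec <- random_cell_spec(n_apical = 5, n_basal = 6, n_central = 9, seed = 3)
sim <- make_mitotic_cell(spec, seed = 3)
sim$stack          # <image_stack> with dna / tubulin / cortical channels
sim$ground_truth   # every generative parameter, incl. the true census
```

Geometry (defaults, all µm, all configurable in `cell_spec()`):

* soma: ellipse/ellipsoid with semi-axes 5.0 × 6.2 (× optional z) — a
  columnar, apico-basally elongated metaphase soma below a flat
  ventricular surface;
* chromosome plate: 2.5 × 0.9 ellipse tilted by `plate_angle_deg` from
  the apico-basal axis, uniform intensity;
* peri/centromeric foci: sub-resolution point sources rendered as
  PSF-width Gaussians with peak exactly 2× the plate intensity, so "the
  brightest DNA voxels are the foci" holds by construction. Foci are
  placed in the inner 75 % (along) × 45 % (across) of the plate with
  ≥ 0.55 µm pairwise separation so they remain individually resolvable;
* spindle: two poles on the axis perpendicular to the plate, 1.9 µm
  from the plate centre, a dense central-spindle ellipse between them,
  bright pole spots, and one anti-aliased rod per astral microtubule.
  Overlapping rods composite by maximum (a rod's stain density does not
  double where rods converge at the pole);
* cortical channel: uniform cytoplasm inside the soma plus a one-pixel
  cortical band painted along the digital boundary chain with intensity
  `cortical_profile_fn(s)` above cytoplasm, where `s` is the normalized
  clockwise arc position from the apical midpoint — the same
  parameterization the profiling operation measures, which is what
  makes the generative profile well defined on a pixel grid. Profile
  values are clipped at 0 (intensities are non-negative);
* PSF: in-plane Gaussian blur (σ = 0.10 µm) on the DNA plate and the
  tubulin channel; the cortical band is left unblurred;
* noise: optional Poisson (shot) noise followed by additive Gaussian
  noise, both off by default; one seed drives one generator, and
  identical spec + seed gives voxel-identical stacks.

The census sampler places astral directions inside the *feasible angle
windows* of each (pole, region) pair — directions whose endpoint lands
in the requested cortical region with a ≥ 0.5 µm safety margin from the
partition planes — spacing them ≥ 8° apart on a pole so that adjacent
rods stay optically separable. Cortex-reaching rods end 0.4 µm inside
the soma boundary (well inside the 1.0 µm "reaching" tolerance);
deliberately short rods stop at 65 % of the pole-to-cortex distance and
are only accepted where that leaves them ≥ 1.6 µm from the boundary, so
tip erosion under thresholding can never flip them across the reaching
rule.

**What the generator does not emulate.** Photon-accurate optics (only a
Gaussian in-plane PSF), spectral bleed-through, photobleaching, tissue
background, chromosome-arm texture, curved astrals, or out-of-plane
astral geometry in 2D mode. Passing the recovery tests therefore shows
that the measurement chain is *correct under its stated geometric
conventions and robust to moderate noise* — not that it reproduces
expert manual counts on real micrographs, which cannot be tested
without the original data.

## The anchored-spindle trajectory model

The conceptual model behind the study is mechanical: astral microtubules
anchored at the apical/basal cell cortex act like guy ropes on a tent
pole, and fewer anchors mean larger excursions of spindle orientation.
The source gives no equations, so the quantitative form here is a
package design choice — the simplest stochastic process with a
restoring force proportional to anchor count, an Ornstein–Uhlenbeck
process in the plate angle:

$$ d\theta = -k_{\mathrm{eff}}\,\theta\,dt + \sigma\,dW,\qquad
   k_{\mathrm{eff}} = k\,(n_{\mathrm{polar}} + \varepsilon\,
   n_{\mathrm{central}}) $$

with stationary SD $\sigma/\sqrt{2k_{\mathrm{eff}}}$. Central-cortex
anchors pull nearly orthogonally to the tilt direction and enter with a
small weight (ε = 0.1). Sampling uses the exact AR(1) discretization,
so any `dt` is admissible. Defaults: `k = 0.08 /min` per anchor,
`σ = 7.5 deg/√min`, `dt = 1 min`, 15 min of metaphase ending at
anaphase onset (t = 0), θ(0) = 0, reflection at ±90°. These values were
chosen once so that a proliferating-AP-like anchor count (≈ 12
apical+basal astrals) yields amplitudes of the observed order
(~15–20°); the model's amplitude contrast across anchor counts is
compressed relative to real measurements because the OU form scales
only as $1/\sqrt{n}$ — the package treats the *direction* of the
effect (more anchors, smaller amplitude) as the claim under test, not
the exact ratios.

## Numerical and algorithmic choices

* **Plate axis**: 2D second-moment principal axis on the
  maximum-intensity projection; degenerate (isotropic) masks raise an
  error. Recovery on noise-free renders is better than 1° across tilts
  of ±60°; joint rotation of mask and surface changes the result by
  < 0.5° (discretization).
* **Foci**: local maxima inside the plate mask with prominence over the
  median plate intensity (default ≥ 0.3), deduplicated within 0.45 µm,
  refined to sub-pixel position by parabolic interpolation. The
  partition planes inherit that sub-pixel accuracy.
* **Poles**: brightest tubulin maxima outside the dilated plate mask,
  parabolically refined, then projected onto the spindle axis (the line
  through the plate centroid perpendicular to the plate axis) — a
  bipolar spindle straddles its plate orthogonally, and the projection
  suppresses localization bias from the asymmetric astral fan.
* **Astral detection**: at the 0.09 µm pixel size all rods merge into
  one fan near the pole, so connected components cannot separate them.
  Instead the detector samples probe circles (r = 2.1 and 2.5 µm)
  around each pole, takes angular intensity peaks above threshold
  (default 40 % of the brightest far-field tubulin pixel) as rod
  directions, and follows each ridge outward, re-centring the angular
  peak every 0.4 µm, until the intensity drops below threshold; the
  last above-threshold point is the endpoint. Rods shorter than the
  inner probe radius are invisible — by construction these never reach
  the cortex, so no census is affected. Endpoints within
  `delta_cortex_um = 1.0` of the soma boundary count as reaching;
  endpoints exactly on a partition plane are central (the central
  region owns its bounding planes, as it is defined to contain all
  foci).
* **Front/Side rule**: Front if the pole–pole axis makes strictly less
  than 45° with the sectioning plane *and* spans ≤ 3 sections;
  otherwise Side. 45° exactly is Side.
* **BP sectors**: half-angle 45° about the ventricle and pial
  directions (equal apical/basal coverage); boundary angles count as
  oriented, not central.
* **Cytoplasm estimate**: median over the soma eroded by the expected
  band width (3 px) — robust to the bright cortex; corrected
  intensities are clipped at 0.
* **Region windows on the profile**: apical = 20 % of perimeter centred
  on s = 0, basal = 20 % centred on s = 0.5, central the remainder —
  the source marks the regions only graphically, so the fractions are a
  package default and results carry a flag saying so.
* **Main spindle region and area**: the region object keeps its
  defining landmarks; `spindle_area()` integrates pixel rows straddling
  a partition plane at their fractional overlap (partial-volume
  weighting). A full pixel row of the band is ≈ 2.6 % of the area, so
  binary row inclusion would make the area jump discontinuously under
  sub-pixel plane shifts.
* **SD flavour**: population SD (divisor N) in `normalized_sd()`.
* **Bisect/bypass**: an intersection exactly on a domain endpoint is a
  bypass — bisection must split the domain into two non-empty parts.
* **Zone bands**: half-open toward basal, nuclei classified by
  centroid; a nucleus exactly on the VZ/SVZ boundary is SVZ.
* **Dunn adjustment**: Bonferroni by default (the source does not state
  the family correction), switchable through any `p.adjust` method.
  Significance threshold α = 0.05.

## Validation strategy and problem sizes

The test suite validates each operation against an independent oracle:
analytic geometry for contour lengths, chords and division
classification; brute-force voxel labeling for the region partition;
the generator's ground truth for plate angle (±60° sweep, < 1°), astral
censuses (exact on noise-free renders, within ±1 per region at Gaussian
noise of 10 % of the rod peak), cortical profiles (< 10⁻³ of the
generative function) and spindle area (< 2 % of the ground-truth
region); label permutation for the Kruskal–Wallis p (10⁵ draws); and
2000 null simulations for type-I calibration. The standard acceptance
run uses 50 randomized cells for recovery, 100 cells for the partition
oracle, 1000 random geometries for the division oracle, 300 replicate
trajectories per anchor count, and 2000 simulated divisions per
angle-SD level — sizes chosen to make the Monte-Carlo error comfortably
smaller than the effects being checked while a full run stays in the
half-minute range on one core.

## Known limitations

* The astral detector assumes near-straight rods emanating from the
  poles; strongly curved astrals would be followed only while the ridge
  stays within ±3° per 0.4 µm step.
* Central astral counts in 3D "Front" views are not assessed at all
  (matching the stated practice), so total censuses from Front-view
  cells underestimate the truth.
* The OU trajectory model is phenomenological; its parameters are not
  identifiable from the censuses and are not fitted to data.
* Agreement with human expert counts on real micrographs is untestable
  here; all quantitative guarantees are relative to the synthetic
  ground truth.
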