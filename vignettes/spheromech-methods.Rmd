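---
title: "Methods: spheroid stiffness estimation and TEM morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid stiffness estimation and TEM morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spheromech)
```

This vignette documents the models, parameters and numerical choices
behind the two pipeline arms, and what the synthetic-data generators do
and do not emulate.

## 1. The stiffness arm

### Measurement model

A spheroid of diameter $D_0$ sits between two cantilever tips whose
commanded separation $s$ decreases by a fixed increment each actuation
step (both tips move symmetrically). With the sample present, each tip
deflects outward by $d$ until the elastic restoring force balances the
contact force of the compressed sphere:

$$ k\,d \;=\; F(\delta), \qquad
   \delta = \max\!\big(0,\; D_0 - (s + 2d)\big), $$

where $\delta$ is the total diameter reduction. We model the sphere
between two rigid plates as two small-strain Hertz contacts in series,
each indenting $\delta/2$:

$$ F(\delta) = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,
   \Big(\frac{\delta}{2}\Big)^{3/2}. $$

This closed form replaces a finite-element inversion: it is the standard
result for a homogeneous incompressible sphere compressed between
platens, it is exactly invertible, and it makes parameter recovery a
well-posed consistency test. We do not claim absolute agreement with an
FE treatment of the true tip geometry; the model is linear in $E$, so
any multiplicative geometry correction would rescale all moduli equally
and cancel from ratios.

Assumptions: small strain (the late actuation steps compress the
synthetic spheroids by up to roughly 25–40% of their diameter, well
beyond the Hertzian regime — the generator and the fitter share the same
model, so recovery remains exact, but absolute moduli from deeply
compressed real data should be read with this caveat), rigid plates,
no adhesion, no viscoelastic relaxation (each step is treated as an
equilibrium).

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| beam length / width / thickness | 1.6 mm / 100 μm / 15 μm | m | printed probe geometry |
| beam material modulus | 4 | GPa | SU-8-like photoresist; gives k = 3EI/L³ ≈ 0.0824 N/m |
| voltage step / range | 1.1 / 40 | V | instrument schedule (36 steps) |
| actuation gain | 4.9/1.1 | μm/V | 4.9 μm of tip travel per step |
| Poisson ratio ν | 0.5 | – | incompressible soft tissue; not measured, configurable |
| pixel pitch | 2 | μm/px | required conversion; no default exists for real imagery, so real-mode configs must set it |
| spheroid presets | 421 μm / 260 Pa and 457 μm / 680 Pa | | the two measured age groups |

The per-step displacement is taken as *per tip* (the two tips close at
9.8 μm/step); the alternative reading (4.9 μm of total closure) would
halve all compressions but leave modulus recovery consistent because
generation and analysis share the convention.

### Equilibrium solver

$k d - F(\delta(d))$ is strictly increasing in $d$ on
$[0, (D_0-s)/2]$ with opposite signs at the ends, so bisection is used
to a force residual below $10^{-12}$ N (about $10^{-6}$ relative for
micronewton forces). Degenerate cases short-circuit exactly: no contact
($s \ge D_0$) and zero modulus both return zero deflection and force.

### Tip tracking

Matching uses zero-mean normalised cross-correlation: it is invariant
to affine illumination changes and bounded in $[-1,1]$, which gives a
meaningful score floor. Ties break to the smallest row, then column.
Sub-pixel refinement fits a separable 1-D parabola through the peak and
its axis neighbours (offset clamped to ±0.5 px). The default template is
a wide smooth Gaussian spot (σ = 3 px): a smooth template keeps the
correlation surface locally quadratic, which is exactly the assumption
the parabola makes — with it, noiseless tracking on rendered sequences
is accurate to ~0.004 px RMS, and ~0.07 px at 5% pixel noise.

Search is windowed (default radius 6 px) around the previous step's
position rather than global: per-step motion is ~2.5 px, and a small
window is both faster and robust against the second tip's pattern. A
best score below 0.5 raises a tracking-lost error naming the step —
half-correlation on a structured template indicates occlusion or drift,
and failing loudly beats silently producing garbage deflections.

### Modulus fitting

$F = E\,g(\delta)$ with
$g(\delta) = \tfrac{4}{3}(1-\nu^2)^{-1}\sqrt{R}\,(\delta/2)^{3/2}$ is a
zero-intercept linear regression in the transformed variable, so
$\hat E = \sum gF / \sum g^2$ — exact, no iterative optimiser, no
tuning. Points before first contact ($\delta = 0$) are excluded; small
negative deflections (tracking noise before contact) are clipped to
zero with a warning. `modulus_oracle()` is an independent exhaustive
grid scan of the same RMS objective kept for cross-checks; both
routes are compared in the tests.

## 2. The TEM morphometry arm

### Protocol

Cells are counted only when *complete*: the whole outline strictly
inside the image bounds and the whole nucleus inside the cell. Regions
are assigned by centroid along the primary axis — inner for the central
50% of the extent (half-open interval; a centroid exactly on the 25%
boundary is inner), outer for the flanking quarters. Area statistics
pool the complete cells of all strips in a condition (matching how the
published group Ns combine three sections per condition) and report
mean ± sample SD (ddof 1).

Space density is deliberately raster-based, because "fill the spaces
between the outlines" is a raster operation on the real images: the
clipped cell outlines are filled at a configurable resolution (default
2 px/μm) over the full panel, and the density is the percentage of
uncovered pixels, so density + covered% = 100 exactly. The exact
polygon-area route (`space_density_exact()`) is kept only as an oracle
for synthetic data, where outlines cannot overlap; manual tracings can
overlap, and the raster union handles that correctly. Nuclei are not
subtracted from cell areas (both are reported separately), and the
density denominator is the full panel area.

Density panels per strip: the panel whose midpoint is closest to the
strip midpoint ("center"), and on each side the outermost panel free of
the spheroid edge ("outer", one per side — i.e. two outer panels per
strip). Panels overlap by 10% of their width; the overlap of real
stitched series is unquantified, and 10% is a typical stitching margin.

## 3. The synthetic generators

### Compression sequences

Frames are zero-background grayscale images with the tip template
stamped at sub-pixel positions by bilinear interpolation, plus i.i.d.
Gaussian pixel noise (default SD 2% of the intensity range) clipped to
[0, 1]. The reference run renders the commanded kinematics (modulus 0);
the loaded run renders the equilibrium positions. The generator returns
full ground truth (positions, deflections, forces, compressions), and
identical seeds give bit-identical frames.

Not emulated: the microscope's PSF and illumination drift, tip shape
changes under load, out-of-plane motion, and any 3-D rendering of the
spheroid itself (only the tips are drawn, which is what the tracker
sees). Passing tests therefore demonstrate correctness of the
*measurement chain*, not robustness to real optical artefacts.

The generator and the fitter share the contact model by design, so
modulus recovery is a consistency test of the whole chain (tracking,
unit conversions, inversion), not an independent validation of the
Hertz model itself — an FE oracle is out of scope.

### TEM strips

A strip (length = the group mean diameter, height 80 μm — a few cell
diameters, like a stitched micrograph band) is tessellated by a
Laguerre (power) diagram:

1. Per region, target *post-gap* cell areas are drawn from a lognormal
   matched by moments to the region's mean/SD (areas are positive and
   right-skewed), inflated by $1/(1-\rho)$ so the cells tile the region
   before gaps are carved, and normalised to sum exactly to the region
   area. Seeds are dart-thrown with a spacing proportional to each
   cell's equivalent radius.
2. Diagram weights start at the classic $r_i^2$ initialisation and are
   iterated ($w_i \mathrel{+}= 0.3\,(a_i^{target}-a_i)$, 50 rounds, with
   occasional centroidal relaxation). Because the targets are i.i.d.
   draws they are exchangeable within a region, so every fifth round
   they are re-matched to cells by rank of realised area; this removes
   the geometric frustration of a random assignment without changing
   the sampled area law, and leaves realised areas within ~1% of their
   targets.
3. Gaps: each cell is shrunk inward — a constant-width erosion
   ("uniform", used for the tightly packed day-20 inner core) or a
   sinusoidally modulated inward offset of the densified boundary
   ("beaded", wavelength ≈ 4 μm, amplitude 0.8, random phase per cell),
   which reproduces the bead-like interstitial spots seen along cell
   boundaries elsewhere. The shrink depth is calibrated per region by
   bisection so the exact polygon-computed uncovered fraction of the
   region equals the target density.
4. Nuclei are scaled-down copies of their cell about its centroid.
   Nucleus target areas are drawn from the region's nucleus law and
   rank-matched to realised cell sizes (bigger cells carry bigger
   nuclei), keeping the marginal nucleus law while making the
   containment clamp (nucleus ≤ 80% of cell area) rare.

Calibration is region-wide, so a single centre panel samples slightly
below the region's target density (the seams where differently eroded
regions meet count toward the region total); across seeds the day-20
centre-panel density comes out near 2% against a 2.4% region target,
well inside the measured spread.

Not emulated: actual TEM texture (the rendered panels are flat
three-tone rasters), organelles, cell-shape anisotropy near the
spheroid surface, necrotic morphology, and section-thickness effects.
The generator provides geometry with known statistics, which is what
the morphometry code consumes; it says nothing about segmentation of
real micrographs (tracings are inputs).

## 4. Statistics

Welch's unequal-variance t-test is used throughout (the group variances
in the measured tables differ visibly); Student's pooled test is
available behind `var_equal = TRUE` for sensitivity. All p-values are
two-sided, with no multiple-testing correction (three comparisons per
table, reported as-is). Marks: `*` p < 0.005, `**` p < 0.001. Summary
and raw-sample routes use identical formulas and agree to 10⁻¹⁰ on
samples constructed to match the summaries.

A caveat worth stating: applying Welch's test to the published day-20
inner-vs-outer *area* summaries (224±106, n=26 vs 164±86, n=53, with ±
read as SD) gives p ≈ 0.016, and the nucleus summaries give p ≈ 0.011 —
neither reaches the p < 0.005 the published marks claim, under any
standard two-sample test computable from those summaries. The density
comparison (2.4±0.9 vs 10.5±1.6, n=3) does reach p ≈ 0.0039 < 0.005.
The package reports what its formulas give; on its own synthetic data
(larger complete-cell Ns) the day-20 inner-vs-outer differences are
significant far beyond these thresholds and the day-5 ones are not,
reproducing the qualitative pattern.

On synthetic moduli the group SD reflects only tracking noise (fractions
of a pascal), not biological spread, so the synthetic stiffness p-value
is astronomically small; the headline group comparison is therefore
computed from the published summaries (260±100 vs 680±150, n=6), giving
p ≈ 3.3 × 10⁻⁴.

## 5. Problem sizes and runtime

Defaults were chosen so a full desk-scale reproduction stays light: six
compression runs per age preset (36 steps, ~300 × 80 px frames) and
three strips per preset (~180–240 cells each) complete in well under a
minute; the test suite exercises smaller strips (160 × 60 μm) for the
property checks. All seeds are explicit function arguments; nothing
reads or mutates global RNG state beyond a save/restore wrapper.

## 6. Known limitations

* The contact model ignores large-strain stiffening; absolute moduli
  from deep compressions are model-dependent (ratios are not).
* The force ratio statement $F_{20}/F_5 = E_{20}/E_5$ holds exactly
  only at equal compression and geometry; at equal actuation step the
  two presets differ in diameter, so the generated peak-force ratio is
  smaller than the modulus ratio.
* Tessellation cells are convex-ish polygons; real inner-core cells can
  be markedly concave.
* The per-spheroid density SDs of the synthetic strips are much smaller
  than the measured ones (a fixed target density per region; biological
  spheroid-to-spheroid spread is not modelled).
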