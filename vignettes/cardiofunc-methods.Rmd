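---
title: "Quantifying contraction, calcium handling, alignment and migration in micropatterned cardiac cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contraction, calcium handling, alignment and migration in micropatterned cardiac cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofunc)
```

# What this package measures

Engineered cardiac tissues built from stem-cell-derived cardiomyocytes and
cardiac fibroblasts on micropatterned substrates are characterized
functionally along four imaging axes, and `cardiofunc` implements the full
computational chain for each:

1. **Contractility** — bright-field videos of spontaneously contracting
   tissue are converted to full-field displacements by subset-based digital
   image correlation (DIC), then to strain-tensor fields; the magnitude of
   the masked, per-frame mean second principal strain at its extremum is
   the *maximum contractile strain*, in percent.
2. **Calcium handling** — high-speed fluorescence movies of calcium
   transients yield per-pixel activation times (maximum upstroke
   derivative), rise-up times (10–90% upstroke duration), transient
   durations at 80% relaxation (CaTD80), and conduction-velocity fields
   with a longitudinal/transverse anisotropy ratio.
3. **Structural alignment** — windowed spectral orientation analysis of
   fiber and myofibril images gives per-window dominant angles and the
   percentage of structure aligned within ±10° of the dominant
   ("superior") angle, plus intensity-threshold area-coverage statistics.
4. **Migration** — trajectory tables from cell tracking are summarized as
   per-step direction angles (90° = up), speeds in µm/min, rose
   histograms, a lane-directionality index, and per-cell-then-cohort
   speed summaries.

Because real recordings of this kind are rarely shareable, the package
ships a **synthetic-data module** that generates every input modality with
analytic ground truth, and the test suite exercises the complete pipeline
against those truths.

# Synthetic ground truth

## Speckle movies and imposed strain

`gen_speckle()` renders Gaussian dots (density in dots per 100 px²,
radius in px) on a dim background — a stand-in for bright-field cell
texture with the one property DIC needs, distinctive local pattern.
`warp_movie()` pushes the frame through the displacement field
$u(x) = s(t)\,E\,(x - x_0)$, where $E$ is the uniform strain tensor with
principal strains $(0, \varepsilon_{\mathrm{peak}})$ along a chosen axis
and $s(t)$ is a raised-cosine event profile normalized to start at 0 and
peak at 1. The analytic displacement and strain fields are returned with
the movie. Frames are resampled by exact inverse affine mapping with
bilinear interpolation; dot centers are also exposed so tests can render
*exactly* band-limited subpixel shifts by re-rendering displaced dots.

A margin rule rejects events whose forward or inverse corner displacement
exceeds 1/16 of the frame edge, so no sampled content ever leaves the
frame materially.

## Calcium-transient template

Each pixel's fluorescence is baseline, then a **linear upstroke** of
duration $R$ starting at the pixel's wavefront arrival time, then a
**single-exponential decay** $e^{-(t-t_\mathrm{peak})/\tau}$. This
template was chosen because the metrics then have closed forms:

* activation (max upstroke derivative, plateau-midpoint convention for
  the exactly linear case) at $t_a + R/2$;
* rise-up time (10–90%) $= 0.8R$;
* CaTD80 (activation → 20%-of-peak crossing) $= R/2 + \tau\ln 5$.

Arrival times come from elliptical wavefront geometry
$t_a = \sqrt{(l/v_L)^2 + (\mathrm{tr}/v_T)^2}$ in the pattern frame
(planar waves as the degenerate case), so conduction speed and anisotropy
are exact by construction. Defaults mirror a high-speed mapping camera:
60 µm/pixel, 1000 fps, 1 Hz pacing. The generator refuses geometries
whose upstroke has fewer than 3 samples or whose wave does not cross the
field in the requested frames.

## Fiber images, coverage images, walks

`gen_fiber_image()` draws anti-aliased segments with axial von Mises
orientations (κ = 0 uniform; large κ a point mass). Because all fibers
share one length, the ground-truth aligned fraction is a direct tally of
sampled angles. The default geometry (340 fibers of 40 px on 768²) was
chosen once so that a 24–32 px analysis window typically contains a
single fiber — the regime in which the per-window statistic and the
per-fiber tally estimate the same quantity; denser fields bias the
windowed estimate upward (windows average neighboring fibers toward the
mean).

`gen_coverage_image()` paints an exact pixel fraction at high intensity
over a dim background with Gaussian noise — clearly bimodal contrast for
threshold-based area-density quantification.

`gen_walks()` produces isotropic walks (fresh uniform heading per step)
or lane-confined walks (headings jittered around 90°/270° with SD 8°,
reflecting at the lane walls). Step length is exactly
speed × interval, so cohort speed truth is the input speed (reflections
shorten the net displacement of rare wall-hitting steps marginally).

# Analysis methods and numerical choices

## Digital image correlation

Subsets (default 32 px at 8 px spacing, centers kept a full half-subset
from every border) are matched against a **single fixed reference frame**
(the relaxed field of view) — never frame-to-frame, so there is no drift
accumulation. The criterion is zero-normalized cross-correlation,
invariant to uniform gain and offset; the integer peak over a bounded
search window (default ±10 px) is refined by a parabolic fit to the 3×3
correlation neighborhood. This subpixel scheme resolves imposed half-pixel
shifts to better than 0.1 px on speckle texture, which is sufficient for
strains of a few percent at subset scale; iterative gradient DIC would
add accuracy the downstream statistics do not need.

Failure handling is explicit: zero-variance (flat) subsets are invalid,
and a correlation peak **on the boundary of the searched range** is
invalid unless the match is numerically perfect — an edge-pinned subset
or an out-of-range displacement must surface as missing data, never as a
silent zero. Reported `quality` is the integer-lag peak correlation: 1
for aligned noiseless content, bounded by the texture autocorrelation
(≈0.95 for the default speckle) at half-pixel offsets.

## Strain

The infinitesimal small-strain tensor is computed by centered finite
differences of the displacement grids (one-sided at grid edges), with
physical spacing = subset spacing × pixel size. At the 2–3.5% strains
this assay produces, the quadratic Green–Lagrange term is below the DIC
noise floor. Principal strains use the closed form
$\varepsilon_{1,2} = \tfrac{\varepsilon_{xx}+\varepsilon_{yy}}{2} \pm
\sqrt{(\tfrac{\varepsilon_{xx}-\varepsilon_{yy}}{2})^2+\varepsilon_{xy}^2}$.
Invalid displacements poison their finite-difference neighborhoods and
themselves. Coordinates are right-handed (x right, y up, angles CCW from
+x, 90° = image-up); the row-index flip happens only at module
boundaries.

The **mask** restricts the summary to tissue-occupied points. `auto_mask()`
keeps points whose peak displacement exceeds a configurable fraction
(default 0.2) of the field's robust maximum (95th percentile) and whose
median correlation quality clears a floor (default 0.8); it is computed
once per video, not per frame. The contractile trace is the per-frame
mean of $\varepsilon_2$ over masked valid points; the reported maximum
contractile strain is the magnitude of its most negative value, as a
positive percent. Recordings with several events are served by the global
extremum plus `event_peaks()` as a secondary per-event table.

## Calcium metrics

Traces are spatially binned (averaging), smoothed by a centered moving
average (default 5 samples at 1000 fps), and min–max normalized per beat;
beats come from the pacing period when stated, else from rising
half-range crossings of the field-mean trace (this also yields the
spontaneous rate). Activation uses the maximum of the discrete
derivative with parabolic sub-sample refinement; for an exactly linear
upstroke the derivative plateau is resolved to its midpoint — a
documented tie-break that makes the template's closed forms exact.
Rise-up is 10–90% by linear interpolation (thresholds configurable);
CaTD80 runs from activation (or, optionally, the 50%-upstroke crossing)
to the first post-peak crossing of 20% of peak.

Conduction velocity fits a plane to activation time over sliding 5×5
windows; velocity is $\nabla t / |\nabla t|^2$ in cm/s. Windows are
excluded when under 80% valid, when the RMS fit residual exceeds one
frame interval, or when $|\nabla t|$ falls below 10⁻³ ms/µm (speeds
above 100 cm/s are unresolvable at this geometry) — uniform activation
therefore fails loudly rather than returning noise. Anisotropy averages
window speeds whose propagation direction lies within ±22.5° (axially)
of the pattern axis (longitudinal) or its perpendicular (transverse);
with a 2:1 elliptical wave the sector means give a ratio slightly below
2 because off-axis windows inside each sector are slower than the axis
extreme — the measured ≈1.97 is a property of sector averaging, not an
estimator error.

## Orientation analysis

Windows (default 64 px at 16 px steps; 24 px for the synthetic fiber
fields) are mean-subtracted, Hann-tapered and Fourier transformed. On an
annular band (wavelengths 3–32 px), the dominant orientation is the
principal axis of the doubled-angle first moment of spectral energy —
the structure-tensor axis evaluated in the spectral domain. An explicit
1°-binned angular energy histogram was evaluated first and rejected: at
these window sizes the annulus has only ~5–8 frequency bins of radius,
i.e. 7–11° of angular quantization per bin, which biased grating angles
by about a degree and broke aligned-fraction recovery; the moment
estimator is exact on gratings at any angle. The real-space fiber angle
is the spectral angle + 90°. The per-window weight is the resultant
length of the doubled-angle energy distribution (spectral anisotropy),
so bright-but-isotropic windows do not dominate image statistics; windows
below an energy floor (fraction of the median window energy) are invalid.

`aligned_fraction()` is the weight-weighted fraction of valid windows
within ±10° (axially) of the reference angle; `superior_angle()` is the
weight-weighted axial circular mean (doubled-angle method) and refuses
balanced bimodal fields. Area coverage thresholds intensities by Otsu's
method (or a fixed value) inside a region mask and reports percent above
threshold; the threshold used is attached to the result.

## Migration statistics

Step angles are `atan2(Δy, Δx)` mapped to [0, 360) with 90° = up —
matching rose-plot conventions in time-lapse tracking figures — and are
taken per consecutive sample pair ("direction since the last
measurement"), not as turning angles. Zero-length steps have speed 0 and
an undefined angle excluded from histograms. Cohort statistics aggregate
per cell first (time-weighted mean speed = path length / elapsed time),
then across cells, so long tracks do not dominate; a single-cell cohort
reports SD as `NA`. The directionality index is the fraction of steps
within ±15° (axially) of the lane axis. Importers flip the y-axis for
trackers that report image-origin ("upper") coordinates.

# Problem sizes and what the tests show

The suite runs entirely on synthetic data at desk scale: contraction
movies of 128–256 px and 15–31 frames, calcium movies of 60–100 px and
400–1200 frames at 1000 fps, 768² fiber fields, cohorts of 40–60 walks.
At these sizes the full chain recovers: imposed 2% and 3% contractile
strains within 10% relative; template rise-up times within 1 ms and
CaTD80 within 2 ms; planar-wave speeds of 5–30 cm/s within 5% at
60 µm/px; elliptical 2:1 anisotropy within 0.15 and isotropic controls
within 0.1; fiber aligned fractions within 0.05 of the generator tally
for κ ∈ {0, 1, 2, 4, 8}; painted coverage within 2 points; cohort speeds
within 5%.

What passing does **not** show: the generators contain no photorealistic
cell morphology, no motion blur, illumination drift or photobleaching, no
electrophysiological coupling (no cable model — wavefronts are imposed
geometrically), and no tracker noise in trajectories. Results on real
recordings therefore depend on texture quality, staining uniformity and
tracking fidelity in ways these tests do not probe; the invariants
(equivariances, unit behavior, failure flags) are the portable part.

# Reproducible runs

`run_pipeline()` executes one modality from a config (YAML or list) with
defaults for every parameter, rejects unknown keys, writes
`metrics.json` (units inside key names, percents on the 0–100 scale),
per-point CSV tables, figures, and a `resolved_config.yaml` from which
the run can be repeated exactly; seeded reruns are bitwise-identical at
the metrics level. A thin command-line front end lives at
`exec/cardiofunc`. `scripts/acceptance.R` regenerates every headline
quantity from scratch at the published operating points of the assay
(strains of 2–3%; rise-up 86/37/30 ms; CaTD80 687/651/601 ms; CV
10.5/14.9/12.5 cm/s; anisotropy 2; alignment ≈60–65%; ECM density
7/29/84%; speeds 0.28–0.33 µm/min) and writes them as JSON.

# Known limitations

* Subpixel DIC is parabolic peak interpolation; very large strains or
  rotations (beyond this assay's regime) would need iterative
  shape-function DIC.
* The calcium template is piecewise linear/exponential; alternans,
  double-peaked transients or strong baseline drift are out of scope.
* The orientation estimator reports one dominant axis per window;
  crossing fiber populations inside a window lower the weight rather
  than yield two angles.
* Beat segmentation assumes beats are separated at the field-mean level;
  strongly heterogeneous activation sources would need per-pixel
  segmentation.
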