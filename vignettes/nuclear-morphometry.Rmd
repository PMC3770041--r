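---
title: "Nuclear morphometry of diffusely infiltrating gliomas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry of diffusely infiltrating gliomas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomorph)
```

## The measurement problem

Diffusely infiltrating gliomas are graded II–IV on histology, and the
distinction between non-neoplastic tissue, low-grade (LGG, WHO II) and
high-grade (HGG, WHO III–IV) tumour can be difficult on small or
intraoperative specimens. Nuclear morphometry quantifies what the
pathologist assesses visually: on calibrated images of H&E-stained
sections, each nucleus is outlined and measured for

* **MAJX, MINX** — major and minor axis of the nucleus (µm), here defined as
  the axes of the *moment-equivalent ellipse* of the pixel region:
  $4\sqrt{\lambda_{1,2}}$ of the pixel-coordinate covariance matrix. This
  definition is exact for ideal ellipses and rotation-stable; tools based on
  Feret (caliper) diameters will read slightly larger on irregular nuclei.
* **NA** — nuclear area (µm²), pixel count × (µm/px)².
* **NP** — nuclear perimeter (µm), estimated from the label raster (below).
* **NR** — nuclear roundness, the shape factor
  $\mathrm{NR} = \frac{4\pi\,\mathrm{NA}}{\mathrm{NP}^2}\times 100$,
  equal to 100 for a perfect circle and smaller for pleomorphic outlines
  (isoperimetric inequality).
* **ND** — nuclear density, nuclei per mm² of field area.
* **%TNA** — percent of the field area covered by nuclei.

The first five are nucleus-level size/shape parameters; ND and %TNA are
field-level growth parameters. Per case, five high-power fields (400×) of
maximum cellularity are measured and 100 clearly separated, relatively
larger nuclei enter the shape statistics; per-parameter means per case are
the unit of statistical analysis.

This package implements the whole chain — synthetic ground-truthed fields,
raster measurement, selection rules, and the group-level statistics — so
that every stage is testable without access to the original slides, which
were never deposited.

## Digital perimeter estimation

Perimeter is the only parameter that is genuinely hard to read off a label
raster: counting boundary pixels overestimates circle perimeters by up to
~27%, which would bias NR by tens of points. `nucleus_perimeter()` uses a
local estimator with weighted counts of six boundary features: the 2×2
pixel-configuration classes (1, 2-adjacent, 2-diagonal, 3 foreground
pixels), knight-move ((2,1)-direction) foreground/background transitions,
and single-pixel runs along rows/columns. The last term corrects the
over-counting of scan lines that barely graze a region — the dominant error
for integer-radius disks centred on a pixel.

The six weights are frozen package constants, calibrated by minimax
optimisation over rasterized disks (radii 8–100 px at arbitrary sub-pixel
offsets, including the degenerate pixel-centred cases), axis-aligned squares
and rotated ellipses, and validated on held-out irregular star-shaped
outlines of the kind the simulator produces. The error contract, enforced in
the tests:

* disks of radius ≥ 20 px: within 2% of $2\pi r$ (≤ 1.4% observed);
* measured roundness of disks with radii 10–100 px stays within [98, 102];
* a 10 × 10 px square measures 39.5 px (true 40);
* a single isolated pixel measures the documented constant 1.7656 px.

The diagonal-pair configuration (two foreground pixels sharing only a
corner) never occurs in the calibration shapes — it indicates a pinched,
8-connected neck — so its weight is pinned at 1.41 (the length of a diagonal
crossing) rather than fitted.

Axes use the population covariance of pixel centers with no ½-pixel
correction, matching the moment-equivalent-ellipse definition; rasterized
ellipses with semi-axes ≥ 18 px recover their true diameters within 2%.

## The synthetic cohort generator

No images from the reference cohort exist publicly, so the generator is a
first-class module: it emulates the study conditions — 10 controls (CG), 14
LGG, 16 HGG; 5 fields per case; roughly 100 selected nuclei per case — with
full per-nucleus ground truth, so recovery can be tested end to end.

**Sampling hierarchy.** For each case, a mean nuclear area and a placement
density are drawn from the group's between-sample distributions (truncated
normals with the published group means/SDs, e.g. NA 55.22 ± 13.48 µm² and ND
4350 ± 1089 mm⁻² for HGG), and a WHO grade code from the group's case
spectrum (all LGG are grade II; HGG are glioblastoma vs anaplastic
astrocytoma in proportion 13:3). Within a case, nucleus areas are normal
around the field-adjusted case mean with coefficient of variation
`within_sample_cv` (default 0.30 for tumours, 0.15 for controls — the
nucleus-level spread is not published, so these are stated assumptions
chosen to reflect the visibly wider tumour distributions). Field counts are
Poisson(density × field area).

**Field-to-field heterogeneity.** Tumour groups additionally draw per-field
mean-area multipliers (`field_effect_cv`, default 0.25 for tumours, 0.05 for
controls), renormalised to mean 1 within a case so case-level means are
untouched. This models intratumoral heterogeneity between high-power fields
and is what makes a tumour case's pooled area distribution a mixture —
flatter, wider, and measurably less Gaussian than a control's, as observed.
Without it, every case's areas would be a single normal and the documented
tumour-vs-control deviation ordering could not arise.

**Shape model.** A nucleus outline is a star-convex polygon
$r(\theta) = r_0\, s(\theta)\,\bigl(1 + \sum_{k=2}^{6} a_k \cos(k\theta + \varphi_k)\bigr)$
where $s(\theta)$ is an ellipse radius at the group's aspect ratio (≈1.5,
from the published MAJX/MINX ratios) and the harmonic amplitudes sum to the
`irregularity` parameter. Harmonics start at $k = 2$ so shapes stay simple
and star-convex; `irregularity` < 0.5 keeps the radius positive. Amplitude
is allocated across harmonics with weights ∝ $k^2$: higher harmonics buy
more boundary length per unit amplitude, which is needed to bring roundness
down into the observed nuclear range. Group defaults (CG 0.35, LGG 0.385,
HGG 0.40) were calibrated once, analytically at the polygon level, to land
mean NR near the published 65.5 / 61.5 / 59.8 and were then frozen. The
polygon is rescaled so its shoelace area equals the drawn area exactly; its
analytic area, perimeter, moment axes and roundness are recorded as ground
truth.

**Placement and rendering.** Nuclei are placed by rejection sampling with a
minimum boundary clearance of one pixel (nuclei in the reference protocol
were separated before measurement; overlapping-nucleus segmentation is out
of scope). A candidate gets up to 1000 attempts; when a field saturates at
high density it is emitted with fewer nuclei and a warning. Rasterization
assigns a pixel to a nucleus iff the pixel center lies inside the polygon
(0-based indices; x = column, y = row; physical origin at the top-left pixel
center). For the star-convex shapes this membership test is computed exactly
by sector indexing, and it agrees pixel-for-pixel with the generic
crossing-number test.

**Field geometry.** The reference study never states its camera field size,
and absolute ND/%TNA depend on it. The default is 346 × 260 µm (≈0.09 mm², a
typical 400× digital camera field) at 0.25 µm/px; both are configurable.
Densities are drawn per mm² and counts per field are Poisson with the
configured field area, so ND recovery is independent of this choice; %TNA is
not, which is one reason simulated tumour %TNA (which also includes *all*
nuclei, not just the 100 selected larger ones) runs above the published
values. Only orderings and signs are asserted for %TNA.

## Selection rules

Two judgement calls in the manual protocol are made deterministic:

* "five fields of maximum cellularity" → the 5 fields with the highest
  nucleus count, ties broken by field id;
* "100 nuclei, clearly separated and relatively larger in size" →
  nuclei with no foreign label 8-adjacent and no raster-edge pixel, sorted
  by area descending, first 100 (ties by field then label id).

The size bias of the second rule is deliberate and documented: per-case mean
NA estimates the mean of the *selected larger* nuclei, as in the original
protocol, not of all nuclei. Border-touching nuclei are excluded from shape
statistics but still counted in ND and %TNA, since their pixels are in the
field. Whether the original %TNA used all nuclei or the selected 100 is not
stated; the all-pixels convention is adopted. ND is computed per field and
then averaged (the published wording permits per-field-then-mean or pooled;
the former is adopted).

## Statistical layer

Group summaries report mean, sample SD (n−1) and range. Pairwise group
comparisons use the **pooled-variance two-sided Student t-test**, computed
from summary statistics,
$s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},\quad
 t = \frac{m_2 - m_1}{s_p\sqrt{1/n_1 + 1/n_2}},$
so a published summary table can be verified with no raw data. The pooled
(not Welch) form is the default because it is the one that reproduces the
reference P values — e.g. NA LGG/HGG gives 0.0042 pooled vs 0.0035 Welch
against the printed 0.0042; Welch remains available as an option. No
multiple-testing correction is applied, mirroring the reproduced analysis;
this is a documented limitation, not a recommendation. Correlations against
WHO grade code (controls coded 0) use Pearson r with the t-transform P value
and a least-squares line.

The published grade-correlation magnitudes (r = 0.83 for MAJX/NP, −0.42 for
NR, ND–NP 0.72, ND–NA 0.70) depend on the joint per-case structure of the
real data, which the independent group summaries do not determine; on
synthetic cohorts only the *signs* are asserted (positive for the six
size/growth parameters, negative for NR).

## Area distributions

`area_histogram()` bins areas into uniform left-closed bins (default width
5 µm²; the reference figures' binning is unstated, so this is configurable),
and `gaussian_expected_counts()` supplies the "calculated Gaussian" overlay
$n\,[\Phi(b_{hi}) - \Phi(b_{lo})]$. Because the group SDs order
CG < LGG < HGG, the model peak heights order CG > LGG > HGG.
`gaussian_deviation()` quantifies the qualitative claim that tumour
distributions depart from Gaussianity: a one-sample Kolmogorov–Smirnov
distance against a normal with parameters estimated from the same data
(the P value is therefore approximate and anti-conservative, and is labelled
as such), plus peak-height and range descriptors. The original comparison
was visual; the KS statistic is this package's choice of a quantitative
stand-in.

## Numerical and design choices

* Truncated-normal draws use rejection sampling; area draws are truncated
  positive. Grade mixtures are exact multinomial draws, so a 16-case HGG
  group has grade-4 proportion 13/16 only in expectation.
* Placement clearance is evaluated on the polygon vertex clouds with a
  chord-sag allowance (coarse-to-fine, exact with respect to the allowance).
* Whole-field measurement is vectorised per label; a nucleus that touches
  another label is re-measured on its own binary mask so its perimeter is
  well-defined. Degenerate regions (< 3 px, collinear) yield NA axes rather
  than an error when measured in bulk, and errors when measured singly.
* All randomness flows from `cohort_config(seed)`; regeneration is
  byte-identical (label TIFFs included), which the tests assert.
* Problem sizes in the test suite: unit tests run on small fields
  (120 × 100 µm); the full-scale checks generate the complete default
  cohort (40 cases, 200 fields at 346 × 260 µm, ≈50k nuclei) plus dedicated
  16-case HGG and 10-case CG cohorts — these are the package's standard
  verification sizes and dominate the suite's runtime.

## What passing tests do and do not show

The simulator produces clean, non-touching, star-convex nuclei on a uniform
background. Passing recovery tests therefore validates the *measurement
chain* (rasterization → features → selection → statistics), not performance
on real H&E images: no staining variation, focus blur, touching or
overlapping nuclei, vasculature, or texture is simulated, and no
segmentation of real imagery is attempted (inputs are already-labeled
rasters, as the original nuclei were outlined manually). The statistical
layer's reproduction of the published P values from summary statistics is
exact in the sense that it uses only printed numbers; the stochastic
recovery targets (grand mean NA within ±4 µm² at n = 16, mean ND within
±90 mm⁻² at n = 10) are tight relative to the between-sample standard
errors (≈1.2 and ≈2 SE respectively), so individual seeds can
occasionally fall outside them by construction.
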