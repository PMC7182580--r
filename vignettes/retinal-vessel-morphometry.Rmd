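---
title: "Methods: retinal vessel morphometry and Doppler flowmetry in octaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal vessel morphometry and Doppler flowmetry in octaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaflow)
```

# Scope and scientific setting

Sickle cell retinopathy alters both the architecture of the retinal
microvasculature (tortuosity, capillary density, inter-vessel spacing) and
its haemodynamics (total retinal blood flow, TRBF). octaflow implements the
measurement chain needed to study those quantities jointly: OCTA vessel
segmentation and centerline extraction, the vessel tortuosity index,
fractal-dimension vessel-density metrics, phase-resolved Doppler OCT
flowmetry, and a mixed-model statistics layer for cohorts in which many
subjects contribute both eyes. Since clinical images of this kind are rarely
shareable, every stage is exercised against synthetic inputs whose ground
truth is known by construction.

# Segmentation and centerlines

**Binarization.** Vessels are separated from background by 1-D k-means on
pixel intensity with `k = 2`, centers initialized at the intensity extremes
and Lloyd iterations run to convergence. This is deterministic (no random
restarts) and reduces, for two-valued images, to a midpoint threshold
between the converged centers. For `k > 2` the single brightest cluster is
taken as foreground; `k = 2` is the study condition and the default. A
constant image is rejected as degenerate rather than silently producing an
empty or full mask.

**Skeletonization.** Centerlines require a connected, unit-width skeleton.
We use Zhang–Suen thinning, followed by two post-passes:

* *redundant-pixel pruning* — thinning leaves two-pixel "staircases" on
  diagonal runs; any non-endpoint pixel whose foreground neighbours remain
  mutually 8-connected without it is removed sequentially. Without this the
  bifurcation test below misfires on every diagonal vessel.
* *endpoint extension* — thinning retracts line ends by roughly the vessel
  half-width; each skeleton tip is extended straight along its local
  direction until it leaves the mask, recovering the vessel endpoints.

A distance-transform medial axis was considered and rejected: its skeletons
are generically disconnected at pixel resolution, while the ordered-path
contract below needs connectivity.

**Bifurcations and segments.** Skeleton pixels with ≥ 3 skeleton neighbours
in their 8-neighbourhood are flagged as bifurcation points and removed
(repeatedly, until every remaining pixel has ≤ 2 neighbours, so clustered
junctions are fully resolved). Each remaining connected component is a
simple path, ordered from one endpoint to the other. Components shorter than
`min_length_px` (default 10 px) are discarded as spurs; the default is
exposed because spur handling is a free parameter of any skeleton pipeline.

# The vessel tortuosity index

For a centerline with points \(p_1,\dots,p_n\):

* arc length \(L_A\) = sum of Euclidean steps, chord length \(L_C\) =
  distance between endpoints;
* tangent angles: at each interior point the direction of the central
  difference over ±`step` points (default 2 px), measured against the chord
  direction and wrapped to \((-\pi,\pi]\); \(SD_\theta\) is their sample
  standard deviation;
* the *deviation profile* is the signed perpendicular distance of each point
  from the chord line. Critical points are the local extrema of this
  profile, detected as sign changes of its first difference; differences
  with magnitude below ε = 1e-6 are treated as flat so that pixel-level
  jitter on straight runs does not create spurious extrema. \(N\) is the
  extrema count and \(M\) the mean absolute profile value at the extrema,
  divided by \(L_C\);
* \(\mathrm{VTI} = 0.1\, SD_\theta \cdot N \cdot M \cdot L_A / L_C\), with
  \(\mathrm{VTI}=0\) whenever \(N=0\).

Two operationalizations here are design choices rather than forced by the
index's verbal definition: critical points are defined on the
chord-deviation profile (this reproduces the required straight-line-zero
property and counts the curve's oscillation structure), and \(M\) is
normalized by the chord so the index is invariant under uniform rescaling of
the image — necessary for comparability across pixel sizes. Both choices are
pinned by tests against an independently written brute-force implementation
of the same definitions (agreement to 1e-9 relative on 50 random smooth
curves) and by invariance tests under translation and rotation.

Segments too short for tangent estimation (fewer than `2·step + 2` points)
raise an error when measured directly and are skipped, not failed, when
averaging an eye (`eye_vti_from_mask`). Closed loops have zero chord and are
rejected as degenerate.

# Fractal vessel-density metrics

The local fractal dimension of each pixel uses two-scale box counting inside
a centred window of size `window` (default 3, the smallest odd size): with
\(N(1)\) the number of foreground pixels in the window and \(N(w)=1\) iff the
window holds any foreground, \(\mathrm{LFD} = \log N(1)/\log w\) where the
window is non-empty and 0 elsewhere. A 3 × 3 window admits exactly these two
scales, so no log–log regression is possible or attempted; values lie in
[0, 2]. Borders are zero-padded so the output keeps the image shape.
Whether to compute LFD on the binary map or the grayscale image is an open
choice in this literature; octaflow uses the binary map, consistent with the
segmentation-first pipeline.

The FDR map divides by the global maximum (an all-zero map stays zero), and
the partition assigns `0.7 ≤ FDR ≤ 1` to VD, `0.3 < FDR < 0.7` to SSV and
`0 ≤ FDR ≤ 0.3` to SLV — boundary values belong to VD and SLV respectively,
following the defining inequalities. SLV is computed as `1 - (vd + ssv)` so
the three fractions sum to exactly 1 in floating point; SLV equals its own
pixel-count ratio to within one ulp (asserted at 1e-12 in the tests).

# Doppler flowmetry

Axial velocity follows the standard phase-resolved relation
\(v = \lambda\,\Delta\phi / (4\pi n \tau)\) with τ the inter-A-scan time and
tissue group index n = 1.38; all constants live in `scan_meta` and default
to the acquisition protocol (840 nm, 70 kHz, 2 × 2 mm, 80 × 500 A-scans).
With those defaults a π phase shift maps to ≈ 10.65 mm/s; phases outside
\((-\pi,\pi]\) are rejected rather than unwrapped, because no unwrapping
strategy is part of the protocol. En-face planes are normal to the beam, so
flow is the plain sum of velocity × pixel area over the vein mask (µL/min
after the ×60 conversion), with no Doppler-angle correction. Per vein, the
en-face plane with the largest flow magnitude is recorded (venous flow
toward the nerve head reported positive); per volume, vein maxima are
summed; per eye, volumes are averaged. Fewer than 3 volumes triggers a
warning, matching the 3–26 volumes averaged per eye in practice.

Vein masks are supplied as inputs (matrices or per-plane lists); automated
vein detection from reflectance is out of scope.

# Synthetic data: what it does and does not emulate

All generators take an integer seed, restore the caller's RNG state, and
return their ground truth alongside the data — the truth is never
re-measured from the rendered output.

* **Sinusoid vessels** give a bright band of configurable amplitude, period,
  width (default 3 px), contrast (default 5:1 over a background of 20) and
  additive Gaussian noise (default SD 8, "mild" relative to the 80-unit
  contrast step). The truth centerline is the rounded, deduplicated,
  8-connected sample path. Sub-pixel sampling adapts to the slope so
  rounding never breaks 8-connectivity.
* **Vessel trees** paint smooth correlated-random-walk strokes; each stroke
  after the first starts on an earlier stroke. Strokes draw from per-stroke
  seeds derived from the base seed, so trees of increasing branch count are
  nested — which is what makes "VD non-decreasing in branch count" a clean
  monotonicity property rather than a statistical one.
* **Flow phantoms** render cylindrical veins with parabolic (Poiseuille)
  profiles, so the analytic flow \(Q = v_{peak}\,\pi R^2/2\) is an exact
  oracle. Pixels take the supersampled (6 × 6) mean of the velocity field,
  making the discrete integral match the analytic one to ≪ 1%; the vessel
  spans the middle half of the depth range with a linear taper whose maximum
  (exactly 1) sits at the mid-vessel plane, so the per-vein max-over-planes
  rule is exercised nontrivially. The acceptance phantom (peak 20 mm/s,
  R = 0.05 mm, Q ≈ 4.712 µL/min) is run at a 140 kHz A-scan rate so its peak
  phase (≈ 0.94 π) respects the wrap limit that the generator enforces; at
  the 70 kHz default such a vein would alias and is rejected.
* **Cohorts** sample eye-level metrics directly from the configured group
  means/SDs (VTI 0.61 ± 0.36 vs 0.42 ± 0.11, TRBF 70.42 ± 32.30 vs
  45.85 ± 11.97 µL/min, and so on), rather than rendering images per
  subject, so the statistics layer is tested independently of the imaging
  layer. Each metric splits its variance between a subject random effect and
  an eye-level residual with intraclass correlation `icc` (default 0.5, a
  middle-ground choice in the absence of published fellow-eye correlations);
  the marginal SD always matches the configured group SD. The default layout
  fixes the bilateral subjects (first 3 SCR, first 7 NC) so a default cohort
  has exactly 12/19 subjects and 15/26 eyes; sex follows the study counts,
  and MAP is realized through three synthetic (systolic, diastolic) readings
  with a 40 mmHg pulse pressure whose per-reading MAPs average to the
  sampled value. TRBF is floored at 1 µL/min (the normal draw makes negative
  flow possible at ≈ 1–2% per SCR eye; the floor is physiological and
  negligible for the moments).
* **Association coupling** (optional) regenerates one outcome as
  `common intercept + slope·(TRBF − TRBF mean)/100 + subject effect +
  residual` with user-set SDs. The intercept is common to both groups on
  purpose: the outcome's group structure then arises only through TRBF, the
  fitted association model is correctly specified, and the configured slope
  is the exact estimand — which is what makes slope recovery and CI coverage
  interpretable. With group-specific intercepts the marginal slope would be
  confounded by group and the "truth" ill-defined.

None of the generators simulate OCT speckle, projection artifacts, vessel
caliber variation along a segment, or segmentation failure modes of real
OCTA; passing tests therefore validate the measurement definitions and
their statistical behaviour, not robustness to clinical image quality.

# Statistics layer

MAP is `⅓ systolic + ⅔ diastolic` averaged over readings; readings with
diastolic ≥ systolic are rejected. The folded F statistic is
\(s^2_{max}/s^2_{min}\) with a doubled upper-tail F p-value. The pooled
t-test works from summary statistics so published mean ± SD rows can be
checked directly. Fisher's exact p sums hypergeometric probabilities of
tables no more probable than the observed one (delegated to
`stats::fisher.test`; an exhaustive-enumeration oracle in the tests confirms
equality to 1e-9). Power for detecting a correlation uses the Fisher-z
closed form including the negligible opposite tail, so power → α as r → 0.

The mixed models are `outcome ~ trbf/100 + map + laterality + (1 | subject)`
and `outcome ~ group + map + laterality + (1 | subject)` with NC the
reference level, fitted by REML (`lme4`). Laterality enters as a fixed
binary covariate and subject as a random intercept — the standard reading of
"adjusted for eye, accounting for intra-subject correlation". Inference on
the focal coefficient is Wald-type with Satterthwaite degrees of freedom
(`lmerTest`); with 31 subjects and 41 eyes this gives empirical 95% CI
coverage of ≈ 0.95 (the acceptance suite measures it over 200 simulated
cohorts and requires 0.95 ± 0.03). Rank-deficient fixed-effect designs are
rejected with the collinear columns named. Rows with missing values drop out
listwise per model; no multiple-testing correction is applied, matching the
unadjusted reporting convention of this literature. Tests are two-sided at
α = 0.05 throughout.

# Problem sizes and numerical choices

The test and acceptance runs use: 50 random smooth curves for the VTI oracle
(1e-9 relative agreement), 10⁶ uniform pixels for the FDR partition
(± 0.005), 20 seeded noisy phantoms (phase noise SD 0.1 rad, recovery within
10%; noise-free within 5%), and 200 simulated cohorts for slope recovery
(mean within 10% of 0.5) and CI coverage — sizes at which the checks are
sharp while the full suite runs in well under a minute on one core. The
k-means runs at most 200 Lloyd iterations; skeleton endpoint extension is
capped at 50 px; sign-change detection uses ε = 1e-6; CSV outputs round-trip
through `read.csv`/`write.csv` unchanged.

# Known limitations

* The bifurcation definition (≥ 3 skeleton neighbours) merges junctions
  closer than ~2 px; fine for 6 mm fields at ≥ 256 px but coarse for very
  dense capillary meshes.
* The VTI's extracted-skeleton value differs from the truth-centerline value
  for the same vessel (the skeleton is smoother than the rounded analytic
  path); both rise strictly with generated amplitude, which is the
  behaviour the index is used for.
* TRBF assumes veins are normal to en-face planes; oblique vessels would
  need an angle correction that is deliberately out of scope.
* The cohort generator draws metrics from normal distributions; real VTI
  distributions in disease are right-skewed, so group-difference effect
  sizes transfer only approximately.
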