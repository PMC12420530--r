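---
title: "Co-60 HDR brachytherapy dosimetry with cobraplan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-60 HDR brachytherapy dosimetry with cobraplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobraplan)
```

## What the package models

`cobraplan` is a desk-scale emulation of the dosimetric evaluation of
intracavitary high-dose-rate (HDR) brachytherapy for locally advanced
cervical cancer delivered with a Cobalt-60 stepping source through a
tandem-and-ovoids (Fletcher-style) applicator. The emulated protocol is
7 Gy per fraction in 4 fractions prescribed to Manchester Point A,
following a 45 Gy / 25 fraction external-beam course. The package covers
the full evaluation chain a medical physicist would run in a treatment
planning system (TPS):

1. a TG-43 dose engine (`co60_source()`, `compute_dose()`),
2. plan construction and Point A normalization (`brachy_plan()`,
   `normalize_to_point_a()`),
3. DVH metrics and plan-quality indices (`dvh()`, `d_percent()`,
   `d_2cc()`, `plan_indices()`),
4. EQD2 accumulation and constraint audit (`eqd2()`, `eqd2_audit()`),
5. a rigid-body / TPS-variability uncertainty framework
   (`perturb_and_evaluate()`, `tps_variability()`), and
6. synthetic pelvic phantom cohorts replacing patient CTs
   (`phantom_spec()`, `make_phantom()`, `sample_cohort()`,
   `run_pipeline()`).

## The dose model and its assumptions

Dose rate around a single dwell follows the AAPM TG-43 formalism,

$$\dot D(r,\theta) = S_K \,\Lambda\,
  \frac{G(r,\theta)}{G(r_0,\theta_0)}\, g(r)\, F(r,\theta),$$

with air-kerma strength $S_K$ (U), dose-rate constant $\Lambda$
(cGy h$^{-1}$ U$^{-1}$), the line- or point-source geometry factor $G$,
radial dose function $g(r)$ and 2-D anisotropy function $F(r,\theta)$,
referenced at $r_0 = 1$ cm, $\theta_0 = 90^\circ$. Plan dose is the
dwell-time-weighted superposition over all dwells — dose is exactly
linear in the dwell times, which several tests exploit.

Assumptions inherited from TG-43: water-equivalent, unbounded
homogeneous medium; no applicator shielding or inter-source attenuation;
no heterogeneity corrections. Voxel dose is sampled at the voxel centre
with a single sample, adequate at the default 1 mm grid and a documented
approximation at the CT-like 2.5 mm slice spacing.

The shipped `co60_source()` tables are **generic configuration**, not a
measured dataset: $\Lambda = 1.087$ cGy h$^{-1}$ U$^{-1}$, active length
3.5 mm, a nearly flat $g(r)$ and a mild polar anisotropy dip, all typical
of clinical Co-60 HDR sources. Site-specific tables load through
`source_model()` / `read_source_tables()` (CSV, columns `r_cm,g` and
`r_cm,theta_deg,F`); tables are renormalized on construction so
$g(1\,\text{cm}) = 1$ and $F(r, 90^\circ) = 1$ exactly. A `point` mode
with flat tables gives the analytic inverse-square kernel used by the
validation tests.

Two properties of the line-source geometry factor worth knowing: $G_L$
at fixed $r$ is *minimal* in the transverse plane (transverse field
points are farthest from the source ends), so transverse-peaked dose
profiles at clinical radii come from $F(r,\theta)$, not $G_L$; and $G_L$
is undefined on the source long axis within the active length. The
engine therefore masks voxels closer to any dwell than
$\max(r_\min, 0.55\,L)$ (1.93 mm by default) as `in_applicator`,
excludes them from every DVH, and clamps their kernel radius. These
voxels are inside the applicator lumen in any physical plan.

## Planning model

Clinical planning in the emulated protocol used manual/graphical
optimization. The package abstracts this to a fixed Manchester-style
relative loading (tandem dwells weight 1.0, ovoid dwells 0.9; 9 tandem
dwells at 5 mm steps, 2 dwells per ovoid by default) followed by a
single scalar normalization making the mean dose at the two Point A
positions equal the prescription. The normalization is idempotent and
inversely proportional to $S_K$. An optional non-negative least-squares
dwell-time optimizer (`optimize_dwells()`, via `pracma::lsqnonneg`) is
provided for exploration but is not part of the reference pipeline.

Point A is constructed per the Manchester convention: 20 mm superior to
the external cervical os along the tandem axis, then 20 mm laterally
(left/right) in the tandem's frontal plane; the pair is equivariant
under rigid applicator motion and left/right symmetric in the
unperturbed pose.

## DVH metrics: numerical choices

* The cumulative DVH is an exact voxel-count histogram on a fixed
  0.01 Gy bin grid (`dvh()`), used for export and plotting.
* $D_x$ / D2cc are computed from the exact voxel-dose order statistics,
  not the binned curve: sorted descending, voxel $i$ covers cumulative
  volume $((i-1)v, iv]$ with its dose attributed to the interval centre,
  linear interpolation between centres. This makes uniform-dose
  structures return the uniform dose exactly, a linear dose ramp return
  the closed-form quantile, and every $D_x$ scale *exactly* with a
  multiplicative dose factor — the property the ±2% TPS variability
  model relies on. Sub-half-voxel and beyond-range queries clamp to the
  hottest/coldest voxel dose.
* `d_2cc()` refuses structures below 2 cm³ and suggests reporting
  D(V = total volume) instead.
* Indices use exact voxel counts with the whole-grid (treated-volume)
  convention for V100/V150/V200: CI = V100$_{\mathrm{CTV}}$/CTV,
  COIN = CI × selectivity, DHI = (V100 − V150)/V100, DNR = V150/V100
  (DHI + DNR = 1 identically), ODI = V200/CTV. The treated-volume
  convention follows the printed formulas most literally; in-applicator
  voxels are excluded everywhere.
* Percent-of-prescription values round half-up to one decimal
  (`percent_of_rx()`), matching how such tables are conventionally
  printed; banker's rounding would differ at exact .x5 boundaries.

## EQD2 accounting

`eqd2()` implements $\mathrm{EQD2} = D\,(d + \alpha/\beta)/(2 +
\alpha/\beta)$; `eqd2_audit()` accumulates the external-beam course
(45 Gy at 1.8 Gy/fx by default) plus the brachytherapy fractions
evaluated at their per-fraction D2cc, with $\alpha/\beta = 3$ Gy for
late-responding organs at risk (10 Gy for tumour), and flags the
clinical planning aims: bladder < 80 Gy, rectum/sigmoid/bowel < 75 Gy.
Per-fraction D2cc is assumed equal across fractions, as when one plan is
delivered four times — a conservative simplification (true interfraction
anatomy varies). Note that a bladder receiving 5.40 Gy/fraction
accumulates 79.49 Gy (passes), while 5.73 Gy/fraction accumulates
83.2 Gy (flagged): the audit is intentionally strict around this
boundary, and default-cohort audits therefore flag a substantial share
of bladder rows.

## The uncertainty framework

`perturbation_spec()` defaults encode the evaluated uncertainty model:
±1 mm translations along each cardinal axis (6 scenarios), ±2° rotations
about each axis through the cervical os (6 scenarios), and ±2%
multiplicative TPS dose-calculation variability. Design choices made
where the procedure was genuinely open:

* **No renormalization after perturbation.** The delivered plan is
  fixed; the positioning error moves it. This reproduces the
  delivery-error reading of a displacement table (the alternative —
  re-prescribing after the error — would largely cancel the effect).
* **Dwells move, anatomy stays fixed** (applicator-vs-anatomy error
  model). By relativity the inverse convention gives identical metrics;
  the shifted-grid equivalence is a regression test.
* **Rotation pivot at the os**, where the applicator is anatomically
  anchored. An `applicator_centroid` pivot is available.
* Percent changes are $100\,(x - x_{\mathrm{baseline}})/
  x_{\mathrm{baseline}}$, computed per scenario; the report carries both
  the per-scenario table and min/max ranges (Gy and %).

Cohort statistics (`summarize_cohort()`) report mean, sample SD
($n-1$), SE = SD/$\sqrt{n}$ and a normal-approximation 95% CI
(±1.96 SE, matching the arithmetic of the emulated report rather than
Student-t). `n_override` supports per-fraction observation counting
(30 patients × 4 fractions = 120 observations), which is how an SE of
0.067 arises from an SD of 0.739.

## What the synthetic cohort emulates — and what it does not

`make_phantom()` builds geometric-primitive anatomy on a voxel grid
(default 1 mm isotropic; `voxel_size = c(1, 1, 2.5)` emulates 2.5 mm CT
slices): an ellipsoidal HR-CTV centred on the tandem, bladder anterior,
rectum posterior, sigmoid posterior-superior, bowel draping
anterior-superior over the fundus. Each organ is placed along an
anatomical direction at a *wall-to-tandem offset*; offsets are strictly
ordered bladder < rectum < sigmoid < bowel and `sample_cohort()`
enforces minimum separations (3/2/2 mm) when drawing patients from
truncated normal distributions.

The nominal geometry is **calibration, not measurement**: the emulated
study reports dose statistics, not anatomy, so wall offsets, HR-CTV
semi-axes and organ aspect ratios were chosen once so that the nominal
phantom, planned to 7 Gy at Point A on the 1 mm grid, lands on the
reported cohort anchors (D90 ≈ 100% of prescription, V100 ≈ 90%, D2cc
bladder ≈ 5.7, rectum ≈ 4.7, sigmoid ≈ 3.3, bowel ≈ 3.0 Gy), and the
population spreads give larger relative variability for sigmoid/bowel
than bladder/rectum, echoing the reported SDs. Conformity/homogeneity
indices are *not* calibration targets: simulated COIN is higher and DHI
lower than the printed means, as expected for idealized convex anatomy
with fixed loading — clinical conformity reflects irregular target
shapes and per-patient optimization that primitives do not capture.

Passing tests on this cohort therefore demonstrate the correctness of
the dose engine, metric extraction and uncertainty arithmetic, and the
*reproducibility* of the reported organ-dose ordering and robustness
bounds under realistic geometry. They do not validate contouring,
applicator reconstruction, interfraction deformation, vaginal packing
beyond its offset effect, or any patient-specific clinical claim.

## Degenerate inputs and tie-breaks

* Dwell orientations must be unit vectors; degenerate tandem axes and
  lateral axes parallel to the tandem are constructor errors.
* `dose_rate_at()` errors below `r_min` ("too close to source");
  in-grid voxels that close are masked instead, as above.
* Empty dwell sets, all-zero dwell times, zero Point A dose, empty
  masks, empty prescription isodose (DHI/DNR undefined) and cohorts of
  fewer than 2 values for summary statistics are explicit errors.
* Beyond-range table lookups clamp to the edge value (Co-60 $g(r)$ is
  nearly flat, so clamping is conservative); $\theta$ is folded into
  $[0°, 180°]$ by the arccosine.
* Perturbation scenarios that push dwells outside the dose grid error
  with the scenario name.

## Problem sizes and reproducibility

Everything is deterministic given the seeds: phantom construction is a
pure function of its spec, cohorts derive from a single master seed, and
`run_pipeline()` bundles a manifest (seed, n, grid, prescription,
source strength) so two runs with one config are bit-identical. The test
suite runs its property checks on 2–5 mm grids and small synthetic dose
arrays; the rotation-robustness check runs the full 1 mm reference grid
(~1.6M voxels, about a minute), the size used for all reported reference
numbers. The cohort-ordering property is checked for n = 30 phantoms at
2.5 mm across several master seeds.

## Known limitations

* TG-43 water kernel only: no Monte Carlo transport, shielding,
  applicator attenuation or tissue heterogeneity.
* Single-sample voxel dose underestimates gradients at 2.5 mm slices.
* Geometric-primitive anatomy: no image segmentation, no DICOM import
  (the JSON/CSV interfaces are the extension point).
* One plan delivered for all fractions; no interfraction adaptation.
* The EQD2 model is the bare linear-quadratic conversion without
  repair/repopulation corrections.
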