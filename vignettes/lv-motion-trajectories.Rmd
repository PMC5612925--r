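---
title: "Methods: LV motion trajectories, Linear-Shift transport and their tests"
author: "cardiomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LV motion trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical conventions, and the
design choices that were genuinely open. Everything quantitative stated here
is computed by the test suite or by `scripts/acceptance.R`; nothing is
quoted from external data.

## The statistical model

A case is a pair of landmark surfaces (endocardium, epicardium) with `k`
homologous landmarks observed through one cardiac cycle. The analysis
object is not the shape but the *deformation path*: the sequence of
within-cycle deformations of a case relative to its own mean shape,
expressed at a common reference so cases are comparable.

**Assumptions.**

- Landmarks are anatomically homologous across cases and frames; landmark
  index is identity and is never permuted.
- The cycle is ED → ED (frame 1 at phase 0) and periodic; motion is smooth
  enough that five Fourier harmonics capture the per-coordinate signals.
- Within-cycle deformations are small relative to between-case shape
  differences, so the Euclidean (tangent-space) approximation underlying the
  Linear Shift is adequate. This is the standard small-variation regime of
  geometric morphometrics.
- Groups (`Control`, `MI`) are the only design factor; cases are
  independent.

**Pipeline.** For one surface and one space (SSS = size-and-shape space,
translation + rotation removed; SS = shape space, scale removed as well):

1. common GPA over all case-frames; its consensus is the common template
   (CT, the grand mean). This GPA serves only to find the CT.
2. per-case GPA; the consensus is the case's local template (LT).
3. OPA-align each LT to the CT.
4. Linear Shift: each frame is OPA-aligned to its aligned LT, the
   deformation `d_t = frame_t − LT` is carried over as `CT + d_t`.
5. common GPA over the transported shapes, then one joint PCA over all
   case-frames, so per-frame scores share axes across the cycle.

Transporting the LT itself returns the CT exactly, and `‖d_t‖` is preserved
(step 4 adds a constant), which the tests assert to machine precision.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `nFrames` | 30 | frames | output resolution of the normalized cycle |
| `esTargetPhase` | 0.35 | cycle fraction | systole occupies ~35% of the heartbeat; frame 11 is the nominal ES under the floor convention |
| `nHarmonics` | 5 | — | smooth cardiac motion is band-limited in practice; 30 frames > 2·5+1 satisfies the sampling requirement |
| `nPCs` (trajectory) | 3 | — | the trajectory is analyzed in the space of the first three deformation PCs |
| `nShapePCs` | 15 | — | trajectory-shape scores entering MANOVA/dispersion tests |
| SVM settings | linear kernel, cost 1, z-scoring on train | — | deterministic, appropriate for PCA-derived features; RBF available via `kernel=` |
| splits | 200+200 train / 100+100 test, 1,000 repeats | cases | the evaluation protocol; cohorts smaller than 300 per class fall back to stratified 2/3–1/3 splits |

## The synthetic generator

`generateCohort()` emulates the *structure* of population cardiac shape
data, not cardiac biophysics:

- two nested truncated-ellipsoid surfaces (endo semi-axes 25/75 mm, wall
  8 mm, truncation 2π/3) on a rings × meridians grid plus an apex landmark
  (default 9 × 12 + 1 = 109 per surface; the grid is configurable up to and
  beyond the 1,089 landmarks of full-resolution models — the pipeline is
  size-agnostic, and the default is chosen for test speed);
- a smooth cyclic contraction `g` (raised cosine on a warped "contraction
  clock") with its peak at a case-specific raw ES phase drawn from
  U(0.4, 0.6), sampled at a case-specific raw frame count drawn from
  U{20..35}, so the temporal-registration path does real work;
- anisotropic contraction `diag(ρ, ρ, λ)` about the base plane with
  `ρ = 1 − a·g` and `λ = 1 − a·longRatio·(1−sphericity)·g`; cavity volume
  scales exactly by `ρ²λ`, so the amplitude realizing a programmed ejection
  fraction has a closed form (`amplitudeForEF()`);
- group effects: endocardial radial amplitude 0.55 (Control) vs 0.30 (MI);
  sphericity change 0 vs 0.4 (MI loses long-axis shortening, its
  contraction becomes more spherical); optional septal akinesia as an
  angular-sector damping mask (off by default);
- the epicardium contracts at 0.45× the endocardial amplitude and expresses
  only half of the group amplitude difference (`epiEffectRatio = 0.5`):
  infarct motion abnormality is endocardium-dominant, and this is the
  feature that makes the endocardial effect size exceed the epicardial one
  in the size ANOVA;
- inter-individual variation: 6% lognormal size jitter, 4° orientation
  jitter; per-frame rigid jitter (0.3 mm / 0.3°) and i.i.d. landmark noise
  (SD 0.5 mm, the scale of MR feature-tracking uncertainty).

**What it does not emulate — and what passing tests therefore do not
show.** Baseline anatomy is group-independent: there is no infarct
remodeling of ED size or shape, so the EDV feature classifies at chance by
design and conclusions about traditional-indicator performance on real
cohorts cannot be drawn from the simulator. Wall motion is globally scaled
(no regional strain patterns beyond the optional septal mask), noise is
i.i.d. rather than spatially correlated, and valve-plane motion is absent.
Passing tests demonstrate that the pipeline recovers what the generator put
in — amplitudes, timing, group separations — not that real MI hearts behave
this way.

The canonical fixture `generateNullTransportPair()` builds two cases with
genuinely different baseline shapes sharing an identical displacement field.
The fields are constructed so every Procrustes cross-covariance in the
pipeline is symmetric positive-definite (fields centered, orthogonal to both
templates' rotation and scale directions and to each other's rotation
directions; templates size-matched): all optimal rotations are then exactly
the identity and post-transport trajectories coincide to machine precision
in SSS — the transport-nulling property in its sharpest form.

## Numerical conventions

- **Rotations** are restricted to det = +1 (SVD solution with
  smallest-singular-value sign correction): anatomical shapes must not
  mirror. A fully degenerate cross-covariance returns the identity with a
  warning; near-rank-deficient cases warn that the optimum may be
  non-unique.
- **GPA** iterates align-to-consensus with the consensus re-estimated as
  the mean of aligned shapes; convergence at relative objective change
  < 1e-10, at most 100 iterations (non-convergence returns the current
  state with a warning). In SS the configurations stay at unit centroid
  size and the alignment target is the consensus renormalized each
  iteration; the returned consensus is the plain mean, so "consensus = mean
  of aligned" holds in both spaces.
- **SS-mode OPA** normalizes both configurations to unit size before
  rotating and scaling: the residual is the squared partial Procrustes
  distance and is invariant under common scaling. The optimal scale (the
  cosine of the Procrustes angle) is clamped at zero with a warning for
  pathological near-antipodal pairs.
- **Shape-space curvature.** In SS the optimal scale < 1 leaks a
  template-direction component of order (deformation/size)² into the
  transported deformation. It differs between cases with different
  templates, so transport nulling in SS holds only to that second-order
  scale (~1e-5 at 3% deformation), while SSS nulls to machine precision.
  This is a property of shape space, not an implementation artifact; the
  tests bound it explicitly.
- **Fourier representation.** Harmonic coefficients are obtained by
  least-squares trigonometric regression on the warped samples (classic
  Fourier interpolation), which reproduces any signal band-limited to the
  harmonic budget exactly given ≥ 2H+1 samples — the property the
  registration tests assert at 1e-6. A periodic cubic spline through the
  samples (`periodicSplineFun()`) is provided as the supporting continuous
  interpolant for visualization; extracting harmonics *from* the spline
  would inherit its O(h⁴) interpolation error (~1e-3 for harmonic-5 content
  at 30 samples) and cannot be exact.
- **ES detection.** The cavity-volume minimum of a registered sequence
  generically falls between frames 11 (phase 10/30) and 12 (11/30) when the
  true minimum sits at 0.35, and measurement noise makes the discrete
  argmin flip between them. `detectESFrame()` therefore fits a circular
  parabola through the argmin and its neighbours and reports the frame
  containing the vertex under the floor convention (frame 11 for a minimum
  at exactly 0.35); `refine = FALSE` gives the plain argmin with
  earlier-frame tie-break. On noisy cohorts the modal detected frame is 11
  with a spread into frame 12 — the same qualitative spread seen in real
  registered data.
- **PCA** uses the sample covariance of row-major landmark flattenings
  (x1, y1, z1, x2, ...); each component's largest-magnitude entry is made
  positive so score signs are reproducible across platforms.
- **Angles** are reported in degrees on [0°, 360°). Group tests on angles
  use plain ANOVA; angles live on a circle, so the wrap-around caveat
  applies when group means straddle 0°, and `circularVariance()` is exposed
  as a diagnostic. The ED→ES vector uses nominal frame 11 (times are
  homologous after registration); a per-case ES frame can be passed via
  `esIndex`.
- **Degenerate inputs.** Constant ANOVA data return F = 0, p = 1 (adjusted
  R² ≤ 0); trajectories with coincident ED and ES raise an undefined-angle
  error and are dropped (with a warning naming the case) from angle feature
  sets; trajectory-shape MANOVA returns Λ = 1, p = 1 when aligned
  trajectories carry no variation at all.
- **Permutation nulls.** The dispersion test permutes group labels with a
  fixed seed (p = (1 + #{F* ≥ F})/(nPerm + 1)). For the SVM chance control,
  labels are re-permuted before *every* split: at desk-scale cohorts
  (n = 60) a single fixed permutation retains a chance train–test label
  correlation of order 1/√n that biases mean accuracy above 0.5; fresh
  permutations restore the exact chance level.

## Design choices that were open

- Whether the final common GPA keeps the CT fixed or re-estimates its
  consensus: we re-estimate, and record the CT drift and the largest
  rotation angle as diagnostics (both are near zero on all tested data,
  since transported shapes are small deformations of one template).
- Whether GPA should allow reflections: excluded, as standard for
  anatomical data.
- The effect-size measure for the angle/size ANOVAs is the *adjusted* R²
  (it can be negative under the null, which plain R² cannot).
- Per-frame significance tracks report raw p-values plus
  Benjamini–Hochberg flags, since per-frame testing along a smooth cycle is
  a multiple-comparison setting.
- Serialization of transported datasets uses a plain-text directory (CSV
  matrices + JSON metadata); datasets on disk are tidy per-case CSVs with a
  JSON manifest and an explicit triangle-list mesh file, all at full double
  precision so write → read round-trips exactly.

## Problem sizes used by the tests

The suite validates on desk-scale versions of the study conditions, chosen
as the package's own trade-off between statistical resolution and test
runtime: cohorts of 30 + 30 cases with 109 landmarks per surface for the
calibration and effect-recovery checks (500 label-reassignment replicates
for ANOVA calibration, 200 for the dispersion/per-time/SVM nulls), 10 + 10
cases for EF recovery, and 100 random configuration sets for the Procrustes
property checks. Because group labels are assigned independently of the
data, label reassignment on an exchangeable cohort is equivalent to
regenerating cohorts for type-I calibration, at a fraction of the cost.

## Known limitations

- The Linear Shift is the Euclidean approximation of parallel transport;
  with large deformations or large between-case shape differences the
  approximation degrades (see the SS curvature note above). Riemannian
  connections and thin-plate-spline transport are out of scope.
- Angles are tested linearly despite their circular support.
- The trajectory-shape MANOVA assumes multivariate normality of shape
  scores within groups; the permutation dispersion test is provided
  alongside partly for that reason.
- Real datasets must supply their own surface triangulation for volume
  computation; only the generator's rings × meridians topology is built in.
- `runPipeline()` expects both surfaces of every case to share the landmark
  grid; mixed-resolution cohorts are not supported.
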