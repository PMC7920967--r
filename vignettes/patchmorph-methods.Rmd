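---
title: "Patch-based surface morphometry: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based surface morphometry: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchmorph)
```

This vignette is the package's own account of the science it implements:
the geometric and statistical model, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices a maintainer would want
written down.

## The analysis model

The pipeline asks whether a clinical grouping is associated with
*localized* surface expansion or atrophy of a subcortical structure, as
opposed to a global volume difference. It proceeds in four stages.

**Surface extraction and template.** Subject segmentations become
triangle meshes in world millimetres. We extract iso-surfaces with
marching tetrahedra (the Kuhn 6-tetrahedra decomposition of each voxel
cell, crossing points interpolated at level 0.5): a deliberately simple,
table-free variant of marching cubes that always produces a watertight,
edge-manifold surface. The downstream pipeline never depends on the
mesher. The population template is the iterative vertex-wise mean of
rigidly aligned subject surfaces. Alignment is rotation + translation
only — **no scaling** — because overall size is biological signal here;
head-size differences are handled statistically by the ICV covariate, not
removed geometrically. Template iteration stops when the mean vertex
displacement falls below 1e-4 mm (usually 2–3 iterations).

Cross-subject vertex correspondence is *assumed*: all subject meshes must
share the template's vertex topology. In the study design this package
emulates, correspondence came from diffeomorphic surface registration;
reimplementing that machinery is out of scope, and the pipeline refuses
uncorresponded inputs (e.g. independently meshed masks) with an explicit
message rather than silently producing meaningless Jacobians. The
synthetic generator provides correspondence by construction.

**Parcellation.** The patch count follows the average-area rule
`k = max(1, round(total_area / target_area))` with a 150 mm² target,
rounding half away from zero. On desk-scale stand-ins (icosphere of
radius 10.37 mm for a hippocampus-scale area of ~1350 mm²; radius 6.91 mm
for an amygdala-scale ~600 mm²) this yields k = 9 and k = 4. Vertices are
embedded by their coordinates in low Laplace–Beltrami eigenvectors and
clustered with k-means (20 restarts, seeded). Two readings of "the first
k eigenvectors" exist: including the constant eigenvector wastes one
embedding dimension, so the default uses the k lowest *non-constant*
eigenvectors; `include_trivial = TRUE` reproduces the literal reading.
Patch contiguity is not guaranteed by k-means, so by default label
islands are reassigned to the neighbouring patch with the longest shared
boundary, iterated to convergence. Labels are canonicalized to descending
patch area (ties broken by lowest vertex index) so that runs are
reproducible and reports comparable.

**Features.** The expansion factor at a vertex is the ratio of
barycentric vertex areas (one third of incident triangle area), subject
over template. This is the simplest discrete measure of local area
change; it satisfies exactly the conservation identity that the
template-area-weighted mean of the field equals the total area ratio, and
it is the quantity our tests calibrate against. A one-ring face-area
alternative and a log scale are available behind flags; the default is
the raw factor scale, where 1 means no change and 0.85 means 15% local
atrophy. Patch features are *unweighted* vertex means within each patch
(an area-weighted option exists and is documented as a deviation).

**Inference.** For each patch, two nested ordinary-least-squares models
are fit across subjects: intercept + age + sex + ICV, without and with a
response indicator (1 = non-responder). The statistic is the SSE ratio
`s_p = SSE_null / SSE_alt`, which is always ≥ 1 and equals
`1 + F/(n − 5)` with F the partial F statistic of the response column —
an identity our tests check against an independent `lm()`/`anova()`
implementation at 1e-9. Covariates are left unstandardized: `s_p` is
invariant to affine rescaling of features and covariates, and raw-scale
coefficients stay interpretable in expansion-factor units. Sex is coded
female = 1 (the choice is inert to `s_p`). Familywise error across the
patches of a structure is controlled with the max-statistic permutation
test at the 95th percentile; adjusted p-values use the `(1+b)/(1+B)`
convention, which guarantees validity and avoids zero p-values, and the
critical value is defined as the order statistic that makes
"s_p above the critical value", "adjusted p < 0.05" and the reported
significance flag exactly equivalent, with strict inequality at ties.
When the subjects admit no more than `n_perm` distinct rearrangements the
test enumerates all of them instead of sampling.

Two permutation schemes are provided because the phrase "rearrange the
features among the subjects" is ambiguous about covariates:

- `shuffle_features` (default, the literal reading): whole feature
  vectors are permuted against the fixed design. This also breaks the
  feature–covariate association, so when covariates explain a large share
  of feature variance the permutation null is not exact for the *partial*
  response effect.
- `freedman_lane`: null-model fitted values are kept and only null-model
  residuals are permuted, preserving the covariate structure.

At the package's default noise levels the literal scheme is
well-calibrated (the acceptance suite measures a familywise error rate
statistically indistinguishable from the 5% target over 500 null
cohorts); the
Freedman–Lane scheme is the conservative choice when covariate effects
dominate.

The two supported contrasts are non-responders vs. responders (patients
only) and non-responders vs. the union of healthy subjects and
responders; a second timepoint is just a second response-label column.
Percent atrophy of a flagged patch is reported as
`100 · (1 − mean_NR / mean_comparison)` of the patch expansion factors —
a raw descriptive ratio, deliberately unadjusted, so it includes any
group difference in overall size along with the localized effect.

## The synthetic cohort generator

The generator defines the study conditions every test runs under. Its
defaults are fixed once and mirror the emulated cohort:

- group sizes 21 healthy comparison / 9 responders / 5 non-responders;
- age drawn per group from normals with means (36.3, 37.7, 31.0) years
  and SDs (13.0, 15.2, 9.8);
- sex Bernoulli with P(female) = (0.71, 0.78, 1.0) — the non-responder
  group is all-female by design. Because a modeled covariate needs at
  least two distinct values inside each contrast subset, the sex vector
  is redrawn when a draw happens to make it constant among the patients;
- ICV per group from normals with means (1503, 1472, 1406) × 10³ mm³ and
  SDs (132, 134, 34) × 10³ mm³.

At the **feature level**, the patches × subjects matrix is drawn directly
from the linear model the analysis assumes, with coefficients
(intercept 1; age −0.002 per year; sex +0.02; ICV 5e-8 per mm³ — small
effects on a quantity whose natural scale is 1), a response effect of
−0.15 at one target patch, and Gaussian noise with SD 0.05. The noise SD
was chosen so that a 15% single-patch deficit at n = 35 is detectable but
not trivial, matching the character of a borderline-significant finding.

At the **mesh level**, each subject is the template deformed by (i) a
global isotropic scale `(ICV / ICV_ref)^(1/3)`, (ii) smooth noise along
vertex normals built from the first six non-constant Laplace–Beltrami
eigenfunctions with seeded Gaussian coefficients (default amplitude
0.1 mm) — smooth, correspondence-preserving shape variation standing in
for the anatomical variability that diffeomorphic registration would
otherwise capture — and (iii) for non-responders, a contraction of the
target patch toward its centroid, ramped to zero over the three vertex
rings nearest the patch boundary and calibrated by root-finding so the
patch's mean vertex-area expansion factor equals exactly 1 − a. The ramp
keeps the displacement from denting a wall into neighbouring patches:
with zero noise, off-target patch means stay within 2% of 1. A pure
inward (normal) displacement with a pinned boundary cannot produce a 15%
area deficit at all — the patch area is then bounded below by a minimal
surface spanning the fixed boundary — which is why the generator
contracts tangentially instead.

What the generator does **not** emulate: segmentation error, scanner and
acquisition effects, registration failure, non-smooth or high-frequency
shape variation, and any nonlinear covariate dependence other than the
ICV^(2/3) scaling geometry imposes on areas. That last mismatch is
informative: the GLM models ICV linearly while mesh-level features scale
as ICV^(2/3), and when the shape-noise amplitude is made very small this
curvature residual becomes the dominant "signal", inflating statistics in
all patches under the literal permutation scheme. Passing tests on these
cohorts therefore demonstrate the statistical machinery under its own
assumptions (plus mild geometric mismatch), not robustness to real MRI
artefacts.

## Numerical choices

- **Laplacian.** FEM cotangent stiffness with barycentric lumped mass;
  the generalized eigenproblem `K φ = λ M φ` is solved exactly as the
  dense symmetric problem `M^{-1/2} K M^{-1/2}` (the mass matrix is
  diagonal). At this package's mesh sizes (≤ 2562 vertices; 642-vertex
  icospheres for the desk-scale analyses) a dense solve is fast, handles
  the zero eigenvalue without shift-invert tricks, and matches the
  spherical-harmonic spectrum `l(l+1)/r²` within 3% through l = 3.
  Degenerate triangles (non-finite cotangents) abort with the offending
  face named.
- **Vertex areas.** Barycentric (one-third) rather than Voronoi: always
  positive, exactly conservative, simpler — the properties the Jacobian
  identity and the atrophy calibration rely on.
- **Residual projectors.** SSE is computed through `I − QQᵀ` from the
  thin QR of the design, not from normal equations: with ICV in mm³ the
  cross-product matrix is near-singular in double precision.
- **Perfect fits.** An alternative-model SSE at round-off level
  (≤ 1e-12 of the feature scale) is reported as `s_p = Inf` with a
  warning; the permutation machinery treats it as always-maximal.
- **Tie-breaks.** Patch relabeling breaks area ties by lowest contained
  vertex index; the permutation threshold uses strict `>` at ties.
- **Determinism.** Every stochastic stage takes an explicit seed and
  restores the caller's RNG state; identical configs produce
  byte-identical output files, which the test suite asserts.
- **Problem sizes.** The validation suite runs at the study's own scale:
  35-subject cohorts, 9 patches, 1000 permutations per test and 500
  cohorts for the familywise-error measurement; icospheres at subdivision
  3 (642 vertices) for mesh-level end-to-end runs and subdivision 4
  (2562 vertices) for spectrum accuracy checks. These sizes were chosen
  as the smallest at which the quantities of interest are measured at
  their natural scale.

## Known limitations

- No diffeomorphic registration: correspondence must be supplied, and
  the masks → statistics path intentionally refuses.
- The marching-tetrahedra surface slightly smooths sharp voxel corners
  (a 5-voxel cube's area is recovered to ~6%, well inside the documented
  15% tolerance) and, like any binary-mask mesher, quantizes fine detail.
- Patch geometry is data-independent (template-only), which is the
  method's point, but means patch boundaries need not align with
  anatomical subfields; mapping a flagged patch to a named subregion is
  interpretation, not computation.
- With ≤ 14 subjects in the patients-only contrast the permutation floor
  is `1/(B+1)`; results below ~0.001 are resolution-limited at the
  default 1000 permutations used in tests (10,000 in the analysis
  default).
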