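---
title: "Cortical bone mapping and surface SPM of the proximal femur: models and methods"
author: "boneSPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone mapping and surface SPM of the proximal femur: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package computes

boneSPM studies how the cortical bone of the proximal femur is distributed
over its surface, and in particular whether femur *size* is associated
with a focal cortical deficit at the superior femoral neck.  The analysis
chain is:

1. **Cortical bone mapping (CBM).**  At each surface vertex a CT-style
   density profile is sampled along the outward normal and fitted with a
   blur-aware three-level model, giving cortical thickness (CTh, cm),
   cortical bone mineral density (CBMD, mg/cm³) and their product, the
   cortical mass surface density (CMSD = CTh × CBMD, mg/cm²).
2. **Canonical registration.**  A canonical femur surface (5580 vertices)
   is aligned rigidly and nonrigidly to each individual femur; per-vertex
   cortical data are transferred onto the canonical mesh and smoothed.
3. **Statistical shape model.**  PCA of the registered coordinate vectors
   (16740 numbers per subject) yields linearly independent size and shape
   coefficients S₀, S₁, …; S₀ is the anisotropic size mode.
4. **Surface SPM.**  The vertex-wise GLM
   `1 + S0 + Age + S1..S5 + Site` is fitted to each outcome; an F-test on
   S₀ with family-wise correction (permutation by default) localises
   regions where the cortex depends on size, and effects are quantified
   as percent change per SD of S₀ within a frozen femoral neck patch.

Because no imaging data ship with the package, a first-class synthetic
cohort generator plants all of these quantities — demographics, shape
modes, covariate correlations, the focal deficit, imaging blur and noise
— so that every stage is testable end to end and the pipeline's job is
*parameter recovery*.

# The synthetic generator

## Demographics and covariate structure

`generateCohort()` draws age, weight and height from truncated normal
distributions whose *truncated* moments match the preset's printed
mean/SD (the underlying location and scale are solved by moment matching;
naively truncating a normal with the printed moments would shift the mean
by almost a year for the male age range).  The target correlations —
height–S₀ 0.64, weight–S₀ 0.42, age–S₀ 0, height–weight 0.5 — are
realised through a joint Gaussian copula followed by the
truncated-normal quantile transform; infeasible (non-positive-definite)
targets are rejected with a diagnostic.  Site labels rotate through the
preset's site list after a seeded shuffle, independent of the covariates.

## Shape modes

The planted shape model is built on the synthetic canonical femur (head
sphere, neck frustum, trochanteric bulge, shaft; a 93 × 60 swept grid of
5580 vertices with labelled anatomical axes).  Mode 0 is a purely affine,
rigid-free anisotropic scaling calibrated to a 7 % proximal–distal and
4 % transverse bounding-extent change per SD.  Mode 1 is a neck-shaft
angle rotation, mode 2 a femoral-neck-axis elongation, and the remaining
modes low-frequency surface undulations; per-mode variances realise the
preset fractions (58/15/6 % leading for males, 59/14/6 % for females,
with the remainder decaying over seven minor modes).

Two representation choices matter and are deliberate:

* **Normal-directed non-affine modes.**  A surface constrains a
  deformation only up to within-surface sliding, so any shape model built
  from surface registration expresses its modes in the registration's
  correspondence convention.  The generator adopts the same convention
  the registration uses: a deformation is a global affine map plus a
  normal-directed residual whose scalar field is orthogonal to the normal
  components of the affine fields.  Modes 1+ therefore keep only their
  normal component, with affine-normal scalar content projected out; all
  modes are rigid-free.  This makes "recover the planted modes" a
  well-posed task rather than one confounded by an unobservable sliding
  ambiguity.
* **No Procrustes size normalisation** anywhere: size is the signal.

## The planted lesion and the quantification patch

The focal deficit is planted multiplicatively on cortical thickness over
a generous, contiguous superior-neck/head-neck-junction region:
`CTh ← CTh · (1 + e/100 · S₀)` with e = −6.87 (males) or −6.74 (females)
percent per SD.  The shipped *default femoral neck patch* used for
quantification is the morphological core (3-ring erosion, 232 vertices)
of that region, frozen as a plain-text fixture.  This mirrors how a
quantification region is frozen from a detected SPM cluster in practice —
a supra-threshold cluster sits inside the true lesion — and it keeps the
patch interior free of edge attenuation from surface smoothing.
Age (−0.2 %/year on CTh) and small site offsets (reference site zero)
are also planted so the GLM's confounders do real work, and per-vertex
log-normal noise (SD 5 % on CTh, 2 % on CBMD) plays the role of
biological heterogeneity plus measurement error.

## Imaging model

Profiles follow the same three-level blurred model the CBM stage fits:
outside density 30 mg/cm³, cortical plateau = true CBMD over the true
CTh, trabecular level 150 mg/cm³, convolved with a Gaussian of σ = 0.75
mm and sampled every 0.5 mm over ±15 mm, plus white noise of SD 25
mg/cm³.  σ and the noise level are presets, not claims: clinical QCT
resolution is usually quoted as "around 3 mm", which is 4σ for σ = 0.75.
An optional voxel phantom (`rasterizePhantomVolume()`) rasterises the
cortical shell and blurs it in 3-D so the profile route can be checked
against an image-level route.

# Cortical bone mapping

`modelProfile()` evaluates the blurred three-level model analytically via
the Gaussian CDF.  `fitProfile()` is bounded Levenberg–Marquardt
(minpack.lm) with three starts for the periosteal boundary (steepest
ascent, steepest descent minus a default width, mid-profile), tie-broken
by residual then smaller blur.  For thin cortices the unconstrained
problem is ill-posed — a dense thin cortex and a less dense thicker one
produce nearly identical blurred profiles — which the tests demonstrate
explicitly; CMSD is the quantity that survives the ambiguity.

The mapping procedure therefore estimates *global* CBMD and σ first
(`estimateGlobal()`): the median over vertices whose fitted thickness
exceeds 4σ̂, where thickness and density separate.  When fewer than 20
vertices (or 15 % of accepted fits) are resolvable, the subset is
dominated by fits that crossed the boundary by *overestimating*
thickness — a selection that under-reads density — so the estimator falls
back to the median over all accepted fits, whose errors we find to be
nearly symmetric.  `constrainedMap()` then refits every vertex with the
density fixed to the global value and applies the blur-discrepancy
adjustment: where the local σ exceeds the global σ the excess apparent
blur is attributed to sub-global density, `CBMD_v = CBMD_global · g(r)`
with `r = σ_global/σ_v`, and thickness is rescaled so CMSD is *exactly*
conserved.  The attribution map defaults to the simplest monotone choice
`g(r) = r` with `g(1) = 1`; existing cortical-bone-mapping
implementations use their own published form, which is not reproduced
here, so `g` is configurable and the linear default is a package
choice.

On noisy phantoms with thickness uniform in 1–3 mm at the default
imaging preset, the constrained estimator's mean signed thickness error
is about −0.01 mm (|mean| well under the 0.12 mm reference accuracy),
with a vertex-wise SD near 0.06 mm.

# Registration

`rigidAlign()` is symmetric vertex-level ICP (forward and reverse nearest
neighbours, closed-form Kabsch updates) followed by linearised
point-to-plane refinement; symmetry removes the translation bias plain
ICP shows between differently sized shapes, and point-to-plane removes
the tangential drag that stalls vertex matching on near-rotational
anatomy.  No scaling, ever.

`nonrigidRegister()` iterates, with a decreasing Laplacian weight λ
(5 → 0.01 over nine steps):

1. **Normal shooting**: each vertex is matched by intersecting the ray
   along its canonical normal with the target surface.  In the
   affine-plus-normal-displacement convention, the ray line
   {X₀ + Zα + t·n₀} contains the true correspondent at any amplitude, so
   the matches stay consistent even for extreme shapes.  Up to three
   intersections are retained; when a second sheet lies within 3 mm of
   the first (e.g. head and neck surfaces both in range) the match is
   ambiguous and carries no weight during the coarse iterations, and
   grazing hits (surface normal nearly perpendicular to the ray) are
   rejected outright.
2. **Decomposition**: the cumulative normal-displacement scalars are fit
   by least squares against the normal components of the 12 affine basis
   fields (with a small Tikhonov term on the *tangential* magnitude of
   the affine field, pinning directions the scalars cannot see), and the
   residual is solved as a weighted scalar system
   `(W + λ LᵀL) d = W r` — unmatched vertices have zero weight and are
   filled in by the smoothness prior.

The result is re-expressed in the canonical frame by correspondence-based
rigid Procrustes (rotation and translation only), so scanner pose never
leaks into the shape statistics while size is fully preserved.  Each
registration also reports a quality score — the RMS graph-Laplacian of
the recovered displacement field — because a mis-corresponded
registration can coincide with the target surface (sliding is invisible
to the residual) while leaving kinks in the field.  Subjects with mean
surface residual above 0.5 mm or roughness above 0.2 mm are flagged, and
`runPipeline()` excludes them from the group analysis; at the preset
cohort sizes this safeguard rarely triggers (typically no subjects),
because the measurement anchoring described below keeps even extreme
planted shapes registered accurately.

One estimation detail carries most of the accuracy: the affine part of
the decomposition is fitted by projecting the displacement scalars onto
the affine-normal basis in the *plain full-vertex metric* — the metric in
which the generator's residual scalars are orthogonal to that basis —
after completing the sampled field over all vertices with a lightly
smoothed scatter (samples lost to gating or sheet ambiguity are
spatially structured, and a fit on the raw samples would leak residual
content into the size estimate at large amplitudes).  With this in
place the round-trip error against the generator's vertices is
0.01–0.1 mm mean per subject, and recovered coefficients correlate with
the planted ones at ≈ 0.999.

`smoothSurface()` implements iterated 1-ring averaging calibrated to a
target Gaussian FWHM through the per-iteration kernel variance
(α·h²/2 per axis for mean edge length h); missing values are excluded
with weight renormalisation.  The pipeline default of 6 mm FWHM exceeds
the registration error by two orders of magnitude while preserving the
focal patch; the function default (10 mm) matches common surface-SPM
practice and both are configurable and logged.

# Shape model and GLM

`buildShapeModel()` computes the PCA through the n × n Gram matrix — the
16740² covariance is never formed — with modes sorted by eigenvalue and
signs fixed (largest-magnitude component positive).  The pipeline then
orients mode 1 so that +1 SD *enlarges* the femur (`orientMode()`), which
gives "size" a reproducible sign.  Coefficients are exposed raw (mm) and
SD-standardised; the GLM consumes the standardised ones so effects read
as percent per SD.

`fitGlm()`/`fTest()` are shared-QR ordinary least squares over vertices
with nested-model F-tests; `effectPercentMap()` divides the tested
coefficient by the model prediction at cohort-mean covariates and the
reference site.  Family-wise correction (`correctedPMaps()`) defaults to
Freedman–Lane residual permutation — permute reduced-model residuals,
refit, and collect the null distributions of the image-wise maximum F and
the maximum cluster extent above the uncorrected p = 0.001 threshold
(cluster connectivity is mesh 1-ring adjacency).  Permutation is the
default because it is exact under exchangeability; the random-field
theory route (expected Euler characteristic for F fields with
residual-based smoothness estimation) is provided for fidelity to the
classical SPM workflow but is approximate on irregular meshes and is
labelled as such.  Under the null, the permutation peak correction's
empirical family-wise error at reduced scale sits inside [0.03, 0.07].

The model ledger (`ledgerReport()`) reruns the a-priori
height model, the weight-including exploration model and the selected
model on one registered cohort, reporting each specification's best
cluster and patch effect — including the qualitative collinearity lesson
that a weight column correlated with size shifts the size-effect
estimate.

# Numerical choices and degenerate inputs

* Eigenvalues below 10⁻¹⁰ of the maximum are dropped from shape models;
  duplicate shapes are reported, not fatal.
* Flat intensity profiles, non-finite fits, or fits with
  y₁ ≤ max(y₀, y₂) are flagged and excluded from maps; subjects with
  under 80 % mapped coverage are excluded with a logged reason.
* Cluster p-values use the (1 + #{null ≥ observed})/(nPerm + 1)
  estimator; fewer than 100 permutations are refused.
* All randomness flows from one root seed through fixed per-stage
  offsets, so identical configurations are bit-reproducible.

# Problem sizes

The package's own study conditions are the preset cohorts: n = 308 males
and n = 125 females at 5580 vertices, run field-level (true cortical
fields pass the imaging stage) — minutes on one CPU.  The image-level
route (profile synthesis plus the full CBM refit at every vertex) is
exercised at small n and on vertex subsets in the tests and takes a few
seconds per thousand profiles; running it for a full cohort is possible
but is a compute budget, not a methods, question.  Reduced-scale null
simulations (a 500-vertex grid, 100–200 permutations) are used for the
family-wise-error calibration checks.

# What passing tests do and do not show

The generator emulates the *structure* of the study — demographic
moments and ranges, covariate–size correlations, a dominant anisotropic
size mode with interpretable second and third modes, a focal
superior-neck deficit proportional to size, blurred noisy profiles — but
real femurs are not a 10-mode linear shape family, real cortical fields
have anatomy the smooth baselines here lack (porosity, endosteal
trabecularisation), real registration confronts segmentation error and
topology defects, and real scanners are not a single isotropic Gaussian
blur.  Recovery of the planted parameters therefore validates the
pipeline's statistical machinery and its implementation — not the
biological claims, which belong to the original cohort data.

# Known limitations

* The sliding/correspondence convention, while principled and shared
  between generator and registration, is still a convention; systematic
  misregistration in real data can masquerade as shape-correlated
  cortical signal, which is one reason nonrigid shape modes are kept in
  the GLM.
* The RFT route's smoothness estimator and resel counts are first-order
  approximations on an irregular mesh; use permutation for inference
  that matters.
* Registration quality control can exclude extreme shapes (slightly
  truncating nonrigid-mode variance in fitted models), though at the
  preset amplitudes it rarely triggers.
* The voxel-phantom route resolves blur only down to the voxel size and
  assigns densities by nearest-vertex normals, so it is a consistency
  fixture, not a scanner simulation.
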