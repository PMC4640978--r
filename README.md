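# boneSPM

Cortical bone mapping, statistical shape modelling and surface-based
statistical parametric mapping (SPM) of the proximal femur, in R.

## The scientific problem

Hip-fracture risk is associated with femur size, but classical hip
structure analysis works with correlated geometric measures (neck width,
axis lengths, neck-shaft angle) that are hard to interpret jointly.  An
alternative: parameterise femoral size and shape along *orthogonal*
directions from a principal component analysis of the population, and
ask — vertex by vertex over the whole proximal femoral surface — whether
the cortex depends on the size coefficient, allowing for age, nonrigid
shape and scanning site.  The outcome of interest is the cortical mass
surface density

> CMSD = CTh × CBMD  (mg/cm²),

the product of cortical thickness (cm) and cortical bone mineral density
(mg/cm³), estimated at thousands of surface locations by *cortical bone
mapping*: fitting a blur-aware three-level density model

> y(x) = y₀ + (y₁ − y₀) Φ((x − x₀)/σ) + (y₂ − y₁) Φ((x − x₁)/σ)

to CT-style intensity profiles sampled along surface normals, with a
global-then-local constrained strategy that resolves the thin-cortex
thickness–density ambiguity.  Per-vertex data are transferred to a
canonical femur surface (5580 vertices) by rigid plus regularised
nonrigid registration, smoothed, and analysed with the vertex-wise GLM

> CMSD ~ 1 + S₀ + Age + S₁…S₅ + Site,

where S₀ is the size mode of the point-distribution shape model
(Sᵢ = (X − X̄)·mᵢ over the 16740-element registered coordinate vectors).
An F-test on S₀ with family-wise-corrected p-values (Freedman–Lane
permutation by default; approximate random-field theory optionally)
localises size-dependent regions, and effects are quantified as percent
change per SD of S₀ within a frozen femoral neck patch.

Because the QCT cohorts behind this design are not redistributable, the
package ships a first-class synthetic cohort generator that plants every
quantity of interest — demographics with realistic correlations to size,
a dominant anisotropic size mode (≈7 %/SD proximal–distal), neck-angle
and neck-length modes, a focal superior-neck CMSD deficit proportional
to size, and blurred noisy intensity profiles — so the entire pipeline
runs and is validated end to end as a parameter-recovery exercise.  The
intended users are researchers in skeletal imaging and morphometry who
want a tested, self-contained reference implementation of this analysis
chain.

## A worked example

A reduced male-preset cohort (n = 60), field-level route, one command:

```r
library(boneSPM)
run <- runPipeline(runConfig(preset = "male", n = 60, seed = 1))

run$patchStats
#>   outcome  effectPerSD
#> 1    cmsd -6.590355947
#> 2     cth -6.583393621
#> 3    cbmd -0.006395402

run$model
#> ShapeModel: 60 subjects, 59 modes over 16740 coordinates
#>   variance fractions (%): 53.8 19.0 7.4 4.9 3.9 ...

round(modeExtentChange(run$model, 1, "proximalDistal"), 2)
#> [1] 6.16
round(cor(run$cohort$height, scores(run$model, standardized = TRUE)[, 1]), 3)
#> [1] 0.556
```

Reading the output: within the frozen femoral neck patch the fitted GLM
attributes a 6.6 % CMSD decrease per SD of femur size — carried almost
entirely by thickness (CTh −6.6 %/SD) with density essentially flat —
recovering the planted −6.87 %/SD deficit up to the sampling noise of a
small cohort.  The first shape mode explains ~54 % of the coordinate
variance, changes the proximal–distal extent by ~6.2 % per SD, and
correlates ~0.56 with body height.  At the full preset sizes (n = 308
males, n = 125 females) these recoveries tighten to the planted values;
that is what the acceptance script below measures.

`run$se` is a `SummarizedExperiment` (vertices × subjects; assays cmsd,
cth, cbmd; colData = demographics plus estimated shape coefficients),
`run$spm$cmsd` holds the per-vertex GLM with F- and effect maps, and
`correctedPMaps()`, `extractClusterPatch()` and `ledgerReport()` take it
from there.  Surfaces and overlays can be written as ASCII PLY/VTK, the
cohort and cluster tables as CSV, and a voxel phantom as NIfTI.

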