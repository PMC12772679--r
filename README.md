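# autofif

Automated field-in-field (FiF) planning support for whole-brain radiotherapy
(WBRT), for medical-physics researchers and developers of treatment-planning
automation. WBRT is delivered with two lateral parallel-opposed beams; modern
treatment planning systems (TPS) offer an *Auto-FiF* function that adds
MLC-shaped subfields to suppress hotspots, but its hyperparameters — target
coverage priority, number of subfields, minimum segment MU per fraction and
minimum segment area — must still be chosen per patient, and suboptimal
plans still need a manual critique-and-replan cycle.

`autofif` implements that whole loop as testable, offline R code:

1. **Geometry features.** From a structure set (brain CTV, both eyes, both
   lenses, plus the isocenter) it computes 21 geometric features — volume
   *V*, surface area *A* and maximum Feret diameter *D* of each organ,
   centroid-to-centroid distances, isocenter distances, and the polar /
   azimuthal angles (θ, φ) of each organ centroid seen from the isocenter —
   with lateral left/right pairs averaged. A 10-feature subset (the organ
   diameters, isocenter distances and ocular angles) is the shipped default;
   an agglomerative-clustering + iterative dendrogram-cut selection engine
   can re-derive subsets on new cohorts.
2. **Hyperparameter prediction.** Three small fully connected classifier
   heads map the standardized features to the Auto-FiF settings: coverage
   priority (4 classes, 25–100 % in 25 % steps), number of subfields
   (3 classes), and a joint (MU, area) label over the four clinical
   combinations (2, 4), (4, 6), (6, 9), (8, 10). Training: 1500 epochs,
   batch size 5, Adam, cross-entropy, dropout 35 % (head A) or 10 %/15 %
   (heads B/C), early stopping on validation loss. Integrated-gradients
   attribution (with the completeness axiom verified per report) explains
   every prediction.
3. **Plan evaluation.** DVH metrics — D1 %, D95 %, D99 % for the CTV and
   mean dose for each eye and lens — with D95 % normalization for fair
   comparison, paired t-tests across cohorts, and a grid-search labeler
   that recovers the hyperparameters that best reproduce a reference plan.
4. **Conversational refinement.** A plan critique ("the target coverage is
   poor") is interpreted into structured feedback, mapped to quantitative
   objectives (raise D95 % or D99 % by ≥ 5 %, lower named OAR means by
   ≥ 5 %, never worsen anything else by > 2 %), and resolved by a staged
   localized grid search over coverage priority, then (priority, subfields),
   with a bit-exact revert fallback.

Because clinical TPS backends are proprietary, the package ships a
**surrogate plan engine** — a synthetic, seeded dose model behind a
`TpsAdapter` interface — that reproduces the qualitative dose behaviour of
FiF planning (hotspot suppression by subfields, the coverage-versus-sparing
trade-off, homogeneity coarsening with larger segment limits). It exists to
make the pipeline's logic testable; it is not a dose calculation. A
`synthetic anatomy` module generates plausible phantoms (ellipsoidal brain,
spherical eyes/lenses) and labeled datasets so everything runs with no
clinical data.

## Worked example

```r
library(autofif)

# a labeled synthetic cohort and trained models
ds <- generateLabeledDataset(120, noise = 0, seed = 7)
models <- runTrain(ds, file.path(tempdir(), "models"), seed = 7)

# one-click planning for a new case
casePath <- file.path(tempdir(), "case.txt")
saveFixture(generatePhantom(randomPhantomSpec(31)), casePath)
run <- file.path(tempdir(), "run1")
res <- runAutoplan(casePath, file.path(tempdir(), "models"), run, seed = 4)
res$hyperparameters
#> AutoFifHyperparameters: priority 50%, 2 subfield(s), min MU 8, min area 10 cm^2
#> (leaf pairs 1, end sep 0 cm)
round(res$metrics, 2)
#>  D1_BRAIN_CTV D95_BRAIN_CTV D99_BRAIN_CTV    Mean_EYE_L    Mean_EYE_R
#>         35.83         27.87         27.42         13.34         13.32
#>   Mean_LENS_L   Mean_LENS_R
#>         12.53         12.51

# conversational refinement
fb <- runFeedback(run, "The target coverage is poor.")
fb$outcome
#> [1] "refined"
fb$hyperparameters
#> AutoFifHyperparameters: priority 75%, 2 subfield(s), min MU 8, min area 10 cm^2
#> (leaf pairs 1, end sep 0 cm)
round(dvhMetrics(fb$plan), 2)
#>  D1_BRAIN_CTV D95_BRAIN_CTV D99_BRAIN_CTV    Mean_EYE_L    Mean_EYE_R
#>         35.99         29.60         29.35         13.55         13.53
#>   Mean_LENS_L   Mean_LENS_R
#>         12.73         12.71
```

The critique raised only the coverage priority (50 % → 75 %); CTV D95 %
rose from 27.87 to 29.60 Gy (+6.2 %, satisfying the ≥ 5 % objective) while
the eye and lens mean doses moved by under 2 % — the guard band for metrics
the physician did not mention. An eyes-too-high critique instead leaves
priority alone and adds a third subfield, cutting the eye means by ~6 %.

A command-line front end with `make-fixtures`, `train`, `autoplan`,
`feedback` and `evaluate` subcommands is installed at
`system.file("cli", "autofif.R", package = "autofif")`.

Structure sets load from DICOM RTSTRUCT (`loadRTStruct()`, with a
configurable ROI-name → role pattern map) or from a plain-text fixture
format (`loadFixture()` / `saveFixture()`), always in LPS millimetre
coordinates.

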