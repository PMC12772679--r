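---
title: "Methods: geometric hyperparameter prediction and conversational plan refinement for WBRT field-in-field planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric hyperparameter prediction and conversational plan refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and design decisions behind
`autofif`. It is the companion to the README's worked example: everything
quantitative stated here is recomputed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The problem

Whole-brain radiotherapy uses two lateral parallel-opposed beams; a
treatment planning system's Auto-FiF function then adds MLC-shaped
subfields that block dose hotspots. Four of its hyperparameters dominate
plan quality and are chosen per patient: target coverage priority (25, 50,
75, 100 %), number of subfields (1–3), minimum segment MU per fraction
(2, 4, 6, 8) and minimum segment area (4, 6, 9, 10 cm²); two further
settings are fixed (one open leaf pair, 0 cm leaf end separation).
`autofif` predicts the four settings from the case's geometry, evaluates
the resulting plan through DVH metrics, and converts a physician's
free-text critique into a localized re-search over the two settings that
control coverage and hotspots.

## Coordinates, units and structures

All structure geometry lives in DICOM LPS patient coordinates (+x left,
+y posterior, +z superior) in millimetres, as contour-vertex point clouds —
the native RTSTRUCT layout; no voxel indexing happens at the I/O layer. A
plannable case carries five roles (`BRAIN_CTV`, `EYE_L`, `EYE_R`, `LENS_L`,
`LENS_R`) plus an isocenter; when no isocenter is available the brain
centroid is used, with a warning, because lateral-opposed WBRT beams are
conventionally isocentered in the brain. Features are reported in cm, cm²,
cm³ and radians regardless of the millimetre input: a single unit system
prevents silent scale errors.

## The 21 geometric features

Per organ (brain, eye, lens after lateral averaging): volume, surface area
and diameter (9 values); centroid-to-centroid distances brain–eye,
brain–lens, eye–lens (3); isocenter-to-centroid distances (3); and the
polar and azimuthal angles of each organ centroid seen from the isocenter
(6) — 21 in total. Conventions chosen here and frozen:

* **Diameter** is the maximum Feret diameter (largest pairwise distance) —
  unambiguous and verifiable against a brute-force O(n²) oracle, which the
  tests do. Candidate points are first reduced to per-slice 2-D convex-hull
  vertices; the extreme pair always survives that reduction.
* **Angles**: polar from the superior (+z) axis, azimuth `atan2(y, x)` in
  the axial plane. When the isocenter coincides with an organ centroid the
  direction is undefined and both angles are reported as 0 rather than
  failing (the common "isocenter at brain centroid" configuration).
* **Lateral averaging** is arithmetic; the eye–lens distance pairs the
  same-side eye with the same-side lens before averaging. Whether the
  original workflow averaged same-side or crossed pairs is not documented
  anywhere we could rely on; same-side is the anatomically natural reading
  and is stated here so it can be changed knowingly.
* **Volume and surface area** are computed by per-slice convex-hull
  integration: slab volumes (midpoint rule over the contour planes, end
  slabs extending inward only, which is exact on prisms) and frustum
  lateral areas with the two end caps. On a 3 cm-radius sphere sampled at
  4000 points this is within 0.2 % (volume) and 0.3 % (area) of the closed
  forms; a 2×3×4 cm box is exact. Naive voxel-face counting was rejected
  because it overestimates curved surfaces by up to 50 %. The convexity
  assumption is per-slice only, adequate for brain/eye/lens cross-sections.

The shipped selected subset is the 10 features used by the classifier
heads: the three diameters, three isocenter distances, and the ocular
polar/azimuthal angles. A selection engine (standardized features,
Euclidean distance, agglomerative clustering, default average linkage,
threshold schedule = the sorted unique merge heights descending, cluster
representative = best single-feature evaluator score with name-order tie
break) reproduces the procedure on new cohorts. A candidate subset replaces
the current one only when the user-supplied cross-validation evaluator
improves strictly (tolerance 1e-6), so the final subset never scores below
the full set; with a constant evaluator the full set is returned unchanged.
Linkage, schedule and representative rule are configurable because none of
them is canonical.

## Classifier heads and training recipe

Head A (coverage priority, 4 classes): `FC(32) → LeakyReLU → dropout 0.35 →
FC(16) → ReLU → FC(4)`. Heads B (subfields, 3 classes) and C (joint
(MU, area) label over the four clinical combinations, 4 classes) share one
backbone architecture: `FC(32) → LeakyReLU → dropout 0.10 → FC(16) → ReLU →
dropout 0.15 → FC(K)`; C reuses B's architecture settings, never its
weights. Hidden widths 32 → 16 are a deliberate small-capacity default for
cohorts of tens to hundreds of cases and are configurable.

Training: minibatch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), batch size 5,
up to 1500 epochs, cross-entropy loss; learning rate and weight decay
2e-4/2e-4 for head A and 1e-3/9e-5 for heads B and C; weight decay enters
as an L2 term added to the gradient. Early stopping monitors the loss on a
stratified 20 % validation split with patience 100 epochs and best-weights
restore; the patience and split are our choices — only the monitored signal
(validation loss) is given by the recipe. He-uniform initialisation;
inverted dropout. All randomness (init, shuffling, dropout masks, splits)
derives from one seed through an isolated RNG stream, so identical calls
are bit-identical and never disturb the caller's RNG. Class orderings are
frozen ascending (25/50/75/100; 1/2/3; (2,4)/(4,6)/(6,9)/(8,10)), which
removes a silent label-permutation bug class; `encode`/`decode` round-trip
over all 4 × 3 × 4 = 48 combinations is asserted in the tests.

Cross-validation is stratified k-fold (default 5) with standardization
refit inside each training fold — the leakage-safe choice. Metrics are
per-class precision/recall/F1, macro-averaged unweighted; classes absent
from the truth are excluded with a warning, and a never-predicted class
contributes precision 0.

## Integrated gradients

Attributions integrate the gradient of the predicted class's logit along
the straight path from a baseline to the input. The default baseline is the
all-zeros standardized vector — the cohort mean in raw feature space. These
networks are piecewise linear, so the path derivative is piecewise
constant; a uniform Riemann sum stalls at activation-kink crossings with an
O(1/steps) error that can exceed 1e-3 on sharply trained heads. The
quadrature therefore splits the path exactly at the kink alphas (found
layer by layer; within a segment every pre-activation is linear, so
crossings interpolate exactly) before applying the midpoint rule, making
the sum exact to floating point: completeness residuals
|Σ attributions − (f(x) − f(baseline))| are ~1e-13 in practice and are
reported in every attribution object. Feature rankings use mean absolute
attribution with canonical name-order tie-breaks.

## The surrogate plan engine

The proprietary Auto-FiF implementation is replaced by a synthetic dose
model behind the `TpsAdapter` interface (`generatePlan(s, h, prescription,
seed)`, plus optional context reuse for grid searches); substituting a real
TPS backend touches nothing else. The surrogate samples dose at the voxel
centers of each structure (global 2 mm isotropic lattice by default) and is
engineered to honour, by construction, the qualitative behaviour the
pipeline's logic depends on. With `P` the prescription, `f` the coverage
priority fraction, `w = exp(−depth/15 mm)` the CTV boundary weight and `g`
a seeded sum of three Gaussian hotspot bumps deep in the CTV:

* CTV base dose `P·(1.06 − 0.30·w + 0.28·f·w + g)` — a peripheral droop
  that coverage priority lifts (~6–8 % D95 per 25-point step);
* each subfield k ≤ n compresses the excess above the 97th/93rd/89th
  base-dose percentile by a retention factor `β = 0.25 + 0.045·s`, where
  `s ∈ 0..15` indexes (MU, area) fineness — so D1 % is pointwise
  non-increasing in n, and D1 % − D99 % is non-decreasing in the combo
  index;
* OAR dose `P·exp(−gap/80 mm)·(0.60 + 0.04·f)·(1 − 0.06·(n − 1))` — mean
  eye/lens dose rises ~1.6 % per priority step and falls ~6 % per added
  subfield.

The constants were fixed once so that a single priority step clears the
≥ 5 % coverage objective while staying inside the 2 % OAR guard, and a
single added subfield clears the ≥ 5 % OAR objective — the regimes the
refinement loop must distinguish. The tests assert the four monotonicities
on a 5-phantom × 4-seed panel (20 contexts; a denser panel adds runtime
but no information, since the monotonicities hold pointwise by
construction). The surrogate is labeled `surrogate-fif` in every output and
makes no claim of dosimetric realism: no beam model, no MLC sequencing, no
deliverability.

## DVH metrics, normalization, comparison and labeling

`Dx%` is the largest dose received by at least x % of the structure volume:
the left-continuous (type-4) interpolated order statistic of the voxel
doses at probability 1 − x/100, which reduces to the exact sort-and-count
answer at the order statistics (a two-voxel structure with doses 10 and
20 Gy has D95 % = 10, not an average). Tests pin it to an independent
hand-written sort-based oracle at 1e-9. D95 % normalization is a uniform
rescale — exact, linear in all other metrics, idempotent. Paired plan
cohorts are compared with two-sided paired t-tests at α = 0.05;
zero-variance differences return p = 1 with a degenerate flag instead of
NaN, keeping pipelines stable.

Ground-truth labeling reproduces a reference plan by exhaustive grid search
(full grid 4 × 3 × 4 × 4 = 192 configurations; restricted grid with the 4
clinical combos = 48). The similarity score — our choice, since no
canonical one exists — is the equal-weight L1 distance over the evaluation
metric set (|ΔD1| + |ΔD99| for the CTV plus Σ|Δmean| over the four OARs)
after normalizing the candidate to the reference D95 %; ties break toward
fewer subfields, then lower priority, then lower (MU, area) fineness. In
the closed loop (reference generated by the surrogate at known settings)
recovery is exact with score 0, which the tests and the acceptance script
verify on 10 phantoms.

## The conversation loop

The default interpreter is rule-based and deterministic: sentences naming
the target/coverage are scored for negative versus positive sentiment
(with negation handling), sentences naming eyes/lenses for elevated-dose
language, and left/right qualifiers resolve to roles. An LLM backend with
the same interface wraps any chat-completion callback with the shipped
few-shot exemplars, temperature 0.2 and schema validation (one retry, then
an error carrying the raw output); recorded-response callbacks make it
testable offline. The feedback schema is the minimal one consistent with
the workflow — `target_coverage` ∈ {good, bad, unchanged}, `oar_dose` ∈
{good, high, unchanged}, optional `oar_roles` — and both spaced and
snake_case key spellings are accepted on input.

Objectives: coverage bad → D95 % or D99 % must rise ≥ 5 % over the initial
plan (either suffices); OAR high → each named OAR mean must fall ≥ 5 % (the
same threshold reused symmetrically, configurable); every metric not named
by a goal is guarded against worsening by more than 2 % relative. The
staged search tries coverage priority alone first (ascending from the
initial value for coverage goals, descending for OAR goals; ≤ 3 new
configurations), then (priority, subfields) jointly ordered by perturbation
size with goal-directed tie-breaks (≤ 11 more); the first configuration
meeting all goals and guards wins, and failure reverts bit-exactly to the
initial plan. "Satisfactory" = all active goals met and no guard violated —
the weakest reading that still forbids silent trade-offs. Transcription is
a pluggable backend; the shipped passthrough accepts text, and audio
capture is deliberately outside the package.

## Synthetic anatomy and labeled datasets

Phantoms are ellipsoidal brains with spherical eyes and lenses placed
anterior–inferior–lateral, built as axial contour rings; equator rings with
point counts divisible by four make each organ's Feret diameter exactly its
analytic diameter. Population ranges (documented constants, not fitted to
any cohort): brain antero-posterior diameter 14–18.8 cm, eye diameter
2.2–2.6 cm, lens diameter 0.8–1.1 cm, isocenter within 5 mm of the brain
centroid, right-side asymmetry jitter up to 3 %. Zero jitter gives exact
mirror symmetry, which the symmetry-averaging tests exploit.

Labels follow a deterministic monotone rule on measured features chosen
from among the selected ten, so that planted-feature recovery and
attribution ranking are testable end to end: coverage priority rises as the
eyes approach the isocenter (Eye_Iso quartiles), subfields rise with brain
diameter (terciles), and the (MU, area) combo follows the lens-diameter
quartile. Thresholds are frozen population quantiles (estimated once from
1500 draws of the default ranges). Cases whose rule feature falls within a
small guard band of a threshold (0.08 cm for Eye_Iso, 0.15 cm for brain
diameter, 0.012 cm for lens diameter; ~15–20 % of draws) are redrawn
deterministically: a boundary case's label is unresolvable at any training
size and measures nothing about parameter recovery. Optional label noise
flips each head's label independently to a uniformly drawn different
class. The closed-loop generator instead draws labels uniformly from the
48 restricted combinations and stores surrogate reference plans.

What the generator does **not** emulate: real cortical anatomy, contour
noise and inter-observer variability, CT intensities, correlated
label-assignment ambiguity, or class imbalance resembling any clinic's
case mix. Passing the recovery tests therefore demonstrates that the
pipeline's machinery — features, training recipe, selection, labeling,
refinement — works as specified, not that clinical performance would match.

## Problem sizes and runtime choices

The shipped checks use sizes that keep a full run in minutes on one CPU:
200-case cohorts for 5-fold parameter recovery (macro F1 ≥ 0.85 per head is
the acceptance bar; typical values are 0.90–0.96), 10 phantoms for
closed-loop label recovery on the full 192-configuration grid at 2 mm
voxels, 20-context panels for the dose-model monotonicities, and 256-step
attribution quadrature. Larger sizes change none of the conclusions, only
the wait.

## Known limitations

* The surrogate engine's dose scale is qualitative; absolute OAR doses are
  not calibrated to any machine or technique.
* Volume/area integration assumes per-slice convexity; strongly concave
  cross-sections would be overestimated.
* The rule-based interpreter covers the critique patterns of this workflow
  (coverage and ocular dose); arbitrary free-text plan editing is out of
  scope, as is dialogue memory across sessions.
* Whether angles should be degrees or radians in the original modeling is
  moot after standardization but matters for any attempt to port trained
  checkpoints; this package is radians throughout.
* The fixture text format stores coordinates at full double precision; it
  is a test/interchange format, not an archival replacement for RTSTRUCT.
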