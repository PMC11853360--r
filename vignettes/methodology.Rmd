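---
title: "Quantifying FDG muscle uptake with fixed and hotspot VOIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FDG muscle uptake with fixed and hotspot VOIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgmuscle)
library(dplyr)
```

## The problem

Whole-body [18F]-FDG PET/CT visualizes glucose metabolism, and pathologically
increased muscle uptake is seen in rheumatic musculoskeletal diseases (RMDs):
rheumatoid arthritis (RA), osteoarthritis (OA), and idiopathic inflammatory
myopathy (IIM). Quantifying that uptake requires choosing where to read the
signal. Two procedures are in common use:

* **fixed VOI** — a sphere at a predefined anatomical position (half-way
  along the bone axis; the upper humerus for the deltoid; the lumbosacral
  L5–S1 junction for the psoas), blind to the actual uptake distribution;
* **hotspot VOI** — a sphere at the visually hottest spot, guarded by a
  consecutive-slice check so that a single-slice coincidence is never read
  as a lesion.

When uptake is spatially heterogeneous — and in the quadriceps and
hamstrings it almost always is — the two disagree systematically: the fixed
position can miss focal disease, so hotspot readings run higher. This
package implements both procedures, the body-weight SUV conversion and
SUVpeak statistic they feed, an automated analog of visual
positivity/pattern scoring, and the statistical battery used to compare
methods and patient groups. Because no patient images are available, every
stage is verified against a **digital phantom generator** with known ground
truth.

## The phantom

`muscle_atlas()` builds a stylized whole body on a regular voxel grid
(default 48 × 32 × 100 voxels at 4 mm — a typical reconstructed PET grid;
coarse enough that the full study runs in seconds, fine enough to resolve
10–20 mm VOIs). Twelve compartments (deltoid, biceps, triceps, psoas,
quadriceps, hamstrings; left/right mirror images about the midsagittal
plane) are cylinders on a torso-and-limbs layout. The geometry is
deliberately *not* anatomically faithful: only the topology the VOI rules
need is guaranteed — bone-axis landmarks, a mediastinal blood-pool
compartment (the positivity reference), and vessels, including a femoral
rod carved through each quadriceps so that vessel avoidance is actually
exercised.

`generate_phantom()` works in SUV space and inverts the SUV equation to get
activity: per muscle, uptake is `baseline × group multiplier` plus focal
lesions; then `C = SUV · D / W` (kBq/mL), a Gaussian point-spread blur, and
activity-proportional Gaussian noise (variance = coefficient × activity,
clipped at zero — a simple stand-in for post-reconstruction PET noise).
Ground truth (pattern class, focus centers, pre-blur maximum SUV) is
recorded before blur and noise, so it defines the recovery target
unambiguously.

**Focus model.** A focus is a spherical plateau at `0.8 × amplitude` with a
single-voxel core at the full amplitude. The plateau makes the lesion
visible on the neighbouring axial slices (like a partial-volume-tapered
lesion, and necessary for any consecutive-slice rule to accept it); the
core gives each focus a unique maximum exactly equal to
`baseline + amplitude` at the recorded center, which is what makes "did the
hotspot land on the lesion?" a well-posed question. Unifocal and multifocal
foci keep two radii of separation where the compartment allows it; focus
centers keep a VOI radius of clearance from boundaries and vessels so that
both procedures can legitimately measure any lesion.

**Cohort conditions** (`cohort_config()` defaults, chosen once):

| parameter | default | rationale |
|---|---|---|
| group sizes | 8 / 11 / 10 / 10 | control / RA / OA / IIM cohort sizes |
| multipliers | 1.0 / 1.1 / 1.4 / 2.0 | RA slight, OA moderate, IIM ~2-fold uptake elevation |
| baseline SUV | 0.8 (SD 0.05 between subjects) | resting skeletal muscle |
| blood pool SUV | 1.5 | mediastinal positivity reference |
| weight / dose | N(75, 12) kg clipped to [45, 120]; 3.5 MBq/kg | typical adult FDG protocol |
| PSF FWHM | 6 mm | clinical whole-body PET resolution |
| noise coefficient | 0.05 | ≈ 0.1 SUV noise SD at typical dose/weight |
| P(heterogeneous), thigh | 0.75 / 1 / 1 / 0.925 | thigh muscles almost always heterogeneous |
| P(heterogeneous), other | 0.15 / 0.65 / 0.55 / 0.65 | controls mostly homogeneous elsewhere |
| subtype mix | unifocal 0.3 / multifocal 0.5 / diffuse 0.2 | plausible mix; no published breakdown |
| focus radius | 15 mm thigh, 8 mm other; amplitude 1.8 (diffuse 0.75) | lesions large enough to be confirmable on adjacent slices and to dominate the compartment CV |

What the phantom does **not** emulate: real anatomy, attenuation/scatter
artefacts, axially varying noise from different per-bed acquisition times,
respiratory motion, or inter-reader variability. Passing tests therefore
demonstrate that the *pipeline* recovers known truth under its stated
model, not that the classifier thresholds are clinically validated.

## SUV and SUVpeak

`to_suv()` applies the body-weight convention `SUV = C · W / D` with C in
kBq/mL, W in kg, D in MBq; units cancel under the 1 g/mL tissue-density
assumption. Sphere membership is by voxel-center inclusion with no
partial-volume weighting — reproducible and bit-exact.

`suv_stats()` reports `suv_max`, `suv_mean` and `suv_peak`. SUVpeak is the
noise-robust alternative to the single hottest voxel: a small kernel sphere
(default 12 mm ≈ 1 mL, the common convention) is positioned at every VOI
voxel where it fits **entirely inside the VOI**, and the largest enclosed
mean is reported. Keeping the kernel inside the VOI has three consequences
we consider essential: `suv_peak ≤ suv_max` holds unconditionally; no
kernel position gains a spurious advantage by averaging a partial sphere
that clips off its cold side; and activity just outside the VOI — say, the
femoral vessel the placement rules deliberately avoided — can never leak
into the peak. For VOIs too small to contain the kernel (the 10 mm spheres
with the 12 mm default), the kernel is centered on the VOI and averaged
over the VOI voxels it covers, which reduces SUVpeak to a compact local
mean; as the kernel diameter shrinks below the voxel pitch, SUVpeak
reduces to SUVmax.

## VOI placement

`place_fixed_voi()` finds the plane orthogonal to the bone axis at the
muscle's rule point (50% of bone length; 10% from the proximal humerus for
the deltoid, a configurable fraction; the L5–S1 plane for the psoas),
starts at the centroid of the muscle cross-section, and moves the minimal
Euclidean distance (ties toward the centroid, then lexicographically) to a
voxel center whose whole sphere is in-muscle and vessel-free. Feasible
centers must project within ±10% of bone length of the target plane;
otherwise a placement-infeasible error names the muscle.

`place_hotspot_voi()` ranks in-muscle voxels by SUV and accepts the first
candidate that passes consecutive-slice confirmation, then adjusts exactly
as above. The confirmation rule quantifies "similar increased uptake on
consecutive slices": `k` nearby axial slices (default 2) must each show an
in-muscle maximum within 15 mm in-plane of at least `τ = 0.8` of the
candidate SUV. The `k` slices may lie entirely before, entirely after, or
split as evenly as possible across the candidate slice. The split window
is our addition to the one-sided reading: in a thin muscle (the deltoid
spans five slices here) a lesion on the middle slice is visible on both
neighbours, yet no two-slice run on one side stays inside it — a one-sided
rule would systematically reject the hottest plane while leaving the fixed
method free to use it, which inverts the methods' intended relationship.
Exact SUV ties among confirmed candidates (routine in noiseless fields
with symmetric lesions) are broken by the SUVpeak the resulting VOI would
measure, then lexicographically, so placement is deterministic and lands
on the hottest *measurable* spot. If nothing is confirmed the global
in-muscle maximum is used with a logged warning — the procedure never
fails on a non-empty muscle.

The search is a single 3D ranking with confirmation along one configurable
axis (axial by default): a 3D maximum dominates any per-plane maximum, and
the confirmation axis preserves the anti-coincidence intent of reviewing
neighbouring slices. The ranked scan is capped (500 candidates) before
falling back to the global maximum; smooth fields confirm within the first
few.

## Qualitative scoring

Visual scoring by blinded readers is replaced by a deterministic statistic,
documented as a stand-in rather than a validated classifier:

* **positivity** — SUVpeak ≥ blood-pool reference (boundary inclusive),
  with the reference read from the phantom's mediastinal compartment mean;
* **pattern** — the coefficient of variation of in-muscle SUV decides
  homogeneous (CV ≤ 0.15) versus heterogeneous; heterogeneous compartments
  are subtyped by 26-connected components of voxels above mean + 2 SD
  (one: unifocal; several: multifocal; none despite high CV: diffuse).
  26-connectivity is robust to diagonal adjacency on coarse grids. The
  thresholds are calibrated against the synthetic cohort: with the default
  focus sizes the CV of every focal compartment clears 0.15 across the
  full multiplier range, while noiseless homogeneous compartments sit at
  CV 0. Under the default noise the classifier over-calls heterogeneity —
  an honest reflection of CV-based scoring on noisy data, and the reason
  recovery claims are made on noiseless cohorts only.

`tabulate_patterns()` aggregates scores per group × muscle × side and
reports the heterogeneous fraction of a muscle subset as a whole-number
percentage; `reference_pattern_counts()` ships a published qualitative
scoring table for checking the aggregation logic (quadriceps + hamstrings:
145/156 = 93%).

## Statistics

The battery mirrors standard practice: Shapiro–Wilk normality per group
and a variance-homogeneity check gate the choice between one-way ANOVA and
Kruskal–Wallis (`normality_gate()`, α = 0.05); the classical two-group
variance-ratio F test is extended to four groups by testing the extreme
pair, with Levene's test available because the classical F test is
ill-defined beyond two groups. Left/right symmetry uses the paired t test;
method agreement uses Pearson and Spearman correlation (both, because both
appear in practice) and Bland–Altman analysis with differences oriented
**fixed − hotspot**, bias ± 1.96 SD limits; group differences use
Kruskal–Wallis with Dunn's tie-corrected post-hoc z tests under Bonferroni
adjustment by default ("none" available, since the adjustment convention
is often unstated). All p-values are two-sided; stars follow *, **, ***
at 0.05, 0.01, 0.001. Shapiro–Wilk, the F test, t tests, correlations,
Kruskal–Wallis and ANOVA delegate to the corresponding base-R tests;
Dunn's test and Bland–Altman are implemented from the standard formulas
and cross-checked against hand and permutation oracles in the test suite.

Note one arithmetic consequence of the gate: with α = 0.05 per check, even
perfectly normal, homoscedastic groups select ANOVA only ≈ 86% of the time
(two groups) — the false-alarm rates of the gate tests compound. The tests
assert calibration accordingly rather than a round 90%.

## The full study

`run_study()` wires everything together: simulate the cohort → quantify
every compartment with both methods → paired-t left/right symmetry and
averaging (averaging proceeds regardless of the symmetry outcome, and a
missing limb falls back to the available side with a flag) → pattern and
positivity scoring → per-muscle and pooled method comparison → gated group
comparison on the left/right-averaged hotspot SUVpeak → ground-truth
recovery metrics. Everything is deterministic given the master seed;
per-subject seeds derive from it. Result tables are tibbles; `tidy()`,
`glance()` and `autoplot()` methods cover the fitted objects, and all
tables can be written as CSV.

```{r study, eval = FALSE}
study <- run_study(study_config(cohort = cohort_config(seed = 1)))
study$method_comparison$summary   # per-muscle and pooled agreement
glance(study$group_tests$psoas)   # gated omnibus for one muscle
autoplot(study$method_comparison$bland_altman$pooled)
```

On the default cohort the expected signatures appear: the pooled
fixed − hotspot bias is negative (the hotspot method reads higher where
uptake is heterogeneous, and exactly zero on homogeneous noiseless
cohorts), the two methods correlate strongly, and the IIM group shows the
highest mean SUVpeak in the psoas, hamstrings and quadriceps with a
significant Kruskal–Wallis result. The test suite quantifies each of these
claims; the acceptance script (`scripts/acceptance.R`) recomputes them
from scratch at a caller-chosen seed.

## Numerical choices and limitations

* Voxel-center sphere membership and lexicographic tie-breaking everywhere
  make every placement bit-reproducible.
* The VOI "size" values of 20 and 10 are interpreted as sphere
  **diameters** in mm. Spheres of 20/10 mm³ volume (diameters ≈ 3.4/2.7 mm)
  could not "capture a representative portion" of a large muscle, so the
  diameter reading is the only self-consistent one; both the values and
  the interpretation are configurable.
* Blur kernels are truncated at 3σ and zero-padded: air outside the body
  contributes nothing.
* The deltoid's "upper part of the humerus" is mapped to 10% of humerus
  length from the proximal end (configurable).
* The psoas landmark follows the L5–S1 junction reading; the alternative
  L5–L1 phrasing that appears in visual-assessment contexts is not used.
* Homogeneous-cohort "equality" of the two methods is exact in SUVmax but
  only near-exact (within ≈ 0.02 SUV here) in SUVpeak: in compartments
  thinner than about twice the PSF width no kernel position escapes the
  edge droop, so the statistic retains a small position dependence.
* Simulation sizes used by the tests — a 39-subject cohort, 20 seeds for
  the sign and ordering properties, 50 phantoms for dominance, 1000
  replicates for the Kruskal–Wallis type-I check — keep the whole suite in
  the minutes range while leaving the binomial margins comfortable.
* The diffuse subtype is the declared weak point of the CV classifier:
  packed overlapping foci can present discrete components or none
  depending on geometry, so no recovery guarantee is claimed for it.
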