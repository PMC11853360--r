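# fdgmuscle

Quantification of skeletal-muscle [18F]-FDG uptake on reconstructed PET
volumes, for researchers studying pathophysiological muscle glucose
metabolism in rheumatic musculoskeletal diseases (rheumatoid arthritis,
osteoarthritis, idiopathic inflammatory myopathy) and for methodologists
comparing VOI-placement strategies.

Muscle FDG uptake is frequently heterogeneous — focal patches rather than a
uniform glow — so *where* you place the volume of interest changes the
number you report. The package implements the two placement procedures in
common use and the machinery to compare them:

* **SUV conversion and SUVpeak.** Body-weight SUV, `SUV = C · W / D`
  (activity concentration C in kBq/mL, weight W in kg, dose D in MBq), and
  SUVpeak: the largest mean enclosed by a ~1 mL kernel sphere positioned
  anywhere inside the VOI — the noise-robust alternative to the hottest
  single voxel (SUVmax).
* **Fixed VOI** at an anatomically fixed plane: 50% of the bone axis
  (biceps, triceps, quadriceps, hamstrings on the humerus/femur), the upper
  humerus for the deltoid, the L5–S1 junction for the psoas; the sphere is
  nudged the minimal distance needed to stay in-muscle and clear of
  vessels.
* **Hotspot VOI** at the maximal-uptake position, guarded against
  single-slice coincidences: nearby axial slices must show similarly
  increased uptake (≥ τ = 0.8 of the candidate within 15 mm in-plane)
  before a candidate is accepted.
* **Qualitative scoring**, automated: positivity against the mediastinal
  blood-pool reference (SUVpeak ≥ reference) and
  homogeneous/heterogeneous pattern classification from the in-muscle
  coefficient of variation, with unifocal/multifocal/diffuse subtypes from
  connected components.
* **Statistics**: paired-t left/right symmetry, Pearson/Spearman method
  correlation, Bland–Altman agreement (bias ± 1.96 SD limits, differences
  oriented fixed − hotspot), a Shapiro–Wilk + variance-homogeneity gate
  choosing ANOVA vs Kruskal–Wallis, and Dunn's Bonferroni-adjusted
  post-hoc comparisons.
* **A digital phantom generator** — stylized whole-body anatomy, 12 muscle
  compartments with bone landmarks, vessels, a blood-pool reference,
  group-level uptake multipliers, focal lesion insertion, PSF blur and
  activity-proportional noise — with exact ground truth, so the entire
  pipeline is verifiable without patient data. NIfTI + JSON import/export
  included.

Results are tibbles throughout; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(fdgmuscle)

# simulate the default cohort: 8 controls, 11 RA, 10 OA, 10 IIM,
# uptake multipliers 1.0 / 1.1 / 1.4 / 2.0, PSF 6 mm, noisy
study <- run_study(study_config(cohort = cohort_config(seed = 1)))
study
#> <muscle_study> 39 scans, 936 VOI rows
#>   pooled fixed-hotspot bias -0.447 [-1.272, 0.377], Pearson R^2 0.657
#>   heterogeneous in quadriceps+hamstrings: 100%

dplyr::filter(study$method_comparison$summary, muscle == "pooled")
#> # A tibble: 1 × 12
#>   muscle     n pearson_r pearson_r2 ...   bias sd_diff loa_lower loa_upper
#> 1 pooled   234     0.810      0.657 ... -0.447   0.421     -1.27     0.377

glance(study$group_tests$quadriceps)
#> # A tibble: 1 × 6
#>   test           statistic        p stars n_groups     n
#> 1 kruskal-wallis      31.9  5.4e-07 ***          4    39
```

Reading the output: the pooled Bland–Altman bias of **−0.45** SUV
(fixed − hotspot) says the hotspot method reads systematically higher on a
heterogeneous cohort — the fixed plane misses focal lesions; on a
homogeneous noiseless cohort the bias is exactly zero. The two methods
still correlate strongly (R² ≈ 0.66 pooled), and the Kruskal–Wallis test
on the left/right-averaged hotspot SUVpeak separates the four groups
(H = 31.9, p ≈ 5 × 10⁻⁷ for the quadriceps), with IIM highest in psoas,
hamstrings and quadriceps. `autoplot()` draws the
Bland–Altman and group-comparison figures; `study$pattern_table` mirrors
the qualitative group × muscle × side scoring table.

A thin command-line wrapper lives in `inst/scripts/run_study.R`:

```sh
Rscript inst/scripts/run_study.R --seed 1 --out study_out/
```

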