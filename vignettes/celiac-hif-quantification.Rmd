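---
title: "Quantifying celiac-disease histology with human-interpretable features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying celiac-disease histology with human-interpretable features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celiachif)
```

## The problem

Histological grading of celiac disease (the modified Marsh / Marsh–Oberhuber
scale: 0, 1, 2, 3a, 3b, 3c) is ordinal, qualitative, and suffers from poor
inter-observer agreement. Machine-learning tissue segmentation and cell
classification on H&E whole-slide images make a continuous alternative
possible: compute a catalogue of *human-interpretable features* (HIFs) —
compartment area proportions, cell densities, and cell count proportions —
that track the three histological hallmarks of the disease: villous atrophy,
crypt hyperplasia, and intraepithelial lymphocytosis.

`celiachif` implements everything downstream of the segmentation models.
Its inputs are the models' outputs: an integer-coded tissue label map
(pixel classes: villous epithelium, crypt epithelium, crypt lumen, lamina
propria, blood vessels, muscularis mucosae, other tissue), a classified
cell point set (neutrophils, plasma cells, enterocytes, intraepithelial
lymphocytes, other lymphocytes, eosinophils, goblet cells, other cells),
an optional artifact mask, a per-slide Marsh grade, and the raster scale in
microns per pixel. Because segmentation models and clinical slides are not
distributable, the package also contains a synthetic-histology generator
that emulates the statistical structure of a graded duodenal cohort, so
every stage is testable end to end.

## The feature catalogue

Features are computed per slide, after artifact exclusion
(`apply_artifact_exclusion()` recodes masked pixels to an `artifact` class
that no area or cell count ever includes). Derived compartments are fixed
set algebra over the tissue classes:

* `all_epithelium` = villous + crypt epithelium (lumen excluded);
* `mucosa` = both epithelia + crypt lumen + lamina propria + muscularis
  mucosae;
* `usable_tissue` = every non-background class surviving artifact
  exclusion (including blood vessels and other tissue).

The mucosa definition follows anatomical convention (everything from the
luminal surface to the muscularis mucosae inclusive); "usable tissue" is
defined as all quantifiable tissue because the feature naming refers to
tissue quality, not to a specific compartment subset.

Area features are ratios of pixel counts (the scale cancels), densities are
counts per mm² of compartment area (`count / (pixels × mpp² × 10⁻⁶)`), and
count proportions are ratios of in-compartment cell counts. Densities are
reported per mm² of the *compartment*, not of total tissue: the magnitudes
of published duodenal values (≈900–2700) are consistent with per-compartment
cells/mm². Cells are assigned to the pixel containing them —
`floor(coordinate / mpp)`, 0-based, origin top-left, half-open pixels — an
unambiguous rule that makes every feature an exact function of the inputs.
Undefined ratios (zero-area or zero-count denominators) are `NA`, never 0;
zeros would silently bias downstream correlations. The catalogue
(`hif_feature_names()`) has 18 core features plus two extended crypt-IEL
features (IEL density in crypt epithelium, and the villous:crypt IEL
density ratio), which quantify the spatial distribution of IELs across
epithelial compartments.

The clinical lymphocytosis rule is exposed as `iel_flag()`: positive iff
the IEL-per-enterocyte count proportion in villous epithelium strictly
exceeds 30 per 100 enterocytes.

## The synthetic cohort generator

`simulate_slide()` composes three parts.

**Geometry** (`simulate_label_map()`): villi are rendered as vertical
finger-like regions (epithelial rim around a lamina-propria core) above a
crypt band (periodic crypt units with lumina separated by lamina-propria
septa), a free lamina-propria band, a muscularis-mucosae band, and an
other-tissue base containing blood vessels; background represents the gut
lumen. Grade acts through per-slide targets drawn from `grade_params()`:
villous/mucosa, crypt/mucosa, and LP/mucosa area fractions, with the
remainder split 60/40 between crypt lumen and muscularis mucosae. After
rendering, an exact pixel-count correction reassigns a small number of
pixels so each mucosal class's area equals its drawn target exactly. This
keeps the generator *unbiased by construction* with respect to its
calibration targets, at the cost of a little salt-and-pepper texture at
compartment boundaries — invisible to every feature, which depends only on
counts and positions.

Three draw-level choices matter:

* Lamina propria is negatively coupled to the villous draw
  (`lp_villous_coupling = 0.4`): villous blunting and lamina-propria
  expansion co-occur in real mucosa, and the coupling keeps the three
  drawn fractions jointly feasible almost always. Only the rare residual
  tail (fraction sum > 0.985) is rescaled.
* Grade-0 targets anchor to published normal-duodenum means/SDs and
  grade-3c to the celiac column; intermediate grades interpolate linearly
  on the ordinal scale. The source data pool all celiac grades into one
  column, so the within-spectrum schedule is a modeling choice — the
  weakest part of the emulation, and deliberately simple (any monotone
  schedule yields the same qualitative grade trends).
* `crypt_frac_of_epith` (crypt share of all epithelium) is retained in
  `grade_params()` as a documented emergent target; the generator draws
  crypt/mucosa directly and the epithelial share falls out with the right
  mean.

**Cells** (`populate_cells()`): a homogeneous Poisson point process per
compartment and cell class, at per-slide densities drawn from the grade
targets, followed by 3 µm minimum-spacing thinning (a nuclear radius; it
prevents degenerate coincident points). Two couplings reproduce published
ratio features with the right mean *and* spread: villous enterocyte
density is derived per slide as drawn IEL density / drawn IEL-per-enterocyte
ratio, and lamina-propria class densities are a drawn total density times
drawn count proportions. Neutrophil and eosinophil densities are derived
analytically at the anchors from their mucosa-wide count-proportion
targets. Quantities no table reports are fixed once at realistic values:
crypt IEL density 350 → 900 cells/mm² (normal → 3c), crypt epithelial
cells 4800 /mm², goblet cells ≈ 10% of enterocytes, a small `other_cell`
background in epithelium. Thinning removes ~5–15% of points at epithelial
densities, biasing realized densities slightly low (well inside the
generator's 3-SD tolerance) while leaving ratios unbiased.

**Artifacts** (`simulate_artifact_mask()`): disk-shaped blobs accumulated
over tissue until the grade's `artifact_fraction` (default 2%) of tissue
pixels is covered — debris, folds and out-of-focus regions are blob-like
at slide scale.

All randomness flows from one root seed; per-slide and per-stage child
seeds are derived deterministically, so any slide is reproducible in
isolation and identical inputs give bit-identical outputs.

**What the generator does and does not emulate.** It reproduces the
joint statistical structure of the feature table (means, SDs, grade
trends, group separations) and plausible compartment topology. It does not
render nucleus shapes, staining, tissue orientation artifacts, fragment
heterogeneity, or spatially correlated cell clustering beyond the
compartment structure. Tests passing on synthetic cohorts therefore
validate the *measurement pipeline* — that the features compute what they
claim on known inputs, and that the statistics recover planted structure —
not the segmentation models or real-tissue performance.

## Multi-annotator consensus validation

Cell-call validation follows the standard frame protocol: sample
non-overlapping 75 µm × 75 µm frames (`sample_frames()`), have several
annotators (and the model, treated as one more labeler) exhaustively mark
cells, then:

1. **Cluster** all labelers' points (`cluster_annotations()`):
   single-linkage agglomeration cut at 4 µm (about a lymphocyte radius) —
   points closer than that across labelers refer to the same cell.
   Clusters holding two points from one labeler are split by nearest
   assignment, recursively. Labelers missing from a location are recorded
   `"absent"`.
2. **Estimate truth** (`estimate_truth()`): a Dawid–Skene latent-class
   model fit by EM to a MAP solution under symmetric Dirichlet smoothing
   (`Dirichlet(1 + prior_strength)` on prevalences and confusion rows,
   default `prior_strength = 0.1`). `"absent"` is non-informative —
   detection is kept separate from classification so confusion matrices
   stay interpretable. Majority-vote initialization makes the fit
   deterministic; exact posterior ties break to the lowest class code.
   EM-MAP was chosen over posterior sampling because it is deterministic
   and desk-scale while capturing the Bayesian-consensus intent; full
   sampling is a straightforward extension.
3. **Score labelers** (`labeler_metrics()`): one-vs-rest sensitivity and
   specificity per cell class against the MAP consensus, `"absent"`
   counting as a negative for every class; `labeler_confusion()` gives the
   row-normalized observed confusion matrix. F1 components are derivable
   from the same TP/FN/FP/TN counts.

A caveat worth knowing: with a single labeler the latent-class likelihood
is flat along a label-switching ridge and the smoothing prior softens the
fit, so posteriors concentrate (majority mass) on the labeler's labels
without reaching certainty. With ≥3 labelers of reasonable accuracy the
model recovers planted confusion diagonals to within ±0.05 and planted
truth at ≥95% agreement (this is tested).

## Cohort statistics

`correlate_features()` computes tie-corrected Spearman rank correlations of
each feature with the ordinal-encoded Marsh grade (0, 1, 2, 3a, 3b, 3c →
0..5; any strictly monotone encoding gives identical rank correlations, so
the sub-grade choice is cosmetic), with two-sided p-values from the t
approximation on n − 2 df. `compare_groups()` runs per-feature independent
t-tests between normal (grade 0) and celiac (all other grades) slides.
Welch's unequal-variance form is the default — published group SDs differ
markedly — with the pooled Student variant behind a flag.
`welch_from_summary()` exposes the summary-statistic form so published
mean/SD/n tables can be tested directly; it agrees with the raw-data Welch
test to ≥10 significant figures. Missing feature values are removed
pairwise, never imputed. Raw p-values are reported, as is conventional for
descriptive feature tables; Benjamini–Hochberg adjustment is available as
an opt-in column, never applied silently.

## Numerical choices and degenerate inputs

* EM stops when the largest absolute posterior change < `tol` (default
  1e-6) or at `max_iter` (default 100); the MAP objective is
  non-decreasing across iterations (asserted in tests on the logged
  trace).
* Frame placement is rejection sampling with restarts: a partial greedy
  placement can be a geometric dead end, so after 200 consecutive
  rejections the placement restarts; a cap on total tries turns truly
  infeasible requests into an error.
* Degenerate generator inputs: rasters under 64×64 px cannot hold a villus
  and a crypt and raise a geometry error; a zero-mean zero-SD villous
  target yields exactly zero villous pixels; positive cell densities in
  zero-area compartments warn and skip; a zero-slide cohort is an empty
  success, not an error.
* Both SDs zero in a t-test: equal means give an undefined test (`NA`),
  unequal means are an error (infinite t).

## Problem sizes

The package's standard synthetic problem sizes, used by its tests and
reproduction script, are: 768×768 px at 1.0 µm/px for cohort-level runs
(a realistic ~0.6 mm² biopsy fragment at segmentation-heatmap resolution —
large enough that Poisson counting noise does not drown the planted
group differences in cell-count features), 128×128 px for calibration
replicates, and ≤32×32 px hand-checkable rasters for exact-arithmetic
oracle tests. Default raster scale elsewhere is 0.25 µm/px, the nominal
40× scanning resolution.

## Known limitations

* The per-grade interpolation schedule is a modeling choice; only the two
  anchor columns are data-derived.
* Villous/crypt *length* morphometry (villus height, crypt depth) is out
  of scope; area proportions are the implemented surrogates.
* HIFs are slide-global: per-fragment reporting and orientation
  variability are not modeled.
* The generator's artifact blobs and uniform point processes are
  simplifications; real artifact and cell spatial structure is richer.
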