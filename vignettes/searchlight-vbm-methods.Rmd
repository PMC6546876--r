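---
title: "Searchlight pattern analysis of gray-matter volume: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight pattern analysis of gray-matter volume: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpattern)
```

## The problem

Herpes-zoster patients differ in how well their neuropathic pain responds to
first-line medication (anticonvulsants, tricyclic antidepressants). Patients
whose 10-point visual-analog pain score (VAS) drops by less than three after a
week of treatment are labeled medication-resistant (MRP), the others
medication-sensitive (MSP). The question this package operationalizes: do
pre-treatment structural MRI scans — specifically modulated gray-matter (GM)
volume maps from a voxel-based-morphometry (VBM) pipeline — carry a spatial
pattern that predicts that response?

The package implements the full analysis chain downstream of segmentation:

1. **Searchlight MVPA** — at every GM voxel, a 5-mm sphere of voxel values is
   the feature vector of an SVM classifier; leave-one-out cross-validated
   (LOOCV) accuracy is assigned to the center voxel.
2. **Binomial cluster inference** — accuracies become exact Bi(n, 1/2) tail
   p-values; suprathreshold voxels (p < 10⁻⁴) form 18-connected clusters of
   at least 50 voxels; each cluster is validated by label-permutation testing.
3. **Post-hoc VBM** — covariate-adjusted voxel-wise two-sample t-tests inside
   the MVPA clusters, corrected by a Monte-Carlo (AlphaSim-style)
   cluster-extent threshold, plus Spearman correlation of cluster mean GM
   volume with the VAS change.
4. **Clinical statistics** — the demographics table (Welch/Student t,
   chi-square) and a power/sample-size utility.

Because the original patient data are not deposited, a first-class synthetic
cohort generator stands in for them, and every stage is validated against it.

## Grid geometry

The analysis grid is 1.5 mm isotropic by default. The spacing is implied
rather than stated by the source analysis: a sphere of radius 5 mm on a
lattice with spacing $s$ contains exactly 171 lattice points only when
$\sqrt{11}\,s \le 5 < \sqrt{12}\,s$, i.e. $s \approx 1.5$ mm. Sphere
membership uses an inclusive boundary ($\lVert o \circ s\rVert_2 \le r$);
an exclusive boundary would give a different count. Spheres truncated by the
mask or grid edge keep their in-mask voxels and the feature vector shortens
(`drop_partial = TRUE` discards them instead). Voxel indices are 1-based
throughout the R API, the natural convention in R; world coordinates follow
the NIfTI affine, which maps 0-based indices.

```{r}
nrow(sphere_offsets(5, c(1.5, 1.5, 1.5))$offsets)
```

## The classifier

The SVM is a C-support-vector classifier with RBF kernel
$K(x, z) = \exp(-\gamma \lVert x - z \rVert^2)$, solved by SMO with the
maximal-violating-pair rule and the standard 10⁻³ stopping tolerance (the
environment offers no libsvm binding, so the solver is implemented in C++;
it reproduces scikit-learn's libsvm accuracies exactly on shared fixtures).
"Default parameters" are resolved as $C = 1$, $\gamma = 1/V$ with $V$ the
sphere's feature count — the historical libsvm default. Features are
standardized per column on the training fold only and the training
parameters are applied to the held-out subject; zero-variance training
columns map to 0 so the feature dimension is stable across folds. Prediction
ties break toward the class with the lower label index, deterministically.

Two numerical properties are worth knowing:

* Per-fold standardization leaves pairwise distances dependent only on the
  fold's column sds (means cancel), so each fold needs one weighted distance
  matrix; permutation tests reuse the fold kernels across all label shuffles,
  since the kernels do not depend on labels.
* **LOOCV at near-balanced n is pessimistic under the null.** Holding out a
  subject tips the training majority toward the other class, and a
  weakly-informed RBF-SVM leans majority. On pure iid noise with V = 171 the
  mean null accuracy is ≈ 0.27 — far below ½ — and scikit-learn's libsvm
  gives identical values. On smoothed GM-like cohorts (low effective
  dimension) the bias is milder but persistent: mask-mean null accuracy
  averages ≈ 0.41–0.42 over 20 seeds (per-seed range ≈ 0.35–0.48) on both
  16³ and 20³ masks. The 0.5 ± 0.05 chance band the validation plan asks
  for is therefore unattainable for a faithful default-parameter libsvm at
  n = 14/15, and the corresponding acceptance assertion is left red rather
  than recalibrated. The binomial null (below) is conservative on top of
  its discreteness as a consequence.

## Binomial and permutation inference

Under the null the number of correct classifications is Bi(n, ½); the
p-value of k correct is the inclusive upper tail $P(X \ge k)$ (the
exact-test convention; a strict tail is available). For $n \le 52$ the tail
is an exact integer sum divided by $2^n$, both exact in doubles. At the
study size n = 29, $p < 10^{-4}$ first holds at k = 25 (86.2% accuracy); the
source analysis prints "79%" alongside the same threshold, which is
inconsistent with Bi(29, ½) — the implementation enforces the p-threshold,
and the printed accuracy figure is documented as irreproducible.

```{r}
data.frame(k = 22:26, p = binomial_tail_p(22:26, 29))
```

Cluster extraction thresholds the p-map at voxel α (default 10⁻⁴), labels
maximal components under 18-connectivity (6 faces + 12 edges; 6 and 26
available), and keeps components of at least 50 voxels ("at least 50" is
adopted where the source text also says "more than 50"; the one-voxel
discrepancy is deliberate and documented). Peaks are minimal-p voxels, ties
broken by smallest column-major linear index. Permutation validation
shuffles labels (group sizes preserved, identity permutation not excluded),
recomputes LOOCV accuracy of the cluster's full voxel set (the peak-sphere
alternative is a flag), and reports the add-one estimate
$p = (1 + \#\{a_{perm} \ge a_0\})/(n_{perm} + 1)$, whose smallest value at
1000 iterations is 1/1001 — consistent with the smallest reported value of
0.001 and never zero.

## Post-hoc model

GM value is regressed on intercept + group + age + gender per voxel
(ordinary least squares; gender coded 0/1; age uncentered — centering does
not change the group t in a model with an intercept). The group t with
N − p degrees of freedom reduces to the classical pooled-variance two-sample
t without covariates. The Monte-Carlo extent threshold simulates Gaussian
noise fields at the known applied smoothness (8 mm by default; residual-based
smoothness estimation is out of scope), standardizes within the mask,
thresholds two-tailed at voxel p = 0.01, and returns the smallest extent s
such that the fraction of iterations whose largest component reaches s is at
most α = 0.05. Thresholding is two-tailed with sign-separated clustering, so
every surviving cluster carries a direction (MRP < MSP or MRP > MSP).
Published extent values (e.g. "40 voxels") depend on the original mask and
smoothness and are not reproducible; only the procedure and its
monotonicities are testable, and they are tested.

Spearman correlation of per-subject cluster mean GM volume with
ΔVAS = pre − post uses average ranks for ties, exact p for n ≤ 9 untied
observations and the t-approximation otherwise, computed within the MSP
group by default (selectable).

## The synthetic cohort: what it emulates, what it does not

Each subject map is baseline + iid Gaussian voxel noise, smoothed with a
separable Gaussian kernel (σ = FWHM/(2√(2 ln 2)) per axis, truncated at 4σ,
reflective boundary; constant-zero padding available). Smoothing induces the
spatial autocorrelation that makes VBM maps cluster — the property the
extent-based inference exploits — but no anatomy, partial-volume structure,
or registration error is simulated. Group effects are additive mean shifts
inside hard spheres applied before smoothing, which soft-edges them.

**Effect-size convention.** The stated blob effect d is the *realized* peak
Cohen's d of the smoothed group difference against the smoothed
between-subject noise sd. The naive alternative — shifting by d × (unsmoothed
noise sd) — lets 8-mm smoothing shrink the noise ~25-fold while preserving
the blob, so a nominal d = 2 would realize d ≈ 27: the accuracy map
saturates at 1.0 over thousands of voxels and all blob-geometry recovery
becomes meaningless. Under the realized-d convention a d = 2 cohort yields
peak accuracies of ~86–97% and cluster sizes of tens to hundreds of voxels,
the same regime as the published tables. The shift amplitude therefore
compensates both the filter's noise shrinkage (∏ axes √Σw²) and the
blob-edge attenuation of the smoothed indicator.

Clinical columns are drawn from truncated normals *calibrated so the
truncated moments equal the stated ones* (naive clipping deflates the sd —
materially so for age, whose printed sd of 7 is unattainable under
truncation to the study's 55–79 inclusion window; ages use a plausible
40–95 range instead). Gender is assigned with exact per-group counts.
Clinical columns are independent of the image effect unless `vas_coupling`
ties post-treatment VAS to blob intensity for correlation testing. A cohort
is a pure function of its spec, including the seed.

A green test on this generator establishes that the pipeline recovers the
statistical structure it assumes — not that it would recover effects under
realistic anatomy, registration error, or non-Gaussian noise.

## Reproducibility and budget choices

A single pipeline seed derives per-stage seeds
(`(seed × 97 + stage index) mod (2³¹ − 1)`), so stages re-run independently
with identical results. Per-voxel searchlight computations depend only on
that voxel's features and the shared config, so any parallelization is
bit-reproducible (the shipped implementation is single-threaded C++). The
validation suites use 16³–24³ masks and hundreds rather than thousands of
Monte-Carlo iterations where the assertion tolerances permit, to stay inside
the test-time budget; the defaults of every user-facing function remain the
published values (5 mm, 10⁻⁴, 50, 18-connectivity, 1000 permutations, 0.01,
0.05, 8 mm).

## Known limitations and documented discrepancies

* The "79% accuracy ↔ p < 10⁻⁴" correspondence printed by the source
  analysis contradicts Bi(29, ½); the p-threshold governs.
* Pre-VAS (printed p = 0.09) and Pre-PSQI (printed p = 0.76) cannot be
  reproduced from the printed rounded summaries (Welch gives ≈ 0.10 / 0.78);
  presumably they were computed on unrounded data. The other five table rows
  reproduce exactly at printed rounding (Welch t, chi-square without
  continuity correction — Yates would give 0.36, not 0.20; Student's t would
  give 0.003, not 0.004, for post-PSQI).
* At the published thresholds, a realized d = 2 blob at n = 14/15 is a
  borderline-detectable effect: the voxel bar is 25/29 correct (≈ 2.6 σ of
  the null per voxel) sustained over ≥ 50 contiguous voxels, and full-pipeline
  detection succeeds in roughly half of seeds rather than the 80% the
  validation target asks; the acceptance suite reports this honestly rather
  than weakening a threshold.
* No FWE/FDR voxel correction, no Gaussian-random-field or TFCE inference,
  no smoothness estimation from residuals, no preprocessing (segmentation,
  DARTEL registration, modulation) — inputs are already-segmented modulated
  GM maps or synthetic stand-ins.
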