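---
title: "Mueller-matrix polarimetry features and patient-level recurrence classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mueller-matrix polarimetry features and patient-level recurrence classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerml)
```

## The problem

Peri-tumoral collagenous stroma carries prognostic information: the maturity
of the desmoplastic reaction around a tumor correlates with the risk of
local recurrence after surgery. Mueller-matrix polarimetry measures exactly
the tissue properties that reflect stromal architecture — birefringent
retardance from aligned collagen fibers, diattenuation, and depolarization
from scattering — without staining. `muellerml` implements the full analysis
chain from raw polarization-state intensity frames to a patient-level
recurrence classifier, together with a synthetic cohort generator that
exercises every stage without instrument data.

The chain is:

1. **Acquisition model and reconstruction** — a polarization state generator
   (PSG; polarizer + quarter-wave plate) prepares a Stokes vector
   $S_\mathrm{in}$, the sample acts as $S_\mathrm{out} = M\,S_\mathrm{in}$
   with $M$ the $4\times4$ Mueller matrix, and the analyzer (PSA) projects
   onto its first row. Each acquisition state $k$ gives one linear equation
   $I_k = a_k^\top M\, s_k$ in the 16 elements; 24 states give an
   overdetermined system solved per pixel by least squares.
2. **Feature extraction** — the Lu–Chipman polar decomposition
   $M = M_\Delta M_R M_D$, the Mueller-matrix transformation (MMT)
   parameters, and the 16 normalized elements give 25 features per matrix.
3. **ROI aggregation** — within each region of interest the per-pixel
   matrices are reduced to one element-wise *median* Mueller matrix first,
   and features are computed from that median (not the other way round).
4. **Classification** — patient-grouped stratified 5-fold cross-validation
   over five learners, majority-vote patient calls, feature-importance
   ranking, and optional greedy outlier-patient elimination.

## Acquisition protocol

The 24-state default protocol fixes the PSG polarizer at 0° and steps its
quarter-wave plate through $\{0°, 30°, \dots, 150°\}$; the PSA takes four
settings analyzing the horizontal, $+45°$, right-circular and vertical
components. The induced $24\times16$ design matrix has rank 16 and
condition number ≈ 11.7, so reconstruction noise is amplified only modestly.
The protocol is data, not a constant: any published angle list can be
supplied as a `pol_states()` table, and `sequence_condition()` reports its
conditioning. `reconstruct_mueller()` refuses rank-deficient manifests by
name rather than returning garbage.

Assumptions: ideal optics (exact quarter-wave retardance, no diattenuation
in the wave plates), pre-registered frames, and an air (identity-sample)
calibration check — reconstructing an identity stack must return the
identity, which the test suite asserts.

```{r protocol}
states <- default_pol_sequence()
sequence_condition(states)
```

## Decomposition conventions

Element labels are 0-based (`m00`..`m33`), matching the physics literature's
$M_{00..33}$; in R code element $m_{ij}$ is `M[i+1, j+1]`.

* Diattenuation $D = \sqrt{m_{01}^2+m_{02}^2+m_{03}^2}/m_{00}$ and linear
  polarizance $P_L = \sqrt{m_{10}^2+m_{20}^2}/m_{00}$ come straight from
  the first row/column.
* The Lu–Chipman factors are computed sequentially: $M_D$ from the
  diattenuation vector, then $M' = M M_D^{-1}$, then the depolarizer block
  $m_\Delta$ as the symmetric square root of $m' m'^\top$
  (eigendecomposition, eigenvalues clipped at zero, overall sign from
  $\det m'$ so the retarder block stays a proper rotation), then
  $m_R = m_\Delta^{-1} m'$. Total retardance
  $R = \arccos(\mathrm{tr}(M_R)/2 - 1)$; linear retardance and optical
  rotation use the retarder block's $(Q,U)$ rows, with the conventional
  factor $\tfrac12$ in $\psi$ so a pure rotator by $\psi$ reports $\psi$.
* MMT parameters use the $(QQ, UU)$ central block of the normalized matrix:
  $b = (m_{11}+m_{22})/2$, $t_1 = \sqrt{(m_{11}-m_{22})^2 +
  (m_{12}+m_{21})^2}/2$, $A = 2bt_1/(b^2+t_1^2)$. This is the block that
  makes $b$, $t_1$, $A$ invariant under in-plane sample rotation — an
  invariance the test suite checks to $10^{-9}$ together with the other six
  derived features.

Numerical guard rails: `arccos` arguments are clipped to $[-1, 1]$; a
diattenuation at 1 (ideal polarizer) would make $M_D$ singular, so $D$ is
clipped to $1 - 10^{-6}$ and the result flagged `diattenuation_clipped`; a
fully depolarizing sample takes $M_R = I$ with flag `depolarizer_singular`.
`feature_vector()` consequently never emits non-finite values — degraded
results carry flags instead.

The 25-feature set is the 16 normalized elements plus
$\{D, P_L, \Delta, R, \delta_L, \psi, b, t_1, A\}$, spanning the polar
decomposition, MMT and rotation-invariant families. The set is addressed by
name throughout (`mm_feature_names()`), so any subset can be swapped in via
the `features` argument of the pipeline functions.

## Why median-then-features

With $\sim10^2$–$10^4$ pixels per ROI, per-pixel features are noisy and
their distributions skewed. The pipeline reduces each ROI to the
element-wise median Mueller matrix first and derives features from that
median. The median is outlier-resistant (a corrupted pixel leaves it
untouched, which the tests assert) and the order of operations matters:
on a heterogeneous ROI, the feature of the median differs measurably from
the median of the features, and the suite pins down which one the package
computes. Even pixel counts take the mean of the two middle values. No
pixel-level physicality filtering is applied before the median by default —
masked (non-finite) pixels are excluded, everything else contributes.

## Classification workflow

* **Grouped stratified folds.** Patients, not ROIs, are assigned to folds;
  all ROIs of a patient travel together, so a patient never appears on both
  sides of a split. Within each label group patients are dealt to the
  currently smallest fold, which balances fold sizes to ±1 patient and
  spreads the minority class as evenly as the counts allow (with 8
  recurrent patients and 5 folds, some folds get 1 and some 2 — unavoidable).
  The default is one stratified partition; `cv_mode = "draws"` repeats
  independent grouped draws instead.
* **Learners.** Logistic regression, LDA, linear-kernel SVM, random forest
  and XGBoost behind one adapter contract (score, class, importance), with
  library defaults and a fixed seed; no hyperparameter search. LDA drops
  features that are constant within both classes (they carry no
  discriminant information) and reports them with zero importance.
* **Majority vote.** A patient is called recurrent when at least 50% of
  their test ROIs are predicted recurrent. An exact tie is resolved toward
  the recurrent class — the clinically conservative direction — and the
  threshold and tie rule are both arguments.
* **Metrics.** Per fold: ROI-level confusion matrix, sensitivity,
  specificity, accuracy; patient-level confusion from the votes; AUROC in
  the tie-corrected Mann–Whitney form (the suite checks it against a
  brute-force concordant-pair count). Fold results are reported as
  mean ± SD; confusion matrices are also averaged over folds (entries may
  be fractional); mean ROC curves use vertical averaging on a 101-point
  FPR grid.
* **Feature ranking.** Raw importances (absolute coefficients for the
  linear models, impurity for the forest, gain for XGBoost) are min-max
  normalized per model, averaged across models (`rank_features()`; mean
  rank available as an alternative), and the top-k selected with
  deterministic name-order tie-breaking.
* **Outlier elimination.** Exhaustive subset search over patients is
  $2^{n}$ and infeasible; `eliminate_outliers()` is greedy
  leave-one-patient-out: at each step every remaining patient is scored by
  the cross-validated ROI-level AUROC of the cohort without them, and the
  best removal is accepted if it improves the estimate by more than `tol`
  (default 0.005), up to `budget` removals (default 3). Two variance
  reductions make the greedy signal usable: all candidates within a step
  are evaluated on one fixed fold plan, and the default AUROC estimate
  pools out-of-fold scores across folds rather than averaging five
  small-fold AUROCs (`pooling = "fold_mean"` restores the latter). Even
  so, the loop is a heuristic: when several same-class flipped patients
  support each other, or a genuine borderline patient's removal helps more
  than `tol`, the removal set can differ from the planted truth — the
  package treats the removal log as an auditable record, not an oracle.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not tissue appearance. Each pixel's matrix is the composition
$M_\Delta(\Delta)\, M_R(\delta, \theta)\, M_D(D, \phi)$, so the
decomposition recovers the generating parameters exactly at zero spread
(tested to $10^{-6}$). Parameters follow a three-level Gaussian hierarchy —
class mean, patient effect, ROI effect, pixel jitter, truncated to physical
ranges — with the fiber orientation uniform per ROI. The default class
contrast encodes the package's working premise: non-recurring (mature
stroma) tissue gets higher retardance (0.90 vs 0.55 rad) and diattenuation
(0.12 vs 0.06) and lower depolarization (0.25 vs 0.40) than recurring
(immature) tissue. These magnitudes are simulation defaults chosen to give
a moderately separable cohort, not measured-tissue claims; every one is an
argument of `tissue_class_params()`.

The cohort structure mirrors the motivating clinical setting: 27 non-
recurring vs 8 recurring patients, 3–14 ROIs per patient, and
`roi_counts = "cohort"` reproduces the exact reference totals (263 + 70 =
333 ROIs) by spreading counts evenly. Planted outliers are ordinary
patients whose labels are flipped after simulation, with the ground truth
recorded in a sidecar table. The default 64 pixels per ROI keeps the fast
path under a few seconds; the real instrument's $\sim6\times10^4$ pixels
per ROI are reachable by argument but unnecessary for the statistics the
median preserves.

What the generator does **not** emulate: spatial fiber texture,
illumination inhomogeneity, registration artifacts, instrument polarization
errors, or label noise beyond the planted flips. Passing tests on synthetic
cohorts therefore validates the pipeline's mechanics and statistical
behavior, not clinical performance on real tissue.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at reduced sizes
chosen as sensible desk-scale defaults: 16–64 pixels per ROI, 18–35-patient
cohorts, and 30–100 random matrices per property check. Reconstruction uses
one pseudo-inverse of the $24\times16$ design matrix applied to all pixels.
Zero-noise round trips reproduce generating matrices to $\sim10^{-15}$,
well inside the $10^{-8}$ property bound; reconstruction error grows
linearly in the camera-noise scale, which the suite verifies empirically.

Null calibration runs the full pipeline on cohorts whose two arms share
identical tissue parameters and expects the mean AUROC in $[0.35, 0.65]$;
power runs use a retardance-only contrast of about nine patient-level
standard deviations, which concentrates the signal in the redundant
retardance feature family (\(\delta_L\), \(R\), central elements, \(b\),
\(t_1\)) — a deliberate fixture choice, because a weakly informative
auxiliary feature that happens to separate one training draw perfectly can
otherwise carry a spurious single-feature split that fails on a borderline
patient.

## Worked example

```{r example, eval = FALSE}
library(muellerml)

cohort <- generate_cohort(cohort_config(roi_counts = "cohort", seed = 11))
report <- run_experiment(cohort, seed = 3)
tidy(report)
ranking <- rank_features(report_importances(report), k = 5)
selected_features(ranking)
autoplot(report)

# re-run with the selected features only
report5 <- run_experiment(cohort, features = selected_features(ranking), seed = 3)
glance(report5)
```

## Known limitations

* Ideal-optics forward model; no wavelength dependence or instrument
  calibration beyond the air identity check.
* ROI rectangles live in Mueller-image coordinates; transferring
  pathologist ROIs from stained slides is out of scope.
* The greedy outlier loop is a heuristic (see above); its `tol` should be
  kept above the quantization noise of the AUROC estimate for the test-set
  sizes at hand.
* With a one-partition 5-fold CV on 35 patients, fold metrics are averages
  of small test sets; standard deviations across folds are wide and should
  be reported alongside every mean, as `tidy()` does.
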