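---
title: "Methods: cross-tissue correlation-guided radiomics for PLNM prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue correlation-guided radiomics for PLNM prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnmrad)
```

## The problem

Pelvic lymph node metastasis (PLNM) strongly conditions prognosis and
treatment in prostate cancer, but conventional MRI reading of pelvic nodes
has low sensitivity. Radiomics offers a way out: quantitative texture,
intensity and shape descriptors of the *primary* lesion on biparametric MRI
(T2-weighted imaging plus an ADC map) can be fed to a classifier that
predicts nodal status before surgery.

The difficulty is feature selection. A full 3D radiomic extraction yields
thousands of features per volume of interest (VOI), most of them unrelated
to metastatic behaviour, and purely statistical filters (univariate tests,
sparse regression) must find the needle in that haystack from a few hundred
cases. `plnmrad` implements a complementary, biologically motivated filter:
metastatic deposits in pelvic nodes are clonally derived from the primary
lesion, so lesion features that *co-vary with the same features measured in
metastatic nodes* across node-positive patients are plausibly the ones
carrying the metastatic phenotype. The package builds and compares two
model arms:

* **lesion arm** - primary-lesion features, selected by a per-feature
  two-sample *t* test then LASSO;
* **lesion-correlation arm** - the same pipeline preceded by the
  cross-tissue filter: a lesion feature survives only if its Pearson
  correlation with the same-named node feature across PLNM-positive
  training cases exceeds 0.9 in absolute value.

Both arms end in a SMOTE-rebalanced SVM, and the two are compared with the
paired DeLong test on training and held-out splits.

## Feature space

Each VOI is described by 3748 features: for each of the two modalities (T2,
ADC), 14 shape descriptors of the mask plus 93 intensity/texture features
(18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) computed on
the original image and on each of 19 filtered images:

```{r}
enumerate_feature_images(bank_config())
```

giving `2 * (14 + 20 * 93) = 3748`. Extraction settings, all exposed in
`extraction_settings()`, follow the common conventions of 3D radiomics
software: resampling to 1 mm isotropic spacing (cubic B-spline for images,
nearest neighbour for masks), whole-image intensity normalization to zero
mean and scale 100, a fixed gray-level bin width of 25, a voxel-array shift
of +300 applied only inside the energy-type first-order formulas, and a
10-voxel pad around each VOI bounding box so that filter supports never
truncate at the crop edge (features computed on the padded crop equal the
whole-volume computation, which the test suite asserts).

Numerical conventions worth knowing:

* **Discretization.** Levels are `floor((x - min)/25) + 1`; a maximum
  falling exactly on a bin edge opens its own top level.
* **Degenerate regions.** For a single-level region, GLCM `Correlation` and
  `MCC` are defined as 1, first-order `Skewness`/`Kurtosis` as 0, and the
  LBP kurtosis map uses sentinel 0 where the sampled neighbourhood is
  constant.
* **Direction handling.** GLCM and GLRLM are computed per 13 unique 3D
  directions and feature values are averaged over directions (not merged
  matrices); GLSZM zones use 26-connectivity.
* **Surface model.** Shape features use the voxel-face surface mesh: areas
  are sums of exposed faces, the mesh volume (divergence theorem over that
  mesh) coincides with the voxel volume, and diameters are maximal
  vertex-pair distances. This overestimates the area of smooth bodies
  relative to an iso-surface mesh but is exactly scale-covariant and
  requires no meshing heuristics.
* **Boundary handling.** All convolution filters (Gaussian/LoG, gradient)
  use whole-sample mirror padding. The stationary Haar wavelet deliberately
  uses periodic boundaries instead, so that the orthonormal filter pair
  satisfies the exact energy identity (sub-band energies sum to 8 times the
  input energy), which the tests verify; with mirror padding the identity
  would hold only approximately.
* **LBP-3D.** Intensities are sampled at 12 icosahedron vertices of a
  1-voxel-radius sphere and binarized against the centre; `m1` and `m2` are
  the level-1 and level-2 spherical-harmonic band energies of the binary
  pattern and `k` is the plain kurtosis of the sampled intensities. This
  honours the three-map contract, determinism, and the usual invariances;
  numeric parity with any particular reference implementation is not a
  goal.
* **Multiple nodes.** When a patient has several node masks the default
  policy extracts from the largest node by voxel volume; a mean-over-nodes
  policy is available (`extraction_settings(node_policy = "mean")`). Which
  policy is right is not decidable from data of this kind; both are
  implemented, with the largest node as the default.
* **Shape per modality.** Shape features depend only on the mask, yet they
  are emitted once per modality so that each modality contributes 1874
  named features; this duplication is what makes the 3748 total attainable
  and is flagged here deliberately.

## Selection and modeling

Features are standardized to zero mean and unit variance with parameters
fitted on training rows only. The correlation filter runs on PLNM-positive
training cases (nodes exist only there), pairing features across tissues by
name; absolute correlation is used by default because an anticorrelated
feature is equally informative (a signed mode exists). The *t* test is
Welch's by default (pooled-variance option for textbook reproduction), and
LASSO is an L1-penalized logistic regression whose penalty minimizes
binomial deviance averaged over 5-fold stratified cross-validation repeated
5 times, ties broken toward the sparser model. The retained sets are nested
across stages by construction, and the whole trace (per-stage names, LASSO
weights) is recorded and serializable.

The classifier is an RBF-kernel SVM with cost in {0.1, 1, 10, 100} and
gamma equal to the scale heuristic `1/(p * var(X))` times {0.1, 1, 10}; no
particular kernel is canonical for this task, so the grid is this package's
choice, with a linear kernel available. Hyperparameters maximize mean held-out AUC over
the same repeated stratified 5x5 cross-validation. SMOTE synthesizes
minority rows as convex combinations of minority nearest neighbours and is
applied *inside* each training fold only - never to validation folds - to
avoid the optimistic bias of rebalancing before splitting - the defensible
placement whenever "rebalance the training set" is otherwise ambiguous. The decision threshold
is fixed once, by Youden's J on the training ROC. A mutation test verifies
that no fitted parameter depends on validation rows.

Model comparison uses the Mann-Whitney AUC (midranks for ties), DeLong
structural-component variance for confidence intervals on the AUC scale
(matching the printed-interval convention of clinical radiomics papers; no
logit transform), and the paired DeLong z test, two-sided. The in-package
implementation is cross-checked in the test suite against pROC and against
a case-resampling bootstrap.

## What the synthetic cohort emulates

Clinical MRI cohorts of this design are private, so the package ships a
two-level generator whose defaults encode a realistic two-centre study
shape: 263 training cases (93
PLNM-positive / 170 negative), 74 internal and 57 external validation cases
at prevalences 19/74 and 14/57, and node masks whose short-axis diameter
(the middle principal axis, matching the radiological short-axis
convention) is at least 15 mm - the >= 1.5 cm inclusion rule for
image-diagnosed metastatic nodes.

**Feature-table level** (`simulate_feature_tables()`): each case draws a
latent severity factor; the 20 informative ("metastatic signature")
features load on it with pairwise correlation 0.5 and are mean-shifted by
`effect_size = 0.8` standard deviations in positive cases; informative
lesion-node pairs correlate exactly `cross_tissue_rho = 0.95` across
positive cases; the remaining 480 features are independent noise in both
tissues. The latent factor matters: twenty *independent* d = 0.8 features
would separate the classes almost perfectly and leave feature selection
nothing to improve, whereas correlated signature features cap the pooled
separation near AUC 0.8 - the regime the method actually targets - so the
benchmark is informative about selection quality. No quantitative effect
sizes are available from real cohorts of this design; these defaults are
the package's own calibration, chosen once and exposed in `sim_config()`.

**Image level** (`simulate_cohort()`): aligned T2/ADC phantoms on a 1 mm
grid with an ellipsoidal lesion (reduced ADC, heterogeneous T2 given by a
Gaussian random field whose amplitude and correlation length are case-level
parameters) and, for positives, one or two ellipsoidal nodes; positive
lesions and nodes draw their texture parameters from a shared latent
variable so extracted features correlate across tissues. The phantoms make
no attempt at anatomy, MR physics (coils, bias fields), or realistic organ
context - passing tests on them demonstrates the pipeline's statistical
machinery, not clinical performance.

Everything is a pure function of one master seed, fanned out to stages via
a Lehmer step (`derive_seed()`).

## Benchmark scale and expectations

The repeated benchmark (`run_arm_benchmark()`) trains both arms on the
263-case training split and scores a 74-case held-out split at prevalence
0.35, for 20 simulation seeds; with the default generator the
lesion-correlation arm exceeds the lesion arm by about 0.05 AUC on average
(the acceptance suite asserts at least 0.03). This is a qualitative
statement about the *direction* of the comparison; absolute AUCs on real
clinical cohorts are not reproducible targets for synthetic data. Problem sizes throughout the test suite
(64^3 crops for the feature-space contract, volumes up to 6^3 for the
brute-force texture oracles, 10^5 bootstrap replicates and 10^4 coverage
simulations for the DeLong checks, 20 seeds for the benchmark) were chosen
as the smallest scales at which each property is statistically decidable.

## Known limitations

* The correlation filter needs node segmentations for positive training
  cases; cohorts without VOI-2 masks can only run the lesion arm.
* Shape features use the blocky voxel mesh (see above); absolute values of
  `SurfaceArea`/`Sphericity` are not comparable with iso-surface
  implementations, though orderings across similar masks are.
* Texture families follow the standard matrix definitions but are validated
  against this package's own enumeration oracles, not against an external
  radiomics package (none is available in the environment); cross-software
  numeric parity is explicitly out of scope.
* The phantom generator produces aligned volumes; registration is an
  identity resampling by design, and deformable registration is out of
  scope.
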