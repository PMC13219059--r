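---
title: "Deriving and validating a Metabolic Progression Index from whole-body PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a Metabolic Progression Index from whole-body PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmpi)
```

## The problem

In widely metastatic cancers such as extensive-stage small-cell lung cancer,
no single PET parameter captures disease severity. Metabolic tumour volume
(MTV) measures bulk, SUVmax measures peak glycolysis, and dissemination
distances measure anatomical spread — and they are strongly collinear with
one another while each missing part of the phenotype. `petmpi` treats
severity as a *latent one-dimensional axis* of the joint feature space: it
extracts twenty whole-body lesion features per patient, embeds the cohort
with a diffusion map, and reads the first diffusion component (DC1) as a
pseudotime. The rank of each patient along DC1, rescaled to [0, 1], is the
Metabolic Progression Index (MPI).

## Feature extraction

Lesions are voxels with SUV strictly above a fixed threshold (default 2.5),
grouped by 26-connectivity. Per lesion we compute MTV (voxel count x voxel
volume), SUVmean, SUVmax, TLG = MTV x SUVmean, the summed voxel SUV, and the
unweighted voxel-centre centroid. The twenty cohort features fall into four
families:

* **Global burden** — tMTV, tTLG, Intensity_Sum (all voxel SUVs),
  MeanIntensity_Sum (sum of lesion SUVmeans), Volume_intensity_sum
  (sum of lesion volume x lesion intensity sum; this product reading is the
  one consistent with the ~10^7 magnitudes such cohorts report).
* **Dominant lesion** — MTV_Bulk, MTV_Smallest, tSUVmax, MaxIntensity_Min.
  The *bulk* lesion is the largest by MTV; ties break to the higher
  intensity sum, then the lower lesion id, so output is deterministic.
* **Heterogeneity** — all-pairs absolute difference sums of lesion volumes
  and SUVmax (computed by the `O(n log n)` sorted-prefix identity),
  bulk-anchored difference sums, and highest-lowest ranges. The bulk volume
  difference sum uses signed `bulk - other` differences (non-negative by
  construction); the intensity analogue uses absolute values because the
  bulk lesion need not carry the peak SUVmax.
* **Dissemination** — Dmax (max centroid-pair distance), DmaxVox (max
  voxel-pair distance pooled across *and within* lesions, so single-lesion
  patients report their maximum chord), and max centroid distances from the
  bulk and smallest lesions. Both bulk-distance features are computed
  centroid-wise. DmaxVox is exact: interior voxels (all six face neighbours
  present) cannot be extreme points, so they are pruned and the remainder
  scanned blockwise.

All coordinates are world mm (voxel centres); volumes are ml. Centroids are
unweighted because the feature definitions refer to geometry, not uptake.

## The embedding and the index

The feature matrix is z-scored per column (constant columns dropped with a
warning). On the standardized matrix we build a k-nearest-neighbour graph
(default k = 20, union symmetrization to preserve connectivity at small n)
with a locally adaptive kernel: the per-patient scale `sigma_i` is half the
distance to the k-th neighbour and the affinity is
`exp(-d_ij^2 / (sigma_i^2 + sigma_j^2))`. This is the simplest locally
scaled kernel; a variant with the dimension-dependent prefactor of some
published local kernels is available (`prefactor = TRUE`) and the stability
suite shows the ordering is insensitive to the toggle. Density is removed by
the anisotropic alpha = 1 normalization (dividing by the product of row
sums) — standard in trajectory inference, where sampling density is not
informative — and the result is row-normalized to a Markov operator. Its
eigendecomposition goes through the symmetric conjugate
`D^{1/2} P D^{-1/2}` for numerical stability; the trivial eigenpair
(eigenvalue 1, constant eigenvector) is excluded, and DC1 is the
eigenvector of the largest non-trivial eigenvalue.

Diffusion components are defined up to sign, so every consumer of the
embedding is sign-invariant by contract. DC1 is oriented by its Spearman
correlation with tMTV (low DC1 = low burden); if that correlation is
negligible (|rho| < 0.05) the orientation falls back to DmaxVox, and if that
too is ambiguous the fit stops and asks for an explicit orientation. The
trajectory root is the patient with the lowest oriented DC1. MPI is the
average rank along oriented DC1 mapped to `(rank - 1) / (n - 1)`: ranks
rather than raw DC1 values are rescaled, which makes the index
distribution-free and invariant to any strictly increasing transform of
DC1. Rescaling the raw DC1 values instead is available as
`rescale = "dc1"`; on synthetic cohorts the two orderings correlate above
0.99. A disconnected kNN graph is a hard error by default (pseudotime
across disconnected components is ill-defined), with an explicit
largest-component override for exploration.

## The synthetic cohort generator

No patient-level data accompany the published cohort, so validation runs on
synthetic cohorts with a known severity axis. Each patient draws a latent
severity `s ~ U(0, 1)` which drives, with defaults chosen to resemble an
extensive-stage SCLC cohort at n = 83:

* lesion count `1 + Poisson(1.5 + 6 s)` (median about 4-8);
* a bulk lesion volume, lognormal with median `30 * exp(4 s)` ml (sdlog
  0.6), and metastasis volumes lognormal with median `0.5 * exp(3 s)` ml
  (sdlog 1.0) — total burden in the hundreds of ml at mid-severity, within
  an order of magnitude of published cohort medians;
* placement of metastases in a body-sized cylinder (radius 150 mm, height
  1000 mm) with surface clearance from the bulk lesion up to
  `15 + 70 s` mm, spheres rejected on overlap — so dissemination grows
  with severity;
* a patient-level peak SUVmax, lognormal (median 15, sdlog 0.35) and
  *independent of severity*, assigned to the bulk lesion, with metastasis
  SUVmax uniform between just above threshold and the peak. This mirrors
  the published null association of tSUVmax with outcome and keeps the
  "MPI is more than burden/intensity" checks meaningful;
* bone metastasis with probability `plogis(-0.523 + 1.5 s)` (prevalence
  about 55%);
* 12-month death `Bernoulli(plogis(-0.380 + 3 s))`, whose intercept was
  solved by numeric integration so the marginal mortality is 72.3%;
* overall survival from a Weibull model with shape 1.3, baseline scale
  10.88 months and log-hazard slope 1.2 in s, the scale solved so the
  cohort Kaplan-Meier median is 6.2 months under administrative censoring
  at 24 months. The survival time is drawn *conditionally* on the 12-month
  status (inverse-CDF truncation at 12 months), which keeps the logistic
  mortality marginal exact while respecting the consistency constraint
  that 12-month deaths have events before 12 months.

A `noise_scale` multiplier inflates every lognormal sd for
stress-testing; stability degrades monotonically along that ladder.

Two fidelities exist. The *geometry* path computes features in closed form
from the sphere model: SUV decays linearly from SUVmax at the centre to the
threshold at the boundary, so SUVmean = thr + (SUVmax - thr)/4, and DmaxVox
is the centre distance plus both radii (or one diameter within a lesion).
The *raster* path renders each lesion as the N nearest voxel centres to its
centre (N = volume / voxel volume, default 4 mm isotropic voxels), with the
same linear SUV profile and a random sub-threshold background, then runs
segmentation and voxel-level extraction end-to-end. The two paths agree
within one voxel volume per lesion for volumes and one voxel diagonal for
distances, which is the discretization limit. The generator does not model
respiratory motion, partial-volume effects, scanner noise, physiological
uptake, or non-spherical lesions — so passing tests demonstrate that the
*method* recovers a latent ordering under realistic marginals, not that it
would do so on any particular scanner's images.

## Stability and prognostic evaluation

The robustness suite mirrors a full internal validation: 300 iterations of
80% subsampling without replacement (the entire derivation, including
z-scoring, rerun inside each subsample — the stricter choice; frozen
scaling is a flag), a k sweep over 10-30 against the k = 20 reference,
re-derivation after ablating Dmax and DmaxVox, and an alternative root rule
anchored on the minimal-tMTV patient. All reports store per-iteration
values, not only summaries, and are bitwise reproducible under a seed.

Prognostics use standard machinery with explicit conventions: Mann-Whitney
univariable p-values with AUC = U/(n1 n0) and DeLong intervals; logistic
models with Wald intervals; a paired DeLong test via structural components;
likelihood-ratio tests on nested fits; Harrell's bootstrap optimism
correction with outcome-stratified resampling (avoids single-class
resamples at n = 83 with about 72% events); decile calibration; Kaplan-Meier
medians defined as the earliest time survival reaches 0.5, with log-log
intervals; Cox regression with Efron ties and Harrell's C-index; and VIF as
`1 / (1 - R^2)`. Effects of 0-1 scaled covariates are also reported per
0.1 unit as `exp(0.1 * beta)` — the definitional conversion; published
per-0.1 hazard ratios are not always internally consistent with their full-
scale counterparts (`exp(log(3.31)/10)` is 1.13, not 1.09), and this package
always reports the definitional value.

## Problem sizes and numerical choices

The validation suites run cohorts of 40-83 patients, 300 subsample
embeddings, 50-seed sweeps for latent recovery and model comparison, and
1000 null simulations for likelihood-ratio calibration — sizes at which
every result in the test suite recomputes in minutes on a single core.
Dense eigendecomposition is used throughout (n is at most a few hundred;
approximate neighbour search and Nystrom extension are out of scope).
Degenerate inputs have defined behaviour: empty segmentations are explicit
"no disease" results, constant features are dropped before embedding, a
constant DC1 is an error, ties receive average ranks, and duplicated
patients receive adjacent (tied up to numerical symmetry) MPI values.

## Known limitations

MPI is a cohort-relative rank: it does not transfer across cohorts without
re-embedding, and there is no out-of-sample extension. Branching
trajectories and longitudinal change are out of scope. The generator's
spherical-lesion geometry makes the voxel-level dissemination features
nearly deterministic functions of the configuration; real lesions are
irregular, and the raster path only bounds, not reproduces, that
irregularity.

One structural limitation deserves emphasis. The twenty features are
deterministic functions of a four-channel generative model (bulk volume,
metastasis volumes, lesion count, placement), so the two strongest
conventional features — tMTV and DmaxVox — jointly carry nearly all of the
recoverable severity information in synthetic cohorts, and DmaxVox itself
pools the burden and dispersion channels. The synthetic experiments
therefore reproduce the *direction* of outcome associations (higher MPI in
the deceased group, positive hazard in severity) and the stability of the
ordering, but a multivariable model on the two conventional features is
about as discriminative as the MPI model on these cohorts. Published
cohorts, where a manifold index clearly outperformed two-feature
conventional models, differ plausibly through feature-specific measurement
noise of real semi-automatic segmentation — noise this generator does not
model, since its features are computed exactly from geometry.
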