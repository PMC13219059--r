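# petmpi

Whole-body FDG-PET in widely metastatic cancer yields many prognostic
parameters — metabolic tumour volume, total lesion glycolysis, SUV
statistics, lesion-to-lesion dissemination distances — that are strongly
collinear and individually incomplete. `petmpi` is for imaging researchers
who want a single, data-driven severity coordinate: it computes a
**Metabolic Progression Index (MPI)**, a pseudotime obtained by embedding a
cohort's PET feature matrix with a diffusion map and rank-rescaling the
first diffusion component to [0, 1].

## The method

For each patient, lesions are segmented as 26-connected components of
voxels with SUV > 2.5, and 20 features are computed in four families:
global burden (tMTV = Σᵢ MTVᵢ, tTLG = Σᵢ MTVᵢ·SUVmeanᵢ, intensity sums),
dominant-lesion descriptors (MTV_Bulk, MTV_Smallest, tSUVmax,
MaxIntensity_Min), inter-lesional heterogeneity (all-pairs and
bulk-anchored absolute difference sums of volumes and SUVmax), and spatial
dissemination (Dmax over centroids, DmaxVox = max ‖vᵢ − vⱼ‖ over all tumour
voxels, bulk- and smallest-lesion centroid distances).

The n × 20 matrix is z-scored and embedded with a diffusion map: a
k-nearest-neighbour graph (k = 20, union symmetrization) with a locally
adaptive kernel

  W(i,j) = exp( −d²(i,j) / (σᵢ² + σⱼ²) ),  σᵢ = ½ · d(i, i-th k-NN),

density-corrected with the anisotropic α = 1 normalization and
row-normalized to a Markov operator P. DC1, the eigenvector of the largest
non-trivial eigenvalue of P, is oriented so it correlates positively with
tMTV; the root is the patient with the lowest oriented DC1, and

  MPI = (rank(DC1) − 1) / (n − 1) ∈ [0, 1].

Because no patient-level data accompany published cohorts, the package
ships a synthetic cohort generator in which one latent severity
s ~ U(0, 1) drives lesion count, volumes, dissemination, bone metastases,
12-month mortality (logistic in s, 72% marginal) and overall survival
(Weibull, median ≈ 6 months), while peak SUVmax is severity-independent.
Stability analyses (300 × 80% subsampling, k sweep 10–30, ablation of
Dmax/DmaxVox, alternative roots) and prognostic analyses (Mann–Whitney
screening, predefined logistic models, paired DeLong, likelihood-ratio,
bootstrap optimism correction, decile calibration, Kaplan–Meier, Cox with
C-index, VIF, a second-order polynomial comparator) mirror a complete
study workflow.

## Worked example

```r
library(petmpi)

coh <- simulate_cohort(cohort_params(n_patients = 83, seed = 1))
fm  <- cohort_features(coh)          # 83 x 20 feature matrix
fit <- mpi(fm, k = 20)
fit
#> Metabolic Progression Index fit
#>   n = 83 | k = 20 | rescale = rank
#>   root: P055 | orientation anchor: tMTV (|rho| = 0.85)

cor(fit$mpi, coh$outcomes$severity, method = "spearman")
#> [1] 0.8107342

mpi_k_sensitivity(fm, k_values = 10:30)
#> MPI stability - k_sensitivity
#>   median 0.9980 | min 0.9872 | max 1.0000  (21 values)

km_median(coh$outcomes$time_months, coh$outcomes$event)$median
#> [1] 7.157451
```

The fit reports the trajectory root (the lowest-burden patient) and the
orientation anchor. On this seeded cohort the MPI ordering recovers the
generator's latent severity at Spearman ρ = 0.81, the ordering is almost
unchanged across neighbourhood sizes 10–30 (minimum |ρ| = 0.987 against
k = 20), and the Kaplan–Meier median survival is 7.2 months (the
generator's population target is 6.2; n = 83 sampling noise moves single
cohorts around it).

`mpi_pipeline(mpi_config(seed = 1), "out/")` runs
simulate → extract → embed → MPI → stability → prognostics end-to-end and
writes CSV/JSON artefacts.

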