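# Shared fixtures built in code.

# Two-lesion worked example: lesion A has voxels (0,0,0) SUV 4 and (4,0,0)
# SUV 6; lesion B has one voxel (0,30,0) SUV 8; voxel volume 0.064 ml.
two_lesion_set <- function() {
  lesion_set("W01",
             list(list(lesion_id = 1L,
                       coords = rbind(c(0, 0, 0), c(4, 0, 0)),
                       suv = c(4, 6)),
                  list(lesion_id = 2L,
                       coords = rbind(c(0, 30, 0)),
                       suv = 8)),
             voxel_volume_ml = 0.064)
}

# Hand-computed expected feature vector for two_lesion_set()
two_lesion_expected <- function() c(
  tMTV = 0.192, tTLG = 1.152, Intensity_Sum = 18, MeanIntensity_Sum = 13,
  Volume_intensity_sum = 0.128 * 10 + 0.064 * 8,
  MTV_Bulk = 0.128, MTV_Smallest = 0.064, tSUVmax = 8, MaxIntensity_Min = 6,
  Volume_DiffSum = 0.064, Bulk_Volume_DiffSum = 0.064,
  BulkSmallest_Volume_Diff = 0.064, MaxIntensity_DiffSum = 2,
  HighestLowest_MaxIntensity_Diff = 2, Bulk_MaxIntensity_DiffSum = 2,
  DmaxVox = sqrt(916), Dmax = sqrt(904), BulkDmax = sqrt(904),
  BulkCentroidCoor_DistMax = sqrt(904),
  SmallestCentroidCoor_DistMax = sqrt(904))

# small default synthetic cohort + features, memoised per test file
small_cohort <- function(n = 40, seed = 7, ...) {
  simulate_cohort(cohort_params(n_patients = n, seed = seed, ...))
}

# naive O(N^2) max pairwise distance oracle
brute_max_dist <- function(xyz) {
  n <- nrow(xyz)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- max(best, sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  sqrt(best)
}

# brute-force AUC by pair counting with ties at half weight
brute_auc <- function(score, y) {
  xs <- score[y == 1]; ys <- score[y == 0]
  num <- 0
  for (a in xs) num <- num + sum(a > ys) + 0.5 * sum(a == ys)
  num / (length(xs) * length(ys))
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
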