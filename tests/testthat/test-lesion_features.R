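test_that("two-lesion worked example reproduces the hand-computed features", {
  f <- compute_features(two_lesion_set())
  expect_equal(f, two_lesion_expected()[pet_feature_names()], tolerance = 1e-12)
})

test_that("segmentation groups supra-threshold voxels by 26-connectivity", {
  arr <- array(0, dim = c(9, 5, 5))
  arr[1:3, 2, 2] <- c(4, 5, 6)   # blob 1: 3 voxels
  arr[4, 2, 2] <- 2.0            # sub-threshold gap
  arr[5:6, 2, 2] <- c(7, 8)      # blob 2: 2 voxels
  img <- suv_image(arr, spacing = c(4, 4, 4))
  ls <- segment_lesions(img, 2.5)
  expect_length(ls$lesions, 2)
  expect_setequal(vapply(ls$lesions, function(l) nrow(l$coords), integer(1)),
                  c(3L, 2L))

  # exactly-at-threshold voxels are excluded (strictly-above rule)
  arr2 <- array(2.5, dim = c(3, 3, 3))
  expect_length(segment_lesions(suv_image(arr2, c(4, 4, 4)))$lesions, 0)

  # corner contact joins under 26-connectivity
  arr3 <- array(0, dim = c(4, 4, 4))
  arr3[2, 2, 2] <- 5
  arr3[3, 3, 3] <- 5
  expect_length(segment_lesions(suv_image(arr3, c(4, 4, 4)))$lesions, 1)

  # min_voxels drops small components
  ls4 <- segment_lesions(img, 2.5, min_voxels = 3)
  expect_length(ls4$lesions, 1)
})

test_that("world coordinates are voxel centres offset by the origin", {
  arr <- array(0, dim = c(3, 3, 3)); arr[2, 1, 3] <- 5
  ls <- segment_lesions(suv_image(arr, spacing = c(2, 3, 4),
                                  origin = c(10, 20, 30)), 2.5)
  expect_equal(as.numeric(ls$lesions[[1]]$coords),
               c(10 + 1 * 2, 20 + 0 * 3, 30 + 2 * 4))
})

test_that("per-lesion summaries follow their defining identities", {
  ls <- lesion_set("S", list(list(lesion_id = 1L,
                                  coords = rbind(c(0, 0, 0), c(4, 0, 0)),
                                  suv = c(4, 6))), 0.064)
  s <- summarize_lesions(ls)
  expect_equal(s$MTV, 0.128)
  expect_equal(s$SUVmean, 5)
  expect_equal(s$TLG, 0.64)
  expect_equal(s$SUVmax, 6)

  # single voxel: mean = max, centroid = the voxel
  ls1 <- lesion_set("S", list(list(lesion_id = 1L,
                                   coords = rbind(c(1, 2, 3)), suv = 8)), 0.064)
  s1 <- summarize_lesions(ls1)
  expect_equal(s1$SUVmean, s1$SUVmax)
  expect_equal(c(s1$cx, s1$cy, s1$cz), c(1, 2, 3))

  # TLG = MTV x SUVmean exactly on random lesions
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:20, 1)
    lsr <- lesion_set("R", list(list(lesion_id = 1L,
                                     coords = matrix(runif(3 * n, 0, 100), n),
                                     suv = runif(n, 2.6, 20))), 0.064)
    sr <- summarize_lesions(lsr)
    expect_equal(sr$TLG, sr$MTV * sr$SUVmean, tolerance = 1e-12)
  }
  expect_error(summarize_lesions(lesion_set("E", list(), 0.064)), "empty")
})

test_that("DmaxVox is the exact pooled max pairwise distance", {
  ls <- lesion_set("D", list(list(lesion_id = 1L,
                                  coords = rbind(c(0, 0, 0), c(3, 4, 0)),
                                  suv = c(3, 3))), 0.064)
  expect_equal(dmax_vox(ls), 5)

  ls1 <- lesion_set("D", list(list(lesion_id = 1L,
                                   coords = rbind(c(5, 5, 5)), suv = 3)), 0.064)
  expect_equal(dmax_vox(ls1), 0)

  set.seed(8)
  xyz <- matrix(runif(500 * 3, 0, 200), 500)
  ls2 <- lesion_set("D", list(list(lesion_id = 1L, coords = xyz,
                                   suv = rep(3, 500))), 0.064)
  expect_equal(dmax_vox(ls2), brute_max_dist(xyz), tolerance = 1e-12)

  # blocked BLAS path (> 2000 points) agrees with the naive scan
  xyz3 <- matrix(rnorm(2500 * 3, sd = 50), 2500)
  expect_equal(petmpi:::max_pair_dist(xyz3), max(dist(xyz3)),
               tolerance = 1e-10)
})

test_that("pairwise difference sums match the quadratic oracle", {
  set.seed(5)
  for (rep in 1:10) {
    x <- runif(sample(2:40, 1), 0, 100)
    brute <- sum(abs(outer(x, x, "-"))[upper.tri(outer(x, x, "-"))])
    expect_equal(petmpi:::pair_abs_diff_sum(x), brute, tolerance = 1e-9)
  }
})

test_that("features are invariant under rigid rotation and translation", {
  ls <- two_lesion_set()
  Q <- random_rotation(3)
  shift <- c(17, -42, 8)
  rot <- lesion_set("W01r", lapply(ls$lesions, function(l) {
    list(lesion_id = l$lesion_id,
         coords = sweep(l$coords %*% t(Q), 2, shift, "+"),
         suv = l$suv)
  }), ls$voxel_volume_ml)
  expect_equal(compute_features(rot), compute_features(ls), tolerance = 1e-9)
})

test_that("single-lesion and duplicate-lesion degenerate cases", {
  ls1 <- lesion_set("S", list(list(lesion_id = 1L,
                                   coords = rbind(c(0, 0, 0), c(6, 0, 0)),
                                   suv = c(4, 7))), 0.064)
  f1 <- compute_features(ls1)
  zero_feats <- c("Volume_DiffSum", "Bulk_Volume_DiffSum",
                  "BulkSmallest_Volume_Diff", "MaxIntensity_DiffSum",
                  "HighestLowest_MaxIntensity_Diff",
                  "Bulk_MaxIntensity_DiffSum", "Dmax", "BulkDmax",
                  "BulkCentroidCoor_DistMax", "SmallestCentroidCoor_DistMax")
  expect_true(all(f1[zero_feats] == 0))
  expect_equal(unname(f1["DmaxVox"]), 6)  # within-lesion chord

  # identical lesions at different sites: no heterogeneity, real dissemination
  mk <- function(center) list(lesion_id = NULL,
                              coords = rbind(center, center + c(4, 0, 0)),
                              suv = c(4, 6))
  a <- mk(c(0, 0, 0)); a$lesion_id <- 1L
  b <- mk(c(0, 50, 0)); b$lesion_id <- 2L
  f2 <- compute_features(lesion_set("T", list(a, b), 0.064))
  expect_equal(unname(f2["Volume_DiffSum"]), 0)
  expect_equal(unname(f2["MaxIntensity_DiffSum"]), 0)
  expect_gt(f2["Dmax"], 0)
  expect_gt(f2["DmaxVox"], f2["Dmax"])
})

test_that("tMTV and tTLG are additive over disjoint lesion-set unions", {
  a <- two_lesion_set()
  b <- lesion_set("W02", list(list(lesion_id = 1L,
                                   coords = rbind(c(100, 0, 0)), suv = 5)),
                  0.064)
  merged <- lesion_set("U", c(a$lesions,
                              lapply(b$lesions, function(l) {
                                l$lesion_id <- l$lesion_id + 10L; l
                              })), 0.064)
  fa <- compute_features(a); fb <- compute_features(b)
  fm <- compute_features(merged)
  expect_equal(unname(fm["tMTV"]), unname(fa["tMTV"] + fb["tMTV"]))
  expect_equal(unname(fm["tTLG"]), unname(fa["tTLG"] + fb["tTLG"]))
})
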