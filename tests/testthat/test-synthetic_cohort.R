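test_that("generator is deterministic and satisfies its invariants", {
  p <- cohort_params(n_patients = 30, seed = 11)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(a$outcomes, b$outcomes)

  les <- as.data.frame(a)
  expect_true(all(les$volume_ml > 0))
  expect_true(all(les$suvmax > p$suv_threshold))
  nl <- table(les$patient_id)
  expect_true(all(nl >= 1))

  o <- a$outcomes
  expect_true(all(o$time_months > 0 & o$time_months <= p$admin_censor_months))
  dead <- o$dead_12mo == 1
  expect_true(all(o$event[dead] == 1))
  expect_true(all(o$time_months[dead] <= 12))
  expect_true(all(o$time_months[!dead] > 12))
})

test_that("lesions are non-overlapping spheres inside the body cylinder", {
  coh <- small_cohort(25, seed = 3)
  for (p in coh$patients) {
    les <- p$lesions
    expect_true(all(sqrt(les$x_mm^2 + les$y_mm^2) <= 150 + 1e-9))
    expect_true(all(abs(les$z_mm) <= 500))
    if (nrow(les) > 1) {
      d <- as.matrix(dist(les[, c("x_mm", "y_mm", "z_mm")]))
      rr <- outer(les$radius_mm, les$radius_mm, "+")
      off <- upper.tri(d)
      expect_true(all(d[off] >= rr[off] - 1e-9))
    }
  }
})

test_that("zero severity slopes decouple features from severity", {
  p <- cohort_params(n_patients = 200, seed = 5,
                     lesion_rate = c(base = 4, slope = 0),
                     bulk_volume = c(base_ml = 30, log_slope = 0, log_sd = 0.6),
                     met_volume = c(base_ml = 0.5, log_slope = 0, log_sd = 1),
                     dispersion = c(base_mm = 50, slope_mm = 0))
  coh <- simulate_cohort(p)
  fm <- cohort_features(coh)
  s <- coh$outcomes$severity
  # null Spearman at n = 200 has sd ~ 1/sqrt(199) ~ 0.071; 3 sd bound
  for (f in c("tMTV", "DmaxVox", "tSUVmax", "Dmax")) {
    expect_lt(abs(cor(s, fm[[f]], method = "spearman")), 0.22)
  }
})

test_that("empirical 12-month mortality matches the analytic logistic integral", {
  p <- cohort_params(n_patients = 2000, seed = 21)
  coh <- simulate_cohort(p)
  b0 <- p$outcome_logit[["intercept"]]; b1 <- p$outcome_logit[["slope"]]
  mu <- integrate(function(s) plogis(b0 + b1 * s), 0, 1)$value
  se <- sqrt(mu * (1 - mu) / 2000)  # unconditional Bernoulli SE
  expect_lt(abs(mean(coh$outcomes$dead_12mo) - mu), 2 * se)
})

test_that("default coupling: burden and dissemination rise with severity, peak SUV does not", {
  coh <- small_cohort(500, seed = 13)
  fm <- cohort_features(coh)
  s <- coh$outcomes$severity
  expect_gt(cor(s, fm$tMTV, method = "spearman"), 0.5)
  expect_gt(cor(s, fm$DmaxVox, method = "spearman"), 0.5)
  expect_lt(abs(cor(s, fm$tSUVmax, method = "spearman")), 0.2)
  # bone metastases become more likely with severity
  expect_gt(cor(s, coh$outcomes$bone_met, method = "spearman"), 0)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(cohort_params(n_patients = 2), "n_patients")
  expect_error(cohort_params(admin_censor_months = 6), "admin_censor")
  expect_error(cohort_params(bulk_volume = c(base_ml = -1, log_slope = 1,
                                             log_sd = 0.5)), "positive")
})

test_that("rasterization renders the prescribed voxel count and peak SUV", {
  vox_ml <- 0.064  # 4 mm isotropic
  patient <- list(patient_id = "T1", severity = 0.5,
                  lesions = data.frame(lesion_id = 1L, x_mm = 2, y_mm = 1,
                                       z_mm = 0,
                                       volume_ml = 8 * vox_ml,
                                       radius_mm = sphere_radius_mm(8 * vox_ml),
                                       suvmax = 9))
  img <- rasterize_patient(patient, spacing_mm = 4, background = "zero")
  expect_equal(sum(img$values > 2.5), 8)
  expect_equal(max(img$values), 9)  # peak SUV at the centre voxel

  ls <- segment_lesions(img, 2.5, patient_id = "T1")
  expect_length(ls$lesions, 1)
  expect_equal(nrow(ls$lesions[[1]]$coords), 8)
})

test_that("background-only image segments to an explicit empty lesion set", {
  img <- suv_image(array(runif(4^3, 0, 2), dim = c(4, 4, 4)),
                   spacing = c(4, 4, 4))
  ls <- segment_lesions(img, 2.5)
  expect_s3_class(ls, "lesion_set")
  expect_length(ls$lesions, 0)
})

test_that("geometry fast path agrees with the rasterized path", {
  coh <- small_cohort(6, seed = 17)
  fm_geo <- cohort_features(coh, method = "geometry")
  set.seed(1)
  fm_ras <- cohort_features(coh, method = "raster")
  vox_ml <- attr(fm_ras, "voxel_volume_ml")
  diag_mm <- sqrt(3) * coh$params$voxel_spacing_mm
  nles <- vapply(coh$patients, function(p) nrow(p$lesions), integer(1))
  # one voxel volume per lesion for volumes, one voxel diagonal for distances
  expect_true(all(abs(fm_geo$tMTV - fm_ras$tMTV) <= nles * vox_ml + 1e-9))
  expect_true(all(abs(fm_geo$DmaxVox - fm_ras$DmaxVox) <= diag_mm + 1e-9))
  expect_true(all(abs(fm_geo$tSUVmax - fm_ras$tSUVmax) < 1e-9))
})
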