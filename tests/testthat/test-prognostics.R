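test_that("AUC equals brute-force pair counting, including ties", {
  set.seed(20)
  for (rep in 1:5) {
    n <- 40
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    score <- sample(round(rnorm(n), 1))  # rounded -> ties
    expect_equal(auc_mw(score, y), brute_auc(score, y), tolerance = 1e-12)
  }
  # degenerate and perfect cases
  y <- c(1, 1, 0, 0)
  expect_equal(auc_mw(c(9, 8, 2, 1) / 10, y), 1.0)
  expect_equal(auc_mw(c(9, 1, 8, 2) / 10, y), 0.5)
  expect_equal(auc_mw(rep(1, 4), y), 0.5)  # constant score, all ties
  expect_error(auc_mw(1:4, rep(1, 4)), "non-empty")
})

test_that("univariable screen returns MW p-values and DeLong intervals", {
  set.seed(3)
  d <- data.frame(dead_12mo = rep(c(1, 0), each = 20),
                  strong = c(rnorm(20, 3), rnorm(20, 0)),
                  null = rnorm(40))
  scr <- univariable_screen(d, c("strong", "null"))
  expect_equal(nrow(scr), 2)
  expect_lt(scr$p[1], 0.001)
  expect_gt(scr$auc[1], 0.85)
  expect_true(scr$auc_lo[1] <= scr$auc[1] & scr$auc[1] <= scr$auc_hi[1])
  expect_error(univariable_screen(data.frame(dead_12mo = rep(1, 5), x = 1:5)),
               "non-empty")
})

test_that("logistic report matches the closed-form 2x2 odds ratio", {
  # exposed: 8/10 events; unexposed: 2/10 -> OR (8*8)/(2*2) = 16
  d <- data.frame(y = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)),
                  x = c(rep(1, 10), rep(0, 10)))
  f <- fit_logistic(y ~ x, d)
  expect_equal(f$table$or[f$table$term == "x"], 16, tolerance = 1e-6)
  # per-0.1 odds ratio is definitional
  expect_equal(f$table$or_per_0.1, exp(0.1 * f$table$coef), tolerance = 1e-12)

  # intercept-only model predicts the event rate
  f0 <- fit_logistic(y ~ 1, d)
  expect_equal(unique(round(f0$fitted, 10)), 0.5)

  # perfect separation is an explicit error naming the covariate
  ds <- data.frame(y = rep(c(0, 1), each = 10), z = rep(c(0, 1), each = 10))
  expect_error(fit_logistic(y ~ z, ds), "separation")
})

test_that("paired DeLong comparison: identity, oracle and symmetry", {
  set.seed(30)
  n <- 60
  y <- rep(c(1, 0), c(25, 35))
  p1 <- plogis(2 * y + rnorm(n))
  p2 <- plogis(1 * y + rnorm(n))
  # identical predictors: no difference
  r0 <- delong_compare(p1, p1, y)
  expect_equal(r0$delta, 0)
  expect_equal(r0$p, 1)
  # symmetry in model order
  r12 <- delong_compare(p1, p2, y)
  r21 <- delong_compare(p2, p1, y)
  expect_equal(r12$p, r21$p, tolerance = 1e-12)
  expect_equal(r12$delta, -r21$delta, tolerance = 1e-12)
  expect_equal(r12$auc1, auc_mw(p1, y), tolerance = 1e-12)

  # variance vs jackknife-of-structural-components oracle on n = 12
  y12 <- rep(c(1, 0), each = 6)
  s1 <- c(.9, .8, .7, .65, .4, .35, .6, .5, .45, .3, .2, .1)
  s2 <- c(.85, .6, .75, .5, .55, .3, .7, .45, .65, .25, .35, .15)
  r <- delong_compare(s1, s2, y12)
  jack <- vapply(1:12, function(i) {
    di <- auc_mw(s1[-i], y12[-i]) - auc_mw(s2[-i], y12[-i])
  }, numeric(1))
  v_jack <- (11 / 12) * sum((jack - mean(jack))^2)
  expect_lt(abs(r$var_delta - v_jack) / v_jack, 0.10)

  # cross-check p-value against the reference implementation
  ref <- pROC::roc.test(pROC::roc(y12, s1, quiet = TRUE),
                        pROC::roc(y12, s2, quiet = TRUE), method = "delong")
  expect_equal(r$p, unname(ref$p.value), tolerance = 1e-8)

  # both models perfect: degenerate variance is an error, not p = 0
  expect_error(delong_compare(y12 + 0, y12 * 2, y12), "degenerate")
})

test_that("likelihood-ratio test on nested logistic models", {
  set.seed(8)
  d <- data.frame(y = rbinom(80, 1, 0.5), x = rnorm(80))
  d$y <- rbinom(80, 1, plogis(-0.3 + 1.2 * d$x))
  small <- fit_logistic(y ~ 1, d)
  large <- fit_logistic(y ~ x, d)
  lr <- likelihood_ratio(small, large)
  expect_equal(lr$df, 1)
  expect_gt(lr$delta_deviance, 0)
  expect_equal(lr$p, pchisq(lr$delta_deviance, 1, lower.tail = FALSE))
  # identical models
  lr0 <- likelihood_ratio(small, small)
  expect_equal(lr0$delta_deviance, 0)
  expect_equal(lr0$p, 1)
  # non-nested sets refuse
  d$z <- rnorm(80)
  expect_error(likelihood_ratio(fit_logistic(y ~ z, d), large), "not nested")
  # a strong predictor's deviance gain grows with n
  gains <- vapply(c(100, 400), function(n) {
    set.seed(99)
    x <- rnorm(n); yy <- rbinom(n, 1, plogis(1.5 * x))
    dd <- data.frame(y = yy, x = x)
    likelihood_ratio(fit_logistic(y ~ 1, dd),
                     fit_logistic(y ~ x, dd))$delta_deviance
  }, numeric(1))
  expect_gt(gains[2], gains[1])
})

test_that("bootstrap optimism is reproducible and penalizes overfitting", {
  set.seed(41)
  d <- data.frame(y = rbinom(60, 1, 0.5),
                  matrix(rnorm(60 * 10), 60,
                         dimnames = list(NULL, paste0("n", 1:10))))
  f <- y ~ n1 + n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9 + n10
  a <- bootstrap_optimism(f, d, iterations = 120, seed = 3)
  b <- bootstrap_optimism(f, d, iterations = 120, seed = 3)
  expect_identical(a, b)
  expect_lt(a$corrected, a$apparent)  # pure-noise model must be shrunk
  expect_gt(a$optimism, 0.02)
})

test_that("decile calibration accounts for every patient and flags collapse", {
  set.seed(17)
  pred <- runif(200)
  y <- rbinom(200, 1, pred)
  cal <- calibration_by_decile(pred, y)
  expect_equal(sum(cal$n), 200)
  expect_true(all(diff(cal$mean_pred) > 0))
  expect_false(attr(cal, "collapsed"))

  expect_message(cal1 <- calibration_by_decile(rep(0.4, 50), rbinom(50, 1, .4)),
                 "single group")
  expect_equal(nrow(cal1), 1)
  expect_error(calibration_by_decile(runif(10), rbinom(10, 1, .5)), "n >= 20")
})

test_that("Kaplan-Meier median follows the product-limit definition", {
  # 10 distinct uncensored times: survival crosses 0.5 at the 5th smallest
  t10 <- c(2, 4, 5, 7, 8, 10, 13, 16, 20, 25)
  km <- km_median(t10, rep(1, 10))
  expect_equal(km$median, 8)
  expect_true(km$reached)

  # hand-computed mixed-censoring table: S = .8, .8, .5333, .5333, .2667
  km2 <- km_median(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(km2$median, 5)

  kmn <- km_median(c(5, 6, 7), c(0, 0, 0))
  expect_false(kmn$reached)
})

test_that("Cox report: definitional identities and concordance oracle", {
  set.seed(52)
  n <- 120
  x <- runif(n)
  t <- rexp(n, rate = 0.1 * exp(1.5 * x))
  d <- data.frame(time = t, event = 1, x = x)
  f <- fit_cox(survival::Surv(time, event) ~ x, d)
  expect_equal(f$table$hr, exp(f$table$coef), tolerance = 1e-12)
  expect_equal(f$table$hr_per_0.1, exp(0.1 * f$table$coef), tolerance = 1e-12)

  # no censoring: C-index equals brute-force concordant-pair fraction
  risk <- f$table$coef * x
  conc <- 0; usable <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      usable <- usable + 1
      hi <- if (t[i] < t[j]) i else j  # earlier death = higher risk expected
      lo <- if (t[i] < t[j]) j else i
      conc <- conc + (risk[hi] > risk[lo]) + 0.5 * (risk[hi] == risk[lo])
    }
  }
  expect_equal(f$c_index, conc / usable, tolerance = 1e-9)

  # random scores concord at chance level
  set.seed(5)
  d2 <- data.frame(time = rexp(200), event = 1, x = rnorm(200))
  f2 <- fit_cox(survival::Surv(time, event) ~ x, d2)
  expect_lt(abs(f2$c_index - 0.5), 0.08)
})

test_that("VIF follows the closed form and flags exact collinearity", {
  set.seed(61)
  # orthogonal design: VIF exactly 1
  x1 <- rep(c(-1, 1), 20); x2 <- rep(c(-1, -1, 1, 1), 10)
  expect_equal(unname(vif(cbind(a = x1, b = x2))), c(1, 1), tolerance = 1e-10)

  # correlated pair: VIF = 1 / (1 - rho^2) with the empirical correlation
  z <- rnorm(100); w <- 0.8 * z + 0.6 * rnorm(100)
  v <- vif(cbind(z = z, w = w))
  expect_equal(unname(v), rep(1 / (1 - cor(z, w)^2), 2), tolerance = 1e-9)

  expect_warning(vd <- vif(cbind(u = z, v = 2 * z + 1)), "collinearity")
  expect_true(all(is.infinite(vd)))
})

test_that("polynomial comparator builds squared standardized terms", {
  set.seed(71)
  n <- 600
  d <- data.frame(tMTV = rlnorm(n, 5, 1), DmaxVox = runif(n, 5, 120))
  # linear truth on the standardized scale
  eta <- -0.2 + 0.9 * scale(d$tMTV) + 0.6 * scale(d$DmaxVox)
  d$dead_12mo <- rbinom(n, 1, plogis(eta))
  f <- polynomial_comparator(d)
  sq <- f$table[grepl("_sq", f$table$term), ]
  expect_equal(nrow(sq), 2)
  expect_true(all(abs(sq$coef) < 0.25))  # squared terms vanish under linearity
  expect_error(polynomial_comparator(transform(d, tMTV = 1)), "zero variance")
})
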