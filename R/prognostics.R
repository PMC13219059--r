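#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' AUC equals the normalized Mann-Whitney U: the probability that a random
#' case scores higher than a random control, ties counted one half.
#'
#' @param score Numeric predictor.
#' @param outcome Binary outcome (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(score, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome groups must be non-empty")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: list with auc, V10 (cases), V01 (controls)
delong_components <- function(score, outcome) {
  x <- score[outcome == 1]; y <- score[outcome == 0]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), V10 = rowMeans(psi), V01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong confidence interval for a single AUC
#'
#' Variance from the structural-components decomposition, Wald interval.
#'
#' @inheritParams auc_mw
#' @param conf Confidence level.
#' @return Named vector `auc, lo, hi, se`.
#' @export
delong_auc_ci <- function(score, outcome, conf = 0.95) {
  dc <- delong_components(score, outcome)
  v <- var(dc$V10) / dc$m + var(dc$V01) / dc$n
  z <- qnorm(1 - (1 - conf) / 2)
  c(auc = dc$auc, lo = max(0, dc$auc - z * sqrt(v)),
    hi = min(1, dc$auc + z * sqrt(v)), se = sqrt(v))
}

#' Paired DeLong comparison of two correlated ROC curves
#'
#' Both prediction vectors must be on the same patients. The variance of the
#' AUC difference uses the paired structural-components covariance; the
#' two-sided p-value comes from the normal approximation.
#'
#' @param pred1,pred2 Prediction vectors on the same patients.
#' @param outcome Binary outcome (0/1).
#' @return Object of class `roc_comparison`: `auc1`, `auc2`, `delta`,
#'   `ci` (of the difference), `z`, `p`, `var_delta`.
#' @export
delong_compare <- function(pred1, pred2, outcome) {
  stopifnot(length(pred1) == length(pred2),
            length(pred1) == length(outcome))
  outcome <- as.integer(outcome)
  if (!all(c(0, 1) %in% outcome)) stop("both outcome classes must be present")
  d1 <- delong_components(pred1, outcome)
  d2 <- delong_components(pred2, outcome)
  S10 <- cov(cbind(d1$V10, d2$V10))
  S01 <- cov(cbind(d1$V01, d2$V01))
  vd <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / d1$m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / d1$n
  delta <- d1$auc - d2$auc
  if (vd < 1e-12) {
    if (abs(delta) < 1e-12 && isTRUE(all.equal(pred1, pred2))) {
      return(structure(list(auc1 = d1$auc, auc2 = d2$auc, delta = 0,
                            ci = c(0, 0), z = 0, p = 1, var_delta = 0),
                       class = "roc_comparison"))
    }
    stop("degenerate DeLong variance (identical or perfectly separating ",
         "predictors); comparison undefined")
  }
  z <- delta / sqrt(vd)
  structure(list(auc1 = d1$auc, auc2 = d2$auc, delta = delta,
                 ci = delta + qnorm(c(.025, .975)) * sqrt(vd),
                 z = z, p = 2 * pnorm(-abs(z)), var_delta = vd),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUC1 %.3f vs AUC2 %.3f\n", x$auc1, x$auc2))
  cat(sprintf("  dAUC %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$delta, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Univariable screening of features against a binary outcome
#'
#' For each feature: two-group Mann-Whitney (Wilcoxon rank-sum) p-value, AUC
#' as normalized U, and a DeLong confidence interval.
#'
#' @param data Data frame containing the features and the outcome column.
#' @param features Character vector of feature columns (defaults to all
#'   numeric columns other than the outcome).
#' @param outcome Name of the binary outcome column.
#' @return Data frame: `feature, median_pos, median_neg, p, auc, auc_lo,
#'   auc_hi`, ordered as given.
#' @export
univariable_screen <- function(data, features = NULL, outcome = "dead_12mo") {
  y <- as.integer(data[[outcome]])
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both outcome groups must be non-empty")
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        outcome)
  }
  rows <- lapply(features, function(f) {
    v <- data[[f]]
    p <- suppressWarnings(wilcox.test(v[y == 1], v[y == 0])$p.value)
    ci <- delong_auc_ci(v, y)
    data.frame(feature = f, median_pos = median(v[y == 1]),
               median_neg = median(v[y == 0]), p = p,
               auc = ci["auc"], auc_lo = ci["lo"], auc_hi = ci["hi"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Multivariable logistic regression report
#'
#' Maximum-likelihood logistic fit with Wald confidence intervals, odds
#' ratios, deviance and apparent AUC (DeLong CI). For covariates on a 0-1
#' scale (such as MPI) the `or_per_0.1` column gives the definitional
#' per-0.1-unit odds ratio `exp(0.1 * coefficient)`. Perfect separation and
#' non-convergence are explicit errors.
#'
#' @param formula Model formula, binary response on the left.
#' @param data Data frame.
#' @return Object of class `mpi_logit`: `table` (term, coef, se, or, ci,
#'   p, or_per_0.1), `deviance`, `null_deviance`, `df_residual`, `auc`
#'   (with CI), `fitted` (in-sample probabilities), `model` (the glm), `n`.
#' @export
fit_logistic <- function(formula, data) {
  g <- suppressWarnings(glm(formula, data = data, family = binomial()))
  if (!g$converged)
    stop("logistic fit did not converge after ", g$iter, " IRLS iterations")
  pr <- fitted(g)
  cf <- coef(g)
  if ((min(pr) < 1e-8 || max(pr) > 1 - 1e-8) && max(abs(cf[-1])) > 15) {
    culprit <- names(which.max(abs(cf[-1])))
    stop("perfect (or quasi-) separation detected; covariate '", culprit,
         "' drives fitted probabilities to 0/1")
  }
  se <- sqrt(diag(vcov(g)))
  z <- qnorm(0.975)
  tab <- data.frame(term = names(cf), coef = unname(cf), se = unname(se),
                    or = exp(unname(cf)),
                    or_lo = exp(unname(cf - z * se)),
                    or_hi = exp(unname(cf + z * se)),
                    p = 2 * pnorm(-abs(unname(cf) / unname(se))),
                    or_per_0.1 = exp(0.1 * unname(cf)),
                    row.names = NULL)
  y <- g$y
  auc <- delong_auc_ci(pr, y)
  structure(list(table = tab, deviance = g$deviance,
                 null_deviance = g$null.deviance,
                 df_residual = g$df.residual, auc = auc, fitted = pr,
                 model = g, n = length(y), formula = formula),
            class = "mpi_logit")
}

#' @export
print.mpi_logit <- function(x, ...) {
  cat("Logistic model (n =", x$n, ")\n")
  tab <- x$table
  tab$or <- sprintf("%.3f (%.3f-%.3f)", tab$or, tab$or_lo, tab$or_hi)
  print(tab[, c("term", "coef", "or", "p")], row.names = FALSE, digits = 3)
  cat(sprintf("  deviance %.2f | AUC %.3f (%.3f-%.3f)\n",
              x$deviance, x$auc["auc"], x$auc["lo"], x$auc["hi"]))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic models
#'
#' @param small,large `mpi_logit` fits (or glm objects) on the same
#'   patients; `small`'s covariates must be a subset of `large`'s.
#' @return List: `delta_deviance`, `df`, `p`.
#' @export
likelihood_ratio <- function(small, large) {
  gs <- if (inherits(small, "mpi_logit")) small$model else small
  gl <- if (inherits(large, "mpi_logit")) large$model else large
  if (length(gs$y) != length(gl$y))
    stop("models must be fitted on the same patients")
  ts_ <- attr(terms(gs), "term.labels")
  tl_ <- attr(terms(gl), "term.labels")
  if (!all(ts_ %in% tl_))
    stop("models are not nested: ", paste(setdiff(ts_, tl_), collapse = ", "),
         " absent from the larger model")
  dd <- gs$deviance - gl$deviance
  df <- gs$df.residual - gl$df.residual
  if (df == 0) return(list(delta_deviance = dd, df = 0, p = 1))
  list(delta_deviance = dd, df = df, p = pchisq(dd, df, lower.tail = FALSE))
}

#' Bootstrap optimism-corrected AUC (Harrell's procedure)
#'
#' Refits the model on bootstrap resamples (drawn at patient level,
#' stratified on the outcome so both classes stay present); per-resample
#' optimism is the bootstrap-sample AUC minus the AUC of the bootstrap model
#' evaluated on the original data. Corrected AUC = apparent - mean optimism.
#'
#' @param formula Logistic model formula.
#' @param data Data frame.
#' @param iterations Number of resamples.
#' @param seed Integer seed.
#' @param stratify Resample within outcome classes?
#' @return List: `apparent`, `optimism`, `corrected`, `boot_ci` (percentile
#'   interval of the bootstrap AUCs), `iterations`, `failed`.
#' @export
bootstrap_optimism <- function(formula, data, iterations = 1000, seed = 1L,
                               stratify = TRUE) {
  yname <- all.vars(formula)[1]
  y <- as.integer(data[[yname]])
  apparent_fit <- fit_logistic(formula, data)
  apparent <- unname(apparent_fit$auc["auc"])
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  set.seed(seed)
  opt <- auc_b <- numeric(iterations)
  failed <- 0L
  for (b in seq_len(iterations)) {
    ib <- if (stratify) {
      c(sample(idx1, length(idx1), replace = TRUE),
        sample(idx0, length(idx0), replace = TRUE))
    } else {
      sample.int(nrow(data), replace = TRUE)
    }
    db <- data[ib, , drop = FALSE]
    gb <- tryCatch(suppressWarnings(glm(formula, data = db,
                                        family = binomial())),
                   error = function(e) NULL)
    if (is.null(gb) || !gb$converged) {
      failed <- failed + 1L
      opt[b] <- NA_real_; auc_b[b] <- NA_real_
      next
    }
    auc_b[b] <- auc_mw(fitted(gb), as.integer(db[[yname]]))
    auc_orig <- auc_mw(predict(gb, newdata = data, type = "response"), y)
    opt[b] <- auc_b[b] - auc_orig
  }
  if (failed > 0.05 * iterations)
    stop(failed, " of ", iterations, " bootstrap refits failed to converge")
  list(apparent = apparent, optimism = mean(opt, na.rm = TRUE),
       corrected = apparent - mean(opt, na.rm = TRUE),
       boot_ci = unname(quantile(auc_b, c(.025, .975), na.rm = TRUE)),
       iterations = iterations, failed = failed)
}

#' Grouped calibration by predicted-risk deciles
#'
#' Cuts predictions into (up to) ten quantile groups and tabulates mean
#' predicted risk against the observed event fraction. Heavy ties collapse
#' groups; the result is then flagged via the `collapsed` attribute.
#'
#' @param pred Predicted probabilities.
#' @param outcome Binary outcome.
#' @param groups Target number of groups.
#' @return Data frame `group, n, mean_pred, obs_rate` (ordered by risk)
#'   with attribute `collapsed`.
#' @export
calibration_by_decile <- function(pred, outcome, groups = 10) {
  stopifnot(length(pred) == length(outcome))
  if (length(pred) < 20) stop("need n >= 20 for grouped calibration")
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = groups + 1)))
  collapsed <- length(br) < groups + 1
  if (length(br) < 2) {  # constant predictions: one group
    out <- data.frame(group = 1L, n = length(pred), mean_pred = mean(pred),
                      obs_rate = mean(outcome))
    attr(out, "collapsed") <- TRUE
    message("constant predictions: calibration collapsed to a single group")
    return(out)
  }
  g <- cut(pred, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(group = sort(unique(g)),
                    n = as.vector(table(g)),
                    mean_pred = as.vector(tapply(pred, g, mean)),
                    obs_rate = as.vector(tapply(as.numeric(outcome), g, mean)))
  if (collapsed)
    message("ties collapsed calibration groups: ", nrow(out), " of ", groups)
  attr(out, "collapsed") <- collapsed
  out
}

#' Kaplan-Meier median survival with log-log confidence interval
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = death).
#' @return List: `median`, `lo`, `hi` (NA when not reached), `reached`,
#'   `fit` (the survfit object).
#' @export
km_median <- function(time, event) {
  if (sum(event) < 1) {
    return(list(median = NA_real_, lo = NA_real_, hi = NA_real_,
                reached = FALSE, fit = NULL))
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log-log")
  tb <- summary(sf)$table
  # median = earliest event time at which survival reaches 0.5
  cross <- sf$time[sf$surv <= 0.5 + 1e-12]
  med <- if (length(cross)) min(cross) else NA_real_
  list(median = med, lo = unname(tb["0.95LCL"]), hi = unname(tb["0.95UCL"]),
       reached = is.finite(med), fit = sf)
}

#' Cox proportional-hazards report with concordance
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with Wald
#' intervals, Harrell's C-index on the fitted risk scores, and the
#' definitional per-0.1-unit hazard ratio `exp(0.1 * coefficient)` for 0-1
#' scaled covariates.
#'
#' @param formula `Surv(time, event) ~ covariates`.
#' @param data Data frame.
#' @return Object of class `mpi_cox`: `table` (term, coef, hr, ci, p,
#'   hr_per_0.1), `c_index` (+ se), `n`, `n_events`, `model`.
#' @export
fit_cox <- function(formula, data) {
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("monotone likelihood / non-convergence in Cox fit: ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (fit$nevent < 2) stop("need at least 2 events")
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  tab <- data.frame(term = names(cf), coef = unname(cf), se = unname(se),
                    hr = exp(unname(cf)),
                    hr_lo = exp(unname(cf - z * se)),
                    hr_hi = exp(unname(cf + z * se)),
                    p = 2 * pnorm(-abs(unname(cf) / unname(se))),
                    hr_per_0.1 = exp(0.1 * unname(cf)),
                    row.names = NULL)
  conc <- fit$concordance
  structure(list(table = tab,
                 c_index = unname(conc["concordance"]),
                 c_index_se = unname(conc["std"]),
                 n = fit$n, n_events = fit$nevent, model = fit),
            class = "mpi_cox")
}

#' @export
print.mpi_cox <- function(x, ...) {
  cat("Cox model (n =", x$n, ",", x$n_events, "events)\n")
  tab <- x$table
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$hr_lo, tab$hr_hi)
  print(tab[, c("term", "coef", "hr", "p")], row.names = FALSE, digits = 3)
  cat(sprintf("  C-index %.3f (se %.3f)\n", x$c_index, x$c_index_se))
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF of covariate j is `1 / (1 - R^2)` from regressing j on the remaining
#' covariates. Exact collinearity yields `Inf` with the culprit named in a
#' warning.
#'
#' @param x Data frame or matrix of numeric covariates (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 covariates")
  if (nrow(x) <= ncol(x)) stop("need n > number of covariates")
  out <- vapply(seq_len(ncol(x)), function(j) {
    r2 <- suppressWarnings(
      summary(lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  if (any(is.infinite(out)))
    warning("exact collinearity: ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}

#' Second-order polynomial comparator model
#'
#' Logistic model with linear and squared terms of tMTV and DmaxVox (each
#' z-scored before squaring), the simple nonlinear alternative against which
#' the MPI model is compared.
#'
#' @param data Data frame containing the covariates and outcome.
#' @param outcome Name of the binary outcome column.
#' @param vars The two covariate names.
#' @return An `mpi_logit` fit (AUC included for comparison).
#' @export
polynomial_comparator <- function(data, outcome = "dead_12mo",
                                  vars = c("tMTV", "DmaxVox")) {
  for (v in vars) {
    if (sd(data[[v]]) < 1e-12) stop("covariate '", v, "' has zero variance")
  }
  d <- data.frame(y = as.integer(data[[outcome]]))
  for (v in vars) {
    zv <- as.numeric(scale(data[[v]]))
    d[[v]] <- zv
    d[[paste0(v, "_sq")]] <- zv^2
  }
  fit_logistic(y ~ ., d)
}
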