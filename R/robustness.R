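#' Subsampling stability of the MPI ordering
#'
#' Repeatedly draws subsamples of the cohort without replacement, reruns the
#' full derivation (standardize, diffusion map, orientation, rank-rescale)
#' within each subsample, and reports the absolute Spearman correlation
#' against the full-cohort MPI restricted to the subsampled patients. Means
#' and sds are recomputed per subsample by default, matching a full rerun of
#' the derivation; `refit_scaling = FALSE` freezes the full-cohort scaling.
#'
#' @param x Feature matrix (data frame with `patient_id`, as for [mpi()]).
#' @param fraction Subsample fraction (patients kept).
#' @param iterations Number of subsamples.
#' @param seed Integer seed; the whole analysis is deterministic given it.
#' @param k Neighbourhood size used for both full and subsample fits.
#' @param refit_scaling Recompute z-scoring within each subsample?
#' @param ... Further arguments to [mpi()].
#' @return Object of class `mpi_stability`: `analysis`, `values` (one row
#'   per iteration with `rho_abs`), `summary` (median/min/max), `settings`.
#' @export
mpi_subsample_stability <- function(x, fraction = 0.8, iterations = 300,
                                    seed = 1L, k = 20, refit_scaling = TRUE,
                                    ...) {
  n <- nrow(x)
  m <- floor(fraction * n)
  if (m <= k) stop("subsample size ", m, " must exceed k = ", k)
  full <- mpi(x, k = k, ...)
  full_mpi <- setNames(full$mpi, full$patient_id)
  Zfull <- NULL
  if (!refit_scaling) {
    feats <- as.matrix(x[, setdiff(names(x), "patient_id"), drop = FALSE])
    Zfull <- standardize_features(feats)
    rownames(Zfull) <- as.character(x$patient_id)
  }
  set.seed(seed)
  rho <- numeric(iterations)
  for (it in seq_len(iterations)) {
    idx <- sort(sample.int(n, m))
    sub <- x[idx, , drop = FALSE]
    fit <- if (refit_scaling) {
      mpi(sub, k = k, ...)
    } else {
      mpi_on_standardized(Zfull[idx, , drop = FALSE],
                          as.matrix(sub[, setdiff(names(sub), "patient_id")]),
                          as.character(sub$patient_id), k = k, ...)
    }
    sub_mpi <- setNames(fit$mpi, fit$patient_id)
    common <- intersect(names(sub_mpi), names(full_mpi))
    rho[it] <- abs(suppressWarnings(
      cor(sub_mpi[common], full_mpi[common], method = "spearman")))
  }
  new_stability("subsample", data.frame(iteration = seq_len(iterations),
                                        rho_abs = rho),
                list(fraction = fraction, iterations = iterations,
                     seed = seed, k = k, refit_scaling = refit_scaling))
}

# MPI on a pre-standardized matrix (frozen scaling path)
mpi_on_standardized <- function(Z, feats, ids, k = 20, anchor = "tMTV", ...) {
  op <- build_diffusion_operator(Z, k = k)
  emb <- diffusion_components(op, n_components = 2)
  dc1 <- emb$components[, "DC1"]
  ori <- orient_dc1(dc1, feats, anchor)
  list(mpi = mpi_from_dc1(ori$dc1), patient_id = ids)
}

#' Neighbourhood-size sensitivity of the MPI ordering
#'
#' Derives MPI for each k in `k_values` and reports the absolute Spearman
#' correlation of each ordering against the reference `k_ref` ordering.
#'
#' @param x Feature matrix.
#' @param k_values Integer vector of neighbourhood sizes.
#' @param k_ref Reference k.
#' @param ... Further arguments to [mpi()].
#' @return An `mpi_stability` with one row per k (`k`, `rho_abs`).
#' @export
mpi_k_sensitivity <- function(x, k_values = 10:30, k_ref = 20, ...) {
  if (max(k_values) >= nrow(x)) stop("max(k_values) must be < n")
  ref <- mpi(x, k = k_ref, ...)
  rho <- vapply(k_values, function(kk) {
    fit <- mpi(x, k = kk, ...)
    abs(suppressWarnings(cor(fit$mpi, ref$mpi, method = "spearman")))
  }, numeric(1))
  new_stability("k_sensitivity",
                data.frame(k = k_values, rho_abs = rho),
                list(k_values = k_values, k_ref = k_ref))
}

#' Feature-ablation stability of the MPI ordering
#'
#' Re-derives MPI after removing the named feature columns (by default the
#' two spatial dissemination features, Dmax and DmaxVox) and reports the
#' Spearman and Pearson correlations of the ablated index against the
#' full-feature index.
#'
#' @param x Feature matrix.
#' @param drop Character vector of feature columns to remove.
#' @param anchor Orientation anchor for the ablated fit (must survive the
#'   ablation).
#' @param ... Further arguments to [mpi()].
#' @return An `mpi_stability` with `rho` (Spearman) and `pearson_r`.
#' @export
mpi_feature_ablation <- function(x, drop = c("Dmax", "DmaxVox"),
                                 anchor = "tMTV", ...) {
  feat_cols <- setdiff(names(x), "patient_id")
  missing <- setdiff(drop, feat_cols)
  if (length(missing))
    stop("cannot drop absent column(s): ", paste(missing, collapse = ", "))
  if (length(setdiff(feat_cols, drop)) < 2)
    stop("ablation must leave at least 2 feature columns")
  full <- mpi(x, anchor = anchor, ...)
  abl <- mpi(x[, c("patient_id", setdiff(feat_cols, drop))],
             anchor = anchor, ...)
  rho <- suppressWarnings(cor(full$mpi, abl$mpi, method = "spearman"))
  r <- suppressWarnings(cor(full$mpi, abl$mpi))
  new_stability("feature_ablation",
                data.frame(rho = rho, pearson_r = r),
                list(drop = drop, anchor = anchor))
}

#' Root-rule sensitivity of the MPI ordering
#'
#' Compares the default MPI (root at the lowest oriented DC1) with the index
#' derived under an alternative root/orientation rule.
#'
#' @param x Feature matrix.
#' @param rule `"min_tMTV"` (anchor the orientation to the minimal-tMTV
#'   patient) or `"min_dc1"` (the default rule; comparison with itself).
#' @param ... Further arguments to [mpi()].
#' @return An `mpi_stability` with `rho` (Spearman, signed after
#'   re-orientation).
#' @export
mpi_root_sensitivity <- function(x, rule = "min_tMTV", ...) {
  if (!rule %in% c("min_tMTV", "min_dc1"))
    stop("unknown root rule: ", rule)
  default <- mpi(x, root_rule = "min_dc1", ...)
  alt <- mpi(x, root_rule = rule, ...)
  rho <- suppressWarnings(cor(default$mpi, alt$mpi, method = "spearman"))
  new_stability("root_sensitivity", data.frame(rho = rho),
                list(rule = rule))
}

new_stability <- function(analysis, values, settings) {
  num <- unlist(values[, grep("rho|pearson", names(values)), drop = FALSE])
  structure(list(analysis = analysis, values = values,
                 summary = c(median = median(num), min = min(num),
                             max = max(num)),
                 settings = settings),
            class = "mpi_stability")
}

#' @export
print.mpi_stability <- function(x, ...) {
  cat("MPI stability -", x$analysis, "\n")
  cat(sprintf("  median %.4f | min %.4f | max %.4f  (%d value%s)\n",
              x$summary["median"], x$summary["min"], x$summary["max"],
              nrow(x$values), if (nrow(x$values) == 1) "" else "s"))
  invisible(x)
}

#' Write a stability report to CSV and JSON
#' @param report An `mpi_stability`.
#' @param csv_path Per-iteration/setting values.
#' @param json_path Optional summary sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_stability <- function(report, csv_path, json_path = NULL) {
  write.csv(report$values, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(analysis = report$analysis,
                              summary = as.list(report$summary),
                              settings = report$settings),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
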