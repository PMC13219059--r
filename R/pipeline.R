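#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [mpi_pipeline()]. Defaults encode
#' the study settings: segmentation threshold 2.5, k = 20, 300 iterations of
#' 80% subsampling, k sweep 10-30, ablation of the two dissemination
#' features, 1000 bootstrap iterations, and the two predefined logistic
#' models (conventional: tMTV + DmaxVox + bone metastasis; MPI-based: MPI +
#' bone metastasis).
#'
#' @param input `"simulate"` (default) or `"voxel_table"`.
#' @param voxel_table_path CSV path when `input = "voxel_table"`.
#' @param outcomes_path Outcomes CSV (required for prognostics with a voxel
#'   table; simulated cohorts carry their own).
#' @param generator Arguments forwarded to [cohort_params()].
#' @param threshold Segmentation threshold.
#' @param k Neighbourhood size.
#' @param robustness List: `fraction`, `iterations`, `k_values`, `drop`.
#' @param bootstrap_iterations Optimism-correction resamples.
#' @param seed Master seed, propagated to every stochastic stage with
#'   stage-specific offsets.
#' @return List of class `mpi_config`.
#' @export
mpi_config <- function(input = c("simulate", "voxel_table"),
                       voxel_table_path = NULL, outcomes_path = NULL,
                       generator = list(), threshold = 2.5, k = 20,
                       robustness = list(fraction = 0.8, iterations = 300,
                                         k_values = 10:30,
                                         drop = c("Dmax", "DmaxVox")),
                       bootstrap_iterations = 1000, seed = 1L) {
  cfg <- list(input = match.arg(input),
              voxel_table_path = voxel_table_path,
              outcomes_path = outcomes_path, generator = generator,
              threshold = threshold, k = k,
              robustness = modifyList(
                list(fraction = 0.8, iterations = 300, k_values = 10:30,
                     drop = c("Dmax", "DmaxVox")), robustness),
              bootstrap_iterations = bootstrap_iterations,
              seed = as.integer(seed))
  class(cfg) <- "mpi_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [mpi_config()] arguments.
#' @return An `mpi_config`.
#' @export
read_mpi_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(mpi_config, y)
}

#' Run the full MPI pipeline
#'
#' Chains simulate (or ingest) -> feature extraction -> diffusion-map MPI ->
#' stability suite -> prognostics, writing every artefact (feature matrix
#' CSV, MPI CSV + sidecar, stability CSVs, model JSONs and a summary JSON)
#' into `output_dir`. Fully reproducible from the master seed; every output
#' records the configuration hash.
#'
#' @param config An [mpi_config()].
#' @param output_dir Directory for artefacts (created if needed).
#' @return Invisibly, a list with the in-memory results: `features`, `fit`,
#'   `stability`, `prognostics`, `paths`.
#' @export
mpi_pipeline <- function(config = mpi_config(), output_dir = tempfile("mpi_run_")) {
  stopifnot(inherits(config, "mpi_config"))
  n_probe <- if (config$input == "simulate") {
    do.call(cohort_params, c(config$generator,
                             list(seed = config$seed)))$n_patients
  } else NA_integer_
  if (!is.na(n_probe) && config$k >= n_probe)
    stop("config invalid: k = ", config$k, " >= n_patients = ", n_probe)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(paste(
    format(unlist(config[c("input", "threshold", "k", "seed")]),
           trim = TRUE), collapse = "|"), 1, 64)

  outcomes <- NULL
  if (config$input == "simulate") {
    params <- do.call(cohort_params,
                      c(config$generator, list(seed = config$seed)))
    cohort <- simulate_cohort(params)
    fm <- cohort_features(cohort, method = "geometry",
                          threshold = config$threshold)
    outcomes <- cohort$outcomes
    write_cohort_csv(cohort, file.path(output_dir, "cohort_lesions.csv"),
                     file.path(output_dir, "cohort_outcomes.csv"))
  } else {
    ls_list <- read_voxel_table(config$voxel_table_path,
                                threshold = config$threshold)
    fm <- cohort_features(ls_list, threshold = config$threshold)
    if (!is.null(config$outcomes_path))
      outcomes <- read.csv(config$outcomes_path, stringsAsFactors = FALSE)
  }
  write_feature_matrix(fm, file.path(output_dir, "feature_matrix.csv"))

  fit <- mpi(fm, k = config$k)
  write_mpi(fit, file.path(output_dir, "mpi.csv"),
            file.path(output_dir, "mpi.json"))

  rb <- config$robustness
  stability <- list(
    subsample = mpi_subsample_stability(fm, fraction = rb$fraction,
                                        iterations = rb$iterations,
                                        seed = config$seed + 1000L,
                                        k = config$k),
    k_sweep = mpi_k_sensitivity(fm, k_values = rb$k_values,
                                k_ref = config$k),
    ablation = mpi_feature_ablation(fm, drop = rb$drop, k = config$k),
    root = mpi_root_sensitivity(fm, rule = "min_tMTV", k = config$k))
  for (nm in names(stability))
    write_stability(stability[[nm]],
                    file.path(output_dir, paste0("stability_", nm, ".csv")),
                    file.path(output_dir, paste0("stability_", nm, ".json")))

  prog <- NULL
  if (!is.null(outcomes)) {
    d <- merge(merge(fm, as.data.frame(fit)[, c("patient_id", "MPI")],
                     by = "patient_id"),
               outcomes, by = "patient_id")
    conventional <- fit_logistic(dead_12mo ~ tMTV + DmaxVox + bone_met, d)
    mpi_model <- fit_logistic(dead_12mo ~ MPI + bone_met, d)
    base_model <- fit_logistic(dead_12mo ~ bone_met, d)
    prog <- list(
      univariable = univariable_screen(
        d, features = c(pet_feature_names(), "MPI")),
      conventional = conventional, mpi_model = mpi_model,
      delong = delong_compare(mpi_model$fitted, conventional$fitted,
                              d$dead_12mo),
      lrt = likelihood_ratio(base_model, mpi_model),
      optimism = bootstrap_optimism(dead_12mo ~ MPI + bone_met, d,
                                    iterations = config$bootstrap_iterations,
                                    seed = config$seed + 2000L),
      calibration = calibration_by_decile(mpi_model$fitted, d$dead_12mo),
      km = km_median(d$time_months, d$event),
      cox = fit_cox(survival::Surv(time_months, event) ~ MPI, d),
      vif = vif(d[, c("MPI", "bone_met")]),
      comparator = polynomial_comparator(d))
    write.csv(data.frame(patient_id = d$patient_id,
                         pred_mpi_model = mpi_model$fitted,
                         pred_conventional = conventional$fitted),
              file.path(output_dir, "predicted_risk.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = cfg_hash,
           mpi_model = list(table = prog$mpi_model$table,
                            auc = as.list(prog$mpi_model$auc)),
           conventional = list(table = prog$conventional$table,
                               auc = as.list(prog$conventional$auc)),
           delong = prog$delong[c("auc1", "auc2", "delta", "p")],
           lrt = prog$lrt,
           optimism = prog$optimism[c("apparent", "optimism", "corrected")],
           km = prog$km[c("median", "lo", "hi")],
           cox = list(table = prog$cox$table, c_index = prog$cox$c_index),
           vif = as.list(prog$vif),
           comparator_auc = unname(prog$comparator$auc["auc"])),
      file.path(output_dir, "prognostics.json"),
      auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = config$seed, k = config$k,
         n = nrow(fm),
         stability = lapply(stability, function(s) as.list(s$summary))),
    file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(features = fm, fit = fit, stability = stability,
                 prognostics = prog, paths = output_dir))
}
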