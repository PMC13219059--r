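#' Parameters for the synthetic PET cohort generator
#'
#' Builds the parameter list consumed by [simulate_cohort()]. Defaults emulate
#' a stage-IV small-cell lung cancer cohort with multi-lesion disease: about
#' 72% 12-month mortality, median overall survival near 6 months, a median of
#' roughly 4-8 lesions per patient, and total metabolic tumour volume on the
#' hundreds-of-ml scale. One latent severity value per patient, uniform on
#' \[0, 1\], drives lesion count, lesion volumes, spatial dissemination, bone
#' metastasis probability and both outcomes; peak SUVmax is drawn at the
#' patient level independently of severity, so intensity ceiling carries no
#' severity signal.
#'
#' @param n_patients Cohort size (>= 3).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param lesion_rate `c(base, slope)`: lesion count is
#'   `1 + Poisson(base + slope * s)`.
#' @param bulk_volume `c(base_ml, log_slope, log_sd)`: bulk lesion volume is
#'   lognormal with meanlog `log(base_ml) + log_slope * s`.
#' @param met_volume `c(base_ml, log_slope, log_sd)`: metastasis volumes,
#'   same parameterization.
#' @param suvmax_dist `c(log_mean, log_sd)`: patient-level peak SUVmax,
#'   lognormal, independent of severity; assigned to the bulk lesion, with
#'   metastasis SUVmax uniform between just above the segmentation threshold
#'   and the patient peak.
#' @param dispersion `c(base_mm, slope_mm, log_sd)`: metastases are placed
#'   with surface-to-surface clearance from the bulk lesion up to
#'   `(base + slope * s) * exp(N(0, log_sd))` mm, inside a body cylinder
#'   (radius 150 mm, height 1000 mm), with sphere overlap rejected. The
#'   lognormal factor (default off) injects severity-independent placement
#'   variability.
#' @param outcome_logit `c(intercept, slope)` for
#'   `P(death within 12 months) = plogis(intercept + slope * s)`.
#' @param survival `c(shape, scale_months, log_hazard_slope)`: Weibull
#'   survival with per-patient scale `scale * exp(-slope * s / shape)`
#'   (proportional hazards in s), sampled conditionally on the drawn 12-month
#'   status so the logistic marginal is exact.
#' @param bone_logit `c(intercept, slope)` for bone-metastasis probability.
#' @param admin_censor_months Administrative censoring time (>= 12).
#' @param voxel_spacing_mm Isotropic voxel edge used by [rasterize_patient()].
#' @param suv_threshold Segmentation threshold all lesion SUVmax values must
#'   exceed.
#' @param noise_scale Multiplier on every lognormal sd (lesion volumes and
#'   SUVmax); 1 is the default condition, larger values give noisier cohorts.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 83,
                          seed = 1L,
                          lesion_rate = c(base = 1.5, slope = 6),
                          bulk_volume = c(base_ml = 30, log_slope = 4, log_sd = 0.6),
                          met_volume = c(base_ml = 0.5, log_slope = 3, log_sd = 1.0),
                          suvmax_dist = c(log_mean = log(15), log_sd = 0.35),
                          dispersion = c(base_mm = 15, slope_mm = 70, log_sd = 0),
                          outcome_logit = c(intercept = -0.3804, slope = 3),
                          survival = c(shape = 1.3, scale_months = 10.882,
                                       log_hazard_slope = 1.2),
                          bone_logit = c(intercept = -0.5231, slope = 1.5),
                          admin_censor_months = 24,
                          voxel_spacing_mm = 4,
                          suv_threshold = 2.5,
                          noise_scale = 1) {
  p <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
            lesion_rate = lesion_rate, bulk_volume = bulk_volume,
            met_volume = met_volume, suvmax_dist = suvmax_dist,
            dispersion = dispersion, outcome_logit = outcome_logit,
            survival = survival, bone_logit = bone_logit,
            admin_censor_months = admin_censor_months,
            voxel_spacing_mm = voxel_spacing_mm,
            suv_threshold = suv_threshold, noise_scale = noise_scale)
  if (p$n_patients < 3L)
    stop("n_patients must be >= 3")
  if (p$admin_censor_months < 12)
    stop("admin_censor_months must be >= 12")
  pos <- c(bulk_volume[["base_ml"]], bulk_volume[["log_sd"]],
           met_volume[["base_ml"]], met_volume[["log_sd"]],
           suvmax_dist[["log_sd"]], survival[["shape"]],
           survival[["scale_months"]], voxel_spacing_mm, noise_scale)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all scale/sd parameters must be positive")
  class(p) <- "cohort_params"
  p
}

sphere_radius_mm <- function(volume_ml) (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)

BODY_RADIUS_MM <- 150
BODY_HALF_HEIGHT_MM <- 500

in_body_cylinder <- function(xyz) {
  sqrt(xyz[1]^2 + xyz[2]^2) <= BODY_RADIUS_MM && abs(xyz[3]) <= BODY_HALF_HEIGHT_MM
}

# uniform point in the body cylinder, margin keeps a sphere of radius r inside-ish
runif_cylinder <- function(r = 0) {
  rad <- min(BODY_RADIUS_MM - min(r, BODY_RADIUS_MM * 0.6), BODY_RADIUS_MM)
  u <- runif(1); th <- runif(1, 0, 2 * pi)
  c(rad * sqrt(u) * cos(th), rad * sqrt(u) * sin(th),
    runif(1, -BODY_HALF_HEIGHT_MM + min(r, 200), BODY_HALF_HEIGHT_MM - min(r, 200)))
}

runif_sphere_dir <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Simulate a synthetic PET cohort with known latent severity
#'
#' Draws a cohort in which a single latent severity \eqn{s \sim U(0,1)} drives
#' lesion multiplicity, lesion volumes, spatial dissemination, bone
#' metastases, 12-month mortality and overall survival, while peak SUVmax is
#' severity-independent. Lesions are non-overlapping spheres in a body-sized
#' cylinder; the first lesion of each patient is the bulk (largest in
#' expectation) and metastases are scattered around it with a
#' severity-dependent clearance. Twelve-month death is Bernoulli with a
#' logistic link in s; survival time is Weibull (log-hazard linear in s)
#' drawn conditionally on the 12-month status and censored administratively.
#'
#' @param params A [cohort_params()] list.
#' @return An object of class `pet_cohort`: list with `params`, `patients`
#'   (per patient: `patient_id`, `severity`, and a `lesions` data frame with
#'   columns `lesion_id, x_mm, y_mm, z_mm, volume_ml, radius_mm, suvmax`),
#'   and `outcomes` (a data frame with `patient_id, dead_12mo, time_months,
#'   event, bone_met, severity`).
#' @examples
#' coh <- simulate_cohort(cohort_params(n_patients = 10, seed = 42))
#' mean(coh$outcomes$dead_12mo)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  ns <- params$noise_scale
  thr <- params$suv_threshold

  s <- runif(n)
  patients <- vector("list", n)
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    dead_12mo = integer(n), time_months = numeric(n),
                    event = integer(n), bone_met = integer(n),
                    severity = s, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    si <- s[i]
    n_met <- rpois(1, params$lesion_rate[["base"]] + params$lesion_rate[["slope"]] * si)
    bulk_v <- exp(rnorm(1, log(params$bulk_volume[["base_ml"]]) +
                          params$bulk_volume[["log_slope"]] * si,
                        params$bulk_volume[["log_sd"]] * ns))
    bulk_r <- sphere_radius_mm(bulk_v)
    centers <- matrix(runif_cylinder(bulk_r), nrow = 1)
    vols <- bulk_v
    radii <- bulk_r

    if (n_met > 0) {
      met_v <- exp(rnorm(n_met, log(params$met_volume[["base_ml"]]) +
                           params$met_volume[["log_slope"]] * si,
                         params$met_volume[["log_sd"]] * ns))
      disp_sd <- if ("log_sd" %in% names(params$dispersion))
        params$dispersion[["log_sd"]] else 0
      disp0 <- (params$dispersion[["base_mm"]] +
                  params$dispersion[["slope_mm"]] * si) *
        exp(rnorm(1, 0, disp_sd * ns))
      for (j in seq_len(n_met)) {
        rj <- sphere_radius_mm(met_v[j])
        disp <- disp0
        placed <- FALSE
        for (try in seq_len(400)) {
          d <- radii[1] + rj + disp * runif(1)^(1 / 3)
          cand <- centers[1, ] + d * runif_sphere_dir()
          ok <- in_body_cylinder(cand)
          if (ok && nrow(centers) > 1) {
            dd <- sqrt(colSums((t(centers[-1, , drop = FALSE]) - cand)^2))
            ok <- all(dd >= radii[-1] + rj)
          }
          if (ok) {
            centers <- rbind(centers, cand)
            vols <- c(vols, met_v[j])
            radii <- c(radii, rj)
            placed <- TRUE
            break
          }
          if (try %% 80 == 0) disp <- disp * 1.4  # relax clearance if crowded
        }
        if (!placed) next  # extremely crowded configuration: drop this met
      }
    }

    L <- nrow(centers)
    suv_peak <- max(exp(rnorm(1, params$suvmax_dist[["log_mean"]],
                              params$suvmax_dist[["log_sd"]] * ns)), thr + 1)
    suvmax <- c(suv_peak,
                if (L > 1) runif(L - 1, thr + 0.3, suv_peak) else numeric(0))

    patients[[i]] <- list(
      patient_id = out$patient_id[i], severity = si,
      lesions = data.frame(lesion_id = seq_len(L),
                           x_mm = centers[, 1], y_mm = centers[, 2],
                           z_mm = centers[, 3], volume_ml = vols,
                           radius_mm = radii, suvmax = suvmax))

    # outcomes: logistic 12-month death, truncated Weibull survival
    out$bone_met[i] <- rbinom(1, 1, plogis(params$bone_logit[["intercept"]] +
                                             params$bone_logit[["slope"]] * si))
    p12 <- plogis(params$outcome_logit[["intercept"]] +
                    params$outcome_logit[["slope"]] * si)
    d12 <- rbinom(1, 1, p12)
    a <- params$survival[["shape"]]
    b <- params$survival[["scale_months"]] *
      exp(-params$survival[["log_hazard_slope"]] * si / a)
    F12 <- 1 - exp(-(12 / b)^a)
    u <- runif(1)
    tt <- if (d12 == 1) {
      b * (-log(1 - u * F12))^(1 / a)
    } else {
      b * (-log(1 - (F12 + u * (1 - F12))))^(1 / a)
    }
    cens <- params$admin_censor_months
    out$dead_12mo[i] <- d12
    out$event[i] <- as.integer(tt <= cens)
    out$time_months[i] <- min(tt, cens)
  }

  structure(list(params = params, patients = patients, outcomes = out),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  n <- length(x$patients)
  nl <- vapply(x$patients, function(p) nrow(p$lesions), integer(1))
  cat("Synthetic PET cohort:", n, "patients, median",
      median(nl), "lesions/patient\n")
  cat(sprintf("  12-month mortality %.1f%%; events %d/%d\n",
              100 * mean(x$outcomes$dead_12mo), sum(x$outcomes$event), n))
  invisible(x)
}

#' Flatten a cohort's lesion geometry to a data frame
#'
#' @param x A `pet_cohort`.
#' @param ... Unused.
#' @return One row per lesion: `patient_id, lesion_id, x_mm, y_mm, z_mm,
#'   volume_ml, radius_mm, suvmax, severity`.
#' @export
as.data.frame.pet_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$patients, function(p) {
    cbind(patient_id = p$patient_id, p$lesions, severity = p$severity,
          stringsAsFactors = FALSE)
  }))
}

#' Write cohort geometry and outcomes to CSV
#'
#' @param cohort A `pet_cohort`.
#' @param lesions_path,outcomes_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, lesions_path, outcomes_path) {
  write.csv(as.data.frame(cohort), lesions_path, row.names = FALSE)
  write.csv(cohort$outcomes, outcomes_path, row.names = FALSE)
  invisible(c(lesions_path, outcomes_path))
}

#' Rasterize one synthetic patient to an SUV image
#'
#' Renders each spherical lesion onto an isotropic voxel grid as the N voxel
#' centres nearest the lesion centre, where N is the lesion volume divided by
#' the voxel volume (a discrete ball), so threshold segmentation recovers the
#' prescribed voxel count. SUV is the lesion SUVmax at the centre voxel and
#' decays linearly with distance to just above the segmentation threshold at
#' the ball boundary; background voxels are drawn uniformly below the
#' threshold. Lesions smaller than one voxel are rendered as a single voxel.
#'
#' @param patient One element of `pet_cohort$patients`.
#' @param spacing_mm Isotropic voxel edge length in mm.
#' @param threshold Segmentation threshold the lesion SUVs must stay above.
#' @param margin_mm Padding added around the lesion bounding box.
#' @param background `"uniform"` draws background SUV in (0.05, 0.8 * threshold)
#'   using the current RNG state; `"zero"` leaves the background at 0.
#' @return An object of class `suv_image` (see [suv_image()]).
#' @export
rasterize_patient <- function(patient, spacing_mm = 4, threshold = 2.5,
                              margin_mm = 12, background = c("uniform", "zero")) {
  background <- match.arg(background)
  les <- patient$lesions
  stopifnot(nrow(les) >= 1)
  lo <- c(min(les$x_mm - les$radius_mm), min(les$y_mm - les$radius_mm),
          min(les$z_mm - les$radius_mm)) - margin_mm
  hi <- c(max(les$x_mm + les$radius_mm), max(les$y_mm + les$radius_mm),
          max(les$z_mm + les$radius_mm)) + margin_mm
  dims <- pmax(ceiling((hi - lo) / spacing_mm) + 1L, 3L)
  origin <- lo
  vox_ml <- spacing_mm^3 / 1000

  vals <- if (background == "uniform") {
    array(runif(prod(dims), 0.05, 0.8 * threshold), dim = dims)
  } else {
    array(0, dim = dims)
  }

  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing_mm)
  for (j in seq_len(nrow(les))) {
    n_vox <- max(1L, round(les$volume_ml[j] / vox_ml))
    ctr <- c(les$x_mm[j], les$y_mm[j], les$z_mm[j])
    # candidate voxels within a safely padded radius, then take the N nearest
    pad_r <- les$radius_mm[j] + 2.5 * spacing_mm
    ix <- which(abs(ax[[1]] - ctr[1]) <= pad_r)
    iy <- which(abs(ax[[2]] - ctr[2]) <= pad_r)
    iz <- which(abs(ax[[3]] - ctr[3]) <= pad_r)
    g <- expand.grid(i = ix, j = iy, k = iz)
    d2 <- (ax[[1]][g$i] - ctr[1])^2 + (ax[[2]][g$j] - ctr[2])^2 +
      (ax[[3]][g$k] - ctr[3])^2
    ord <- order(d2, g$i + (g$j - 1) * dims[1] + (g$k - 1) * dims[1] * dims[2])
    take <- ord[seq_len(min(n_vox, length(ord)))]
    dmax <- sqrt(max(d2[take]))
    eps <- 0.05
    suv <- if (dmax < 1e-9) {
      rep(les$suvmax[j], length(take))
    } else {
      threshold + eps +
        (les$suvmax[j] - threshold - eps) * (1 - sqrt(d2[take]) / (dmax + 1e-9))
    }
    suv[1] <- les$suvmax[j]  # nearest voxel carries the exact peak
    idx <- cbind(g$i[take], g$j[take], g$k[take])
    vals[idx] <- pmax(vals[idx], suv)
  }
  suv_image(vals, spacing = rep(spacing_mm, 3), origin = origin)
}
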