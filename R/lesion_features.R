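#' Construct an SUV image
#'
#' @param values 3-D numeric array of SUV.
#' @param spacing Voxel spacing in mm per axis (length 3, all > 0).
#' @param origin World coordinate (mm) of the centre of voxel (1,1,1).
#' @return An object of class `suv_image`.
#' @export
suv_image <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3,
            all(spacing > 0), all(is.finite(values)))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  cat("SUV image", paste(dim(x$values), collapse = " x "),
      "voxels; spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Read / write SUV images as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}; voxel spacing travels in the pixdim
#' header field. World coordinates used by this package are
#' `origin + (index - 1) * spacing` (voxel centres); the stored origin is the
#' image's own offset, default 0.
#'
#' @param image An `suv_image`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_suv_nifti()` returns the path invisibly;
#'   `read_suv_nifti()` returns an `suv_image`.
#' @export
write_suv_nifti <- function(image, path) {
  stopifnot(inherits(image, "suv_image"))
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- image$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_suv_nifti
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  suv_image(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3])
}

#' Construct a lesion set
#'
#' A lesion set holds one patient's segmented lesions as voxel world
#' coordinates (mm) with per-voxel SUV. All distances downstream are in mm
#' and all volumes in ml.
#'
#' @param patient_id Identifier.
#' @param lesions List of lesions, each `list(lesion_id, coords, suv)` with
#'   `coords` an n x 3 matrix of voxel-centre world coordinates.
#' @param voxel_volume_ml Volume of one voxel in ml.
#' @return An object of class `lesion_set`.
#' @export
lesion_set <- function(patient_id, lesions, voxel_volume_ml) {
  stopifnot(voxel_volume_ml > 0)
  for (l in lesions) {
    stopifnot(nrow(l$coords) >= 1, length(l$suv) == nrow(l$coords))
  }
  structure(list(patient_id = patient_id, lesions = lesions,
                 voxel_volume_ml = voxel_volume_ml), class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("Lesion set", x$patient_id, "-", length(x$lesions), "lesion(s),",
      sum(vapply(x$lesions, function(l) nrow(l$coords), integer(1))),
      "voxels\n")
  invisible(x)
}

# 26-connectivity half-neighbourhood offsets (13 of the 26)
.offsets26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  key <- g[, 1] + 3 * g[, 2] + 9 * g[, 3]
  g[key > 0, , drop = FALSE]
})

#' Segment supra-threshold lesions from an SUV image
#'
#' Voxels with SUV strictly above `threshold` are grouped into connected
#' components under 26-connectivity (face, edge and corner adjacency);
#' components with fewer than `min_voxels` voxels are dropped. Voxel world
#' coordinates are voxel centres, `origin + (index - 1) * spacing`. An image
#' with no supra-threshold voxel yields an explicit empty lesion set (zero
#' lesions), not an error; the caller decides whether that excludes the
#' patient.
#'
#' @param image An [suv_image()].
#' @param threshold SUV threshold; inclusion is strictly above.
#' @param min_voxels Minimum component size retained.
#' @param patient_id Identifier to attach.
#' @return A [lesion_set()] (possibly with zero lesions).
#' @export
segment_lesions <- function(image, threshold = 2.5, min_voxels = 1L,
                            patient_id = "patient") {
  stopifnot(inherits(image, "suv_image"))
  dims <- dim(image$values)
  sel <- which(image$values > threshold)
  vox_ml <- prod(image$spacing) / 1000
  if (length(sel) == 0)
    return(lesion_set(patient_id, list(), vox_ml))
  idx <- arrayInd(sel, dims)
  key <- as.numeric(idx[, 1]) + dims[1] * (idx[, 2] - 1) +
    dims[1] * dims[2] * (idx[, 3] - 1)
  pos <- seq_along(key)
  names(pos) <- as.character(key)

  edges <- NULL
  for (r in seq_len(nrow(.offsets26))) {
    off <- .offsets26[r, ]
    ni <- idx[, 1] + off[1]; nj <- idx[, 2] + off[2]; nk <- idx[, 3] + off[3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
      nk >= 1 & nk <= dims[3]
    if (!any(ok)) next
    nkey <- as.numeric(ni[ok]) + dims[1] * (nj[ok] - 1) +
      dims[1] * dims[2] * (nk[ok] - 1)
    hit <- pos[as.character(nkey)]
    keep <- !is.na(hit)
    if (any(keep))
      edges <- rbind(edges, cbind(pos[ok][keep], hit[keep]))
  }
  memb <- if (is.null(edges)) {
    seq_along(sel)
  } else {
    g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    igraph::components(g)$membership
  }

  coords <- sweep(sweep(idx - 1, 2, image$spacing, "*"), 2, image$origin, "+")
  comp_ids <- sort(unique(memb))
  lesions <- list()
  lid <- 0L
  for (cid in comp_ids) {
    w <- which(memb == cid)
    if (length(w) < min_voxels) next
    lid <- lid + 1L
    lesions[[lid]] <- list(lesion_id = lid,
                           coords = coords[w, , drop = FALSE],
                           suv = image$values[sel[w]])
  }
  lesion_set(patient_id, lesions, vox_ml)
}

#' Per-lesion summaries
#'
#' MTV is voxel count times voxel volume; TLG is MTV times SUVmean; the
#' centroid is the unweighted mean of voxel centres.
#'
#' @param ls A non-empty [lesion_set()].
#' @return Data frame with one row per lesion: `lesion_id, n_voxels, MTV,
#'   SUVmean, SUVmax, TLG, intensity_sum, cx, cy, cz`.
#' @export
summarize_lesions <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  if (length(ls$lesions) == 0) stop("empty lesion set")
  do.call(rbind, lapply(ls$lesions, function(l) {
    n <- nrow(l$coords)
    mtv <- n * ls$voxel_volume_ml
    mu <- mean(l$suv)
    data.frame(lesion_id = l$lesion_id, n_voxels = n, MTV = mtv,
               SUVmean = mu, SUVmax = max(l$suv), TLG = mtv * mu,
               intensity_sum = sum(l$suv),
               cx = mean(l$coords[, 1]), cy = mean(l$coords[, 2]),
               cz = mean(l$coords[, 3]))
  }))
}

# exact max pairwise distance; prune to boundary voxels, then blocked BLAS.
# the farthest pair is attained at convex-hull vertices, all of which lack at
# least one face neighbour, so the prune is exact.
max_pair_dist <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(0)
  if (n <= 2000) return(max(dist(xyz)))
  nrm <- rowSums(xyz^2)
  best <- 0
  bs <- 512L
  for (start in seq(1L, n, by = bs)) {
    ii <- start:min(start + bs - 1L, n)
    d2 <- outer(nrm[ii], nrm, "+") - 2 * tcrossprod(xyz[ii, , drop = FALSE], xyz)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Maximum voxel-to-voxel distance (DmaxVox)
#'
#' Maximum Euclidean distance over all tumour voxels pooled across lesions;
#' within-lesion chords are included, so a single-lesion patient gets the
#' lesion's maximum chord. Exact (blocked all-pairs), not approximated.
#'
#' @param ls A [lesion_set()] with at least one voxel.
#' @return Distance in mm.
#' @export
dmax_vox <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"), length(ls$lesions) >= 1)
  xyz <- do.call(rbind, lapply(ls$lesions, function(l) l$coords))
  max_pair_dist(xyz)
}

#' Names of the 20 whole-body PET features
#' @return Character vector in canonical order.
#' @export
pet_feature_names <- function() c(
  "tMTV", "tTLG", "Intensity_Sum", "MeanIntensity_Sum", "Volume_intensity_sum",
  "MTV_Bulk", "MTV_Smallest", "tSUVmax", "MaxIntensity_Min",
  "Volume_DiffSum", "Bulk_Volume_DiffSum", "BulkSmallest_Volume_Diff",
  "MaxIntensity_DiffSum", "HighestLowest_MaxIntensity_Diff",
  "Bulk_MaxIntensity_DiffSum",
  "DmaxVox", "Dmax", "BulkDmax", "BulkCentroidCoor_DistMax",
  "SmallestCentroidCoor_DistMax")

# all-pairs sum of absolute differences via the sorted-prefix identity
pair_abs_diff_sum <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  xs <- sort(x)
  sum(((2 * seq_len(n)) - n - 1) * xs)
}

# core feature assembly from per-lesion summaries + a DmaxVox value
features_from_summaries <- function(summ, dmaxvox) {
  L <- nrow(summ)
  # bulk = largest MTV; ties to higher intensity_sum then lower lesion_id
  ord <- order(-summ$MTV, -summ$intensity_sum, summ$lesion_id)
  bulk <- ord[1]
  ords <- order(summ$MTV, -summ$intensity_sum, summ$lesion_id)
  smallest <- ords[1]
  ctr <- as.matrix(summ[, c("cx", "cy", "cz")])
  cd <- as.matrix(dist(ctr))
  f <- c(
    tMTV = sum(summ$MTV),
    tTLG = sum(summ$TLG),
    Intensity_Sum = sum(summ$intensity_sum),
    MeanIntensity_Sum = sum(summ$SUVmean),
    Volume_intensity_sum = sum(summ$MTV * summ$intensity_sum),
    MTV_Bulk = summ$MTV[bulk],
    MTV_Smallest = min(summ$MTV),
    tSUVmax = max(summ$SUVmax),
    MaxIntensity_Min = min(summ$SUVmax),
    Volume_DiffSum = pair_abs_diff_sum(summ$MTV),
    Bulk_Volume_DiffSum = sum(summ$MTV[bulk] - summ$MTV[-bulk]),
    BulkSmallest_Volume_Diff = summ$MTV[bulk] - min(summ$MTV),
    MaxIntensity_DiffSum = pair_abs_diff_sum(summ$SUVmax),
    HighestLowest_MaxIntensity_Diff = max(summ$SUVmax) - min(summ$SUVmax),
    Bulk_MaxIntensity_DiffSum = sum(abs(summ$SUVmax[bulk] - summ$SUVmax[-bulk])),
    DmaxVox = dmaxvox,
    Dmax = max(cd),
    BulkDmax = max(cd[bulk, ]),
    BulkCentroidCoor_DistMax = max(cd[bulk, ]),
    SmallestCentroidCoor_DistMax = max(cd[smallest, ]))
  if (L == 1) {
    zero <- c("Volume_DiffSum", "Bulk_Volume_DiffSum",
              "BulkSmallest_Volume_Diff", "MaxIntensity_DiffSum",
              "HighestLowest_MaxIntensity_Diff", "Bulk_MaxIntensity_DiffSum",
              "Dmax", "BulkDmax", "BulkCentroidCoor_DistMax",
              "SmallestCentroidCoor_DistMax")
    f[zero] <- 0
  }
  f[pet_feature_names()]
}

#' Compute the 20-feature vector for one patient
#'
#' Global burden (tMTV, tTLG, intensity sums), dominant-lesion descriptors
#' (bulk/smallest volumes, peak and minimum SUVmax), inter-lesional
#' heterogeneity (all-pairs and bulk-anchored absolute difference sums), and
#' spatial dissemination (centroid distances and the voxel-level DmaxVox).
#' Single-lesion patients get zero for every pairwise and bulk-distance
#' feature, with DmaxVox equal to the lesion's maximum chord.
#'
#' @param ls A [lesion_set()] with at least one lesion.
#' @return Named numeric vector of length 20 (see [pet_feature_names()]).
#' @export
compute_features <- function(ls) {
  summ <- summarize_lesions(ls)
  features_from_summaries(summ, dmax_vox(ls))
}

# analytic ("fast-path") per-lesion summaries for spherical synthetic lesions:
# SUV decays linearly from SUVmax at the centre to the threshold at the
# boundary, so the volume-average is thr + (SUVmax - thr)/4.
geometry_summaries <- function(lesions, voxel_volume_ml, threshold = 2.5) {
  mu <- threshold + (lesions$suvmax - threshold) / 4
  data.frame(lesion_id = lesions$lesion_id,
             n_voxels = lesions$volume_ml / voxel_volume_ml,
             MTV = lesions$volume_ml, SUVmean = mu, SUVmax = lesions$suvmax,
             TLG = lesions$volume_ml * mu,
             intensity_sum = mu * lesions$volume_ml / voxel_volume_ml,
             cx = lesions$x_mm, cy = lesions$y_mm, cz = lesions$z_mm)
}

geometry_dmaxvox <- function(lesions) {
  L <- nrow(lesions)
  within <- 2 * max(lesions$radius_mm)
  if (L == 1) return(within)
  ctr <- as.matrix(lesions[, c("x_mm", "y_mm", "z_mm")])
  cd <- as.matrix(dist(ctr))
  rr <- outer(lesions$radius_mm, lesions$radius_mm, "+")
  max(within, max(cd + rr - diag(diag(cd + rr))))
}

#' Feature matrix for a whole cohort
#'
#' The geometry method evaluates features in closed form from the spherical
#' lesion model (exact volumes and centroids; DmaxVox approximated as centre
#' distance plus both radii, or the diameter within one lesion). The raster
#' method rasterizes each patient with [rasterize_patient()], segments at the
#' threshold and extracts features from voxels; it agrees with the geometry
#' path to within one voxel volume/diagonal and exists to exercise the full
#' image pipeline.
#'
#' @param cohort A `pet_cohort`, or a list of [lesion_set()] objects.
#' @param method `"geometry"` (closed form, synthetic cohorts only) or
#'   `"raster"`.
#' @param threshold Segmentation threshold.
#' @param spacing_mm Voxel edge for the raster path (defaults to the
#'   cohort's `voxel_spacing_mm`).
#' @return Data frame: `patient_id` plus the 20 feature columns; attributes
#'   `threshold` and `voxel_volume_ml` record provenance.
#' @export
cohort_features <- function(cohort, method = c("geometry", "raster"),
                            threshold = 2.5, spacing_mm = NULL) {
  if (is.list(cohort) && !inherits(cohort, "pet_cohort")) {
    rows <- lapply(cohort, function(ls) compute_features(ls))
    fm <- data.frame(patient_id = vapply(cohort, function(ls)
      as.character(ls$patient_id), character(1)),
      do.call(rbind, rows), stringsAsFactors = FALSE)
    attr(fm, "threshold") <- threshold
    attr(fm, "voxel_volume_ml") <- cohort[[1]]$voxel_volume_ml
    return(fm)
  }
  method <- match.arg(method)
  if (is.null(spacing_mm)) spacing_mm <- cohort$params$voxel_spacing_mm
  vox_ml <- spacing_mm^3 / 1000
  rows <- lapply(cohort$patients, function(p) {
    if (method == "geometry") {
      features_from_summaries(
        geometry_summaries(p$lesions, vox_ml, threshold),
        geometry_dmaxvox(p$lesions))
    } else {
      img <- rasterize_patient(p, spacing_mm, threshold)
      ls <- segment_lesions(img, threshold, patient_id = p$patient_id)
      compute_features(ls)
    }
  })
  fm <- data.frame(patient_id = vapply(cohort$patients, `[[`, character(1),
                                       "patient_id"),
                   do.call(rbind, rows), stringsAsFactors = FALSE)
  attr(fm, "threshold") <- threshold
  attr(fm, "voxel_volume_ml") <- vox_ml
  fm
}

#' Read a voxel table CSV into lesion sets
#'
#' Expected schema: columns `patient_id, lesion_id, x_mm, y_mm, z_mm, suv`,
#' with the voxel volume either as a `voxel_volume_ml` column or supplied as
#' an argument. Rows with SUV at or below the threshold are rejected and
#' counted in a message; duplicated (patient, lesion, coordinate) rows are an
#' error.
#'
#' @param path CSV path.
#' @param voxel_volume_ml Voxel volume in ml (required unless a column).
#' @param threshold Segmentation threshold used to validate SUVs.
#' @return Named list of [lesion_set()] objects, one per patient.
#' @export
read_voxel_table <- function(path, voxel_volume_ml = NULL, threshold = 2.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion_id", "x_mm", "y_mm", "z_mm", "suv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("voxel table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("voxel table is empty")
  if (is.null(voxel_volume_ml)) {
    if (!"voxel_volume_ml" %in% names(df))
      stop("voxel_volume_ml must be a column or an argument")
    voxel_volume_ml <- df$voxel_volume_ml[1]
  }
  key <- paste(df$patient_id, df$lesion_id, df$x_mm, df$y_mm, df$z_mm)
  if (anyDuplicated(key))
    stop("duplicate (patient, lesion, coordinate) rows in voxel table")
  bad <- df$suv <= threshold
  if (any(bad)) {
    message("dropping ", sum(bad), " voxel row(s) with SUV <= ", threshold)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no supra-threshold voxels in table")
  lapply(split(df, df$patient_id), function(pd) {
    lesions <- lapply(split(pd, pd$lesion_id), function(ld) {
      list(lesion_id = ld$lesion_id[1],
           coords = as.matrix(ld[, c("x_mm", "y_mm", "z_mm")]),
           suv = ld$suv)
    })
    names(lesions) <- NULL
    lesion_set(pd$patient_id[1], lesions, voxel_volume_ml)
  })
}

#' Write lesion sets to a voxel table CSV
#'
#' Inverse of [read_voxel_table()]: one row per voxel with the
#' `voxel_volume_ml` carried as a column.
#'
#' @param ls_list List of [lesion_set()] objects (or a single one).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_voxel_table <- function(ls_list, path) {
  if (inherits(ls_list, "lesion_set")) ls_list <- list(ls_list)
  rows <- do.call(rbind, lapply(ls_list, function(ls) {
    do.call(rbind, lapply(ls$lesions, function(l) {
      data.frame(patient_id = ls$patient_id, lesion_id = l$lesion_id,
                 x_mm = l$coords[, 1], y_mm = l$coords[, 2],
                 z_mm = l$coords[, 3], suv = l$suv,
                 voxel_volume_ml = ls$voxel_volume_ml)
    }))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix to CSV
#' @param fm Feature matrix from [cohort_features()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.csv(fm, path, row.names = FALSE)
  invisible(path)
}
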