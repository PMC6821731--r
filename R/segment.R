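#' Reference sphere
#'
#' A sphere of fixed volume used both for the normal-cortex reference reading
#' (default 1.0 cm^3, radius 6.20 mm) and as the user seed sphere that
#' encompasses a lesion.
#'
#' @param center mm coordinates of the sphere center.
#' @param volume_cm3 sphere volume in cm^3 (ignored when \code{radius} given).
#' @param radius optional explicit radius in mm.
#' @return An object of class \code{reference_sphere} with fields
#'   \code{center} and \code{radius} (mm).
#' @export
reference_sphere <- function(center, volume_cm3 = 1.0, radius = NULL) {
  if (is.null(radius)) {
    stop_if(!is_scalar_num(volume_cm3) || volume_cm3 <= 0,
            "volume_cm3 must be a positive number")
    radius <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  }
  structure(list(center = as.numeric(center), radius = radius),
            class = "reference_sphere")
}

#' Cortex reference SUVmean
#'
#' Arithmetic mean SUV over voxels whose centers lie within the sphere; the
#' normal-cortex reading that anchors the contouring threshold and the T/N
#' denominator.
#'
#' @param volume an [suv_volume()].
#' @param sphere a [reference_sphere()].
#' @return SUVmean (scalar).
#' @export
measure_cortex_reference <- function(volume, sphere) {
  stopifnot(inherits(volume, "suv_volume"), inherits(sphere, "reference_sphere"))
  m <- sphere_mask(volume, sphere$center, sphere$radius)
  stop_if(!any(m),
          "reference sphere contains no voxel centers (spacing too coarse or sphere outside grid)")
  mean(volume$values[m])
}

# assemble the lesion VOI container from a logical mask
.make_voi <- function(volume, mask, threshold_suv, reference_mean) {
  idx <- which(mask)
  n <- length(idx)
  voxvol <- prod(volume$spacing)
  if (n == 0L) {
    return(structure(list(mask_idx = integer(0), dim = dim(volume$values),
                          spacing = volume$spacing, threshold_suv = threshold_suv,
                          reference_mean = reference_mean, voxel_count = 0L,
                          volume_ml = 0, suv_max = NA_real_, suv_mean = NA_real_,
                          suv_sd = NA_real_), class = "lesion_voi"))
  }
  v <- volume$values[idx]
  structure(list(mask_idx = idx, dim = dim(volume$values),
                 spacing = volume$spacing, threshold_suv = threshold_suv,
                 reference_mean = reference_mean, voxel_count = n,
                 volume_ml = n * voxvol / 1000,
                 suv_max = max(v), suv_mean = mean(v),
                 suv_sd = sqrt(mean((v - mean(v))^2))),
            class = "lesion_voi")
}

#' @export
print.lesion_voi <- function(x, ...) {
  if (x$voxel_count == 0L) {
    cat("<lesion_voi> empty (no definite uptake above threshold",
        format(x$threshold_suv), "SUV)\n")
  } else {
    cat(sprintf("<lesion_voi> %d voxels (%.2f mL), SUVmax %.2f, threshold %.3f (= 1.3 x %.3f)\n",
                x$voxel_count, x$volume_ml, x$suv_max, x$threshold_suv,
                x$reference_mean))
  }
  invisible(x)
}

voi_mask <- function(voi) {
  m <- array(FALSE, voi$dim)
  m[voi$mask_idx] <- TRUE
  m
}

#' Threshold contouring of a lesion
#'
#' Within the seed sphere, voxels with SUV strictly greater than
#' \code{factor} times the cortex reference mean are candidates; the VOI is
#' the 26-connected candidate component containing the hottest candidate
#' voxel. An empty VOI signals no definite abnormal uptake.
#'
#' @param volume an [suv_volume()].
#' @param seed_sphere a [reference_sphere()] encompassing the lesion.
#' @param reference_mean cortex SUVmean (> 0).
#' @param factor threshold multiplier (default 1.3).
#' @return A \code{lesion_voi} with the mask and its summary statistics.
#' @export
contour_lesion <- function(volume, seed_sphere, reference_mean, factor = 1.3) {
  stopifnot(inherits(volume, "suv_volume"), inherits(seed_sphere, "reference_sphere"))
  stop_if(!is_scalar_num(factor) || factor <= 0, "factor must be > 0")
  stop_if(!is_scalar_num(reference_mean) || reference_mean <= 0,
          "reference_mean must be > 0")
  thr <- factor * reference_mean
  cand <- sphere_mask(volume, seed_sphere$center, seed_sphere$radius) &
    volume$values > thr
  if (!any(cand)) return(.make_voi(volume, cand, thr, reference_mean))
  idx <- which(cand)
  hottest <- idx[which.max(volume$values[idx])]
  comp <- connected_component_26(cand, hottest)
  .make_voi(volume, comp, thr, reference_mean)
}

#' Apply the cohort exclusion rules
#'
#' Cases with an empty VOI are excluded for lacking definite abnormal uptake;
#' non-empty VOIs of at most \code{min_voxels} voxels are excluded as too
#' small for texture quantification; the rest are kept.
#'
#' @param vois list of \code{lesion_voi} objects (optionally named by case).
#' @param min_voxels inclusive small-VOI bound (default 64).
#' @return An \code{exclusion_report}: data frame of per-case status plus
#'   counts per status.
#' @export
apply_exclusions <- function(vois, min_voxels = 64) {
  status <- vapply(vois, function(v) {
    if (v$voxel_count == 0L) "excluded_no_uptake"
    else if (v$voxel_count <= min_voxels) "excluded_small_voi"
    else "kept"
  }, character(1))
  ids <- names(vois)
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_along(vois))
  df <- data.frame(case_id = ids, status = status,
                   voxel_count = vapply(vois, function(v) v$voxel_count, integer(1)),
                   stringsAsFactors = FALSE)
  counts <- c(kept = sum(status == "kept"),
              excluded_no_uptake = sum(status == "excluded_no_uptake"),
              excluded_small_voi = sum(status == "excluded_small_voi"))
  structure(list(cases = df, counts = counts, min_voxels = min_voxels),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d cases: %d kept, %d no definite uptake, %d small VOI (<= %d voxels)\n",
              nrow(x$cases), x$counts["kept"], x$counts["excluded_no_uptake"],
              x$counts["excluded_small_voi"], x$min_voxels))
  invisible(x)
}

#' Tumor-to-normal-cortex ratio
#'
#' Lesion SUVmax divided by the contralateral normal cortex SUVmean; the
#' conventional comparator metric.
#'
#' @param voi a non-empty \code{lesion_voi}.
#' @param reference_mean cortex SUVmean (> 0).
#' @return The T/N ratio (scalar).
#' @export
compute_tn_ratio <- function(voi, reference_mean) {
  stopifnot(inherits(voi, "lesion_voi"))
  stop_if(voi$voxel_count == 0L, "T/N ratio is undefined for an empty VOI")
  stop_if(!is_scalar_num(reference_mean) || reference_mean <= 0,
          "reference_mean must be > 0")
  voi$suv_max / reference_mean
}
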