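#' Specification of one synthetic brain-PET phantom
#'
#' Describes a single phantom: a noisy background near SUV 1, a contralateral
#' cortex region of elevated uptake, and one lesion consisting of a spherical
#' plateau at \code{lesion_peak} (modulated by a multiplicative, spatially
#' correlated Gamma heterogeneity field of mean 1) with a Gaussian
#' infiltrative margin of scale \code{edge_width}. The pre-blur scene is
#' smoothed with a Gaussian point-spread function and independent Gaussian
#' noise is added after smoothing, mimicking a post-reconstruction filtered
#' PET image.
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 16).
#' @param voxel_spacing mm per axis (default 2 mm isotropic).
#' @param background_mean,background_sd background SUV level and its pre-blur
#'   variation.
#' @param cortex_mean SUV of the cortex reference region.
#' @param cortex_center,cortex_radius mm center/radius of the cortex ball;
#'   defaults mirror the lesion through the grid center along x.
#' @param lesion_center mm coordinates of the lesion center.
#' @param lesion_radius lesion radius in mm (>= 2 voxels except for the
#'   \code{subthreshold} class).
#' @param lesion_peak pre-blur lesion SUV on the plateau.
#' @param edge_width mm scale of the Gaussian infiltrative margin beyond the
#'   plateau radius (0 = hard-edged sphere).
#' @param heterogeneity_amplitude multiplicative texture strength (SD of the
#'   mean-1 Gamma field; 0 = perfectly smooth lesion).
#' @param heterogeneity_corr_length correlation length of the texture field, mm.
#' @param psf_fwhm Gaussian post-filter full-width at half-maximum, mm.
#' @param noise_sd SUV standard deviation of post-blur noise.
#' @param class_label one of \code{"recurrence"}, \code{"necrosis"},
#'   \code{"no_uptake"}, \code{"subthreshold"}.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing = c(2, 2, 2),
                         background_mean = 1.0, background_sd = 0.1,
                         cortex_mean = 1.5,
                         cortex_center = NULL, cortex_radius = 10,
                         lesion_center = NULL, lesion_radius = 10,
                         lesion_peak = 3.0, edge_width = 3,
                         heterogeneity_amplitude = 0.3,
                         heterogeneity_corr_length = 2,
                         psf_fwhm = 5, noise_sd = 0.05,
                         class_label = c("recurrence", "necrosis",
                                         "no_uptake", "subthreshold")) {
  class_label <- match.arg(class_label)
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  stop_if(length(grid_shape) != 3L || any(grid_shape < 16L),
          "grid_shape must be 3 values, all >= 16")
  stop_if(any(voxel_spacing <= 0), "voxel_spacing must be > 0")
  extent <- (grid_shape - 1L) * voxel_spacing
  if (is.null(lesion_center)) lesion_center <- extent * c(0.72, 0.5, 0.5)
  if (is.null(cortex_center)) {
    cortex_center <- lesion_center
    cortex_center[1] <- extent[1] - lesion_center[1]
  }
  stop_if(any(c(background_sd, cortex_mean, lesion_peak, psf_fwhm, noise_sd,
                heterogeneity_amplitude, heterogeneity_corr_length,
                edge_width) < 0),
          "negative phantom parameters are not allowed")
  stop_if(class_label != "subthreshold" &&
            lesion_radius < 2 * min(voxel_spacing),
          "lesion_radius must be at least 2 voxels for class ", class_label)
  stop_if(any(lesion_center - lesion_radius < 0) ||
            any(lesion_center + lesion_radius > extent),
          "lesion extends outside the grid; enlarge grid_shape or move/shrink it")
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 background_mean = background_mean, background_sd = background_sd,
                 cortex_mean = cortex_mean, cortex_center = cortex_center,
                 cortex_radius = cortex_radius,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 lesion_peak = lesion_peak, edge_width = edge_width,
                 heterogeneity_amplitude = heterogeneity_amplitude,
                 heterogeneity_corr_length = heterogeneity_corr_length,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 class_label = class_label),
            class = "phantom_spec")
}

# Mean-1 Gamma heterogeneity field on the lesion bounding box via a Gaussian
# copula: a seeded iid normal field is smoothed to the correlation length,
# rank-transformed, and mapped to Gamma(1/a^2, a^2) (mean 1, SD = a). With a
# fixed seed the latent field does not depend on the amplitude, so texture
# strength is monotone in `heterogeneity_amplitude`.
.heterogeneity_field <- function(nb, spacing, amp, corr_len) {
  if (amp <= 0) return(array(1, nb))
  z <- array(stats::rnorm(prod(nb)), nb)
  if (corr_len > 0) z <- blur_gaussian(z, spacing, corr_len * 2.355)
  z <- (z - mean(z)) / stats::sd(as.vector(z))
  u <- stats::pnorm(z)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  h <- stats::qgamma(u, shape = 1 / amp^2, scale = amp^2)
  h / mean(h)
}

#' Generate one synthetic phantom
#'
#' Builds the pre-blur scene (background field, cortex region, lesion profile
#' times heterogeneity field), smooths it with the Gaussian point-spread
#' function, adds post-blur noise, and clamps at SUV 0. Deterministic given
#' \code{seed}.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for this phantom.
#' @return A list with elements \code{volume} (an [suv_volume()]) and
#'   \code{truth}: the pre-blur lesion mask, class label, cortex reference
#'   center, suggested seed sphere (center/radius in mm) and the generative
#'   parameters.
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  noise0 <- array(stats::rnorm(prod(d), 0, 1), d)
  vol <- spec$background_mean + spec$background_sd * noise0
  vref <- suv_volume(vol, sp)
  cmask <- sphere_mask(vref, spec$cortex_center, spec$cortex_radius)
  vol[cmask] <- spec$cortex_mean + spec$background_sd * noise0[cmask]
  lmask <- sphere_mask(vref, spec$lesion_center, spec$lesion_radius)
  if (any(lmask)) {
    # radial profile: full uptake on the plateau (d <= radius), Gaussian
    # infiltrative skirt of scale edge_width beyond it
    cx <- axis_coords(vref)
    d2 <- lapply(1:3, function(a) (cx[[a]] - spec$lesion_center[a])^2)
    dist <- sqrt(outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+"))
    f <- array(0, d)
    f[lmask] <- 1
    if (spec$edge_width > 0) {
      skirt <- !lmask & dist <= spec$lesion_radius + 4 * spec$edge_width
      f[skirt] <- exp(-(dist[skirt] - spec$lesion_radius)^2 /
                        (2 * spec$edge_width^2))
    }
    support <- f > 0
    bb <- apply(arrayInd(which(support), d), 2, range)
    nb <- bb[2, ] - bb[1, ] + 1L
    het <- .heterogeneity_field(nb, sp, spec$heterogeneity_amplitude,
                                spec$heterogeneity_corr_length)
    full_het <- array(1, d)
    full_het[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]] <- het
    vol[support] <- (1 - f[support]) * vol[support] +
      f[support] * spec$lesion_peak * full_het[support]
  }
  vol <- blur_gaussian(vol, sp, spec$psf_fwhm)
  vol <- vol + stats::rnorm(prod(d), 0, spec$noise_sd)
  vol <- pmax(vol, 0)
  dim(vol) <- d
  seed_radius <- max(spec$lesion_radius + 2 * spec$edge_width + 6, 8)
  list(volume = suv_volume(vol, sp),
       truth = list(lesion_mask = lmask,
                    class_label = spec$class_label,
                    cortex_center = spec$cortex_center,
                    seed_sphere_center = spec$lesion_center,
                    seed_sphere_radius = seed_radius,
                    spec = spec, seed = as.integer(seed)))
}

#' Specification of a synthetic cohort
#'
#' Defines the four candidate-lesion strata: two contourable classes
#' (recurrence, necrosis) whose peak uptake and heterogeneity distributions
#' differ, a stratum with no definite uptake, and a stratum whose thresholded
#' volume of interest stays at or below the small-VOI exclusion bound.
#' Defaults give the 33/11/5/3 composition of a 52-candidate cohort.
#'
#' @param n_recurrence,n_necrosis,n_no_uptake,n_subthreshold stratum sizes.
#' @param seed integer; identical seeds give bit-identical cohorts.
#' @param params per-class parameter ranges; see [cohort_params()].
#' @param cortex_range per-case normal-cortex uptake range (SUV), sampled
#'   independently of the lesion class: between-patient variation in global
#'   cortical methionine uptake, which adds patient-level noise to the T/N
#'   denominator.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_recurrence = 33, n_necrosis = 11,
                        n_no_uptake = 5, n_subthreshold = 3,
                        seed = 7, params = cohort_params(),
                        cortex_range = c(1.35, 1.58)) {
  n <- c(n_recurrence, n_necrosis, n_no_uptake, n_subthreshold)
  stop_if(any(n < 0) || sum(n) == 0, "stratum counts must be >= 0 with total > 0")
  structure(list(n_recurrence = n_recurrence, n_necrosis = n_necrosis,
                 n_no_uptake = n_no_uptake, n_subthreshold = n_subthreshold,
                 seed = as.integer(seed), params = params,
                 cortex_range = cortex_range),
            class = "cohort_spec")
}

#' Class-conditional phantom parameter ranges
#'
#' Uniform sampling ranges per stratum. The contourable classes (recurrence,
#' necrosis) draw their uptake as a tumor-to-cortex ratio target (\code{tn}),
#' tied to the per-case cortex level; the excluded strata use absolute
#' plateau SUV ranges (\code{peak}). \code{amp} is the heterogeneity
#' amplitude and \code{radius} the plateau radius in mm. The
#' recurrence/necrosis defaults are calibrated so that cohort medians of
#' post-smoothing SUVmax and GLCM dissimilarity approach the study's class
#' medians (about 3.0 vs 2.7 SUV and 0.65 vs 0.40) while keeping the classes
#' overlapping in SUVmax, as in the clinical data; they are soft targets,
#' not fitted constraints.
#'
#' @param recurrence,necrosis,no_uptake,subthreshold named lists with
#'   \code{tn} or \code{peak}, plus \code{amp} and \code{radius} ranges
#'   (length-2 numeric each).
#' @return A named list of per-class ranges.
#' @export
cohort_params <- function(recurrence = list(tn = c(1.75, 2.45), amp = c(0.30, 0.50), radius = c(11, 14)),
                          necrosis = list(tn = c(1.75, 2.25), amp = c(0.02, 0.06), radius = c(10, 13)),
                          no_uptake = list(peak = c(1.0, 1.25), amp = c(0.03, 0.08), radius = c(7, 10)),
                          subthreshold = list(peak = c(4.2, 4.6), amp = c(0.05, 0.12), radius = c(3.4, 4.0))) {
  list(recurrence = recurrence, necrosis = necrosis,
       no_uptake = no_uptake, subthreshold = subthreshold)
}

#' Generate a synthetic cohort
#'
#' Draws per-case generative parameters from the class-conditional ranges and
#' generates each phantom with a seed derived deterministically from the
#' cohort seed, so identical specs give bit-identical cohorts.
#'
#' @param cohort a [cohort_spec()].
#' @return A list of cases, each as returned by [generate_phantom()] with an
#'   added \code{case_id}.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  classes <- rep(c("recurrence", "necrosis", "no_uptake", "subthreshold"),
                 times = c(cohort$n_recurrence, cohort$n_necrosis,
                           cohort$n_no_uptake, cohort$n_subthreshold))
  set.seed(cohort$seed)
  n <- length(classes)
  draws <- matrix(stats::runif(4 * n), ncol = 4)
  cr <- cohort$cortex_range
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- cohort$params[[classes[i]]]
    u <- draws[i, ]
    amp <- pr$amp[1] + u[2] * diff(pr$amp)
    cortex <- cr[1] + u[4] * diff(cr)
    # contourable classes are parameterized by their tumor-to-cortex ratio,
    # so lesion uptake co-varies with the patient's global cortical uptake;
    # the excluded strata use absolute SUV targets
    target_suvmax <- if (!is.null(pr$tn)) {
      cortex * (pr$tn[1] + u[1] * diff(pr$tn))
    } else {
      pr$peak[1] + u[1] * diff(pr$peak)
    }
    # The hot tail of the heterogeneity field inflates the post-smoothing
    # maximum by about 1.06 * (1 + 1.2 * amplitude) under the default
    # geometry; divide it out so the class SUVmax distribution follows the
    # drawn tumor-to-cortex target rather than the texture strength.
    # Contourable classes keep a plateau floor relative to the cortex level
    # so the 1.3x-threshold VOI stays well above the small-lesion exclusion.
    plateau <- target_suvmax / (1.06 * (1 + 1.2 * amp))
    if (classes[i] %in% c("recurrence", "necrosis")) {
      plateau <- max(plateau, 1.45 * cortex)
    }
    spec <- phantom_spec(lesion_peak = plateau,
                         # tiny residual foci are PSF-limited: no infiltrative skirt
                         edge_width = if (classes[i] == "subthreshold") 0 else 3,
                         heterogeneity_amplitude = amp,
                         lesion_radius = pr$radius[1] + u[3] * diff(pr$radius),
                         cortex_mean = cortex,
                         class_label = classes[i])
    cs <- derive_seed(cohort$seed, "case", i)
    cases[[i]] <- generate_phantom(spec, cs)
    cases[[i]]$case_id <- sprintf("case_%03d", i)
  }
  cases
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' One NIfTI-1 volume per case (SUV voxel values, spacing in the header), a
#' manifest CSV (case id, label, file, cortex reference center, lesion seed
#' sphere, per-case seed) and a JSON echo of the cohort specification for
#' provenance.
#'
#' @param cases list of cases from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param cohort optional [cohort_spec()] echoed to \code{cohort_spec.json}.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cases, dir, cohort = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(dir), "cannot create output directory: ", dir)
  rows <- lapply(cases, function(cs) {
    file <- paste0(cs$case_id, ".nii")
    img <- RNifti::asNifti(cs$volume$values)
    RNifti::pixdim(img) <- cs$volume$spacing
    RNifti::writeNifti(img, file.path(dir, file))
    tr <- cs$truth
    data.frame(case_id = cs$case_id, label = tr$class_label, file = file,
               cortex_x_mm = tr$cortex_center[1], cortex_y_mm = tr$cortex_center[2],
               cortex_z_mm = tr$cortex_center[3],
               seed_x_mm = tr$seed_sphere_center[1], seed_y_mm = tr$seed_sphere_center[2],
               seed_z_mm = tr$seed_sphere_center[3],
               seed_radius_mm = tr$seed_sphere_radius,
               spacing_x_mm = cs$volume$spacing[1], spacing_y_mm = cs$volume$spacing[2],
               spacing_z_mm = cs$volume$spacing[3],
               case_seed = tr$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(cohort)) {
    jsonlite::write_json(unclass(cohort), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(mpath)
}

#' Read a cohort manifest and its volumes
#'
#' Accepts the manifest schema written by [write_cohort()]; the same schema
#' can point at clinical NIfTI volumes.
#'
#' @param manifest path to a manifest CSV.
#' @return List with \code{manifest} (data frame) and \code{volumes} (named
#'   list of [suv_volume()]).
#' @export
read_cohort <- function(manifest) {
  stop_if(!file.exists(manifest), "manifest not found: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  vols <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$file[i])
    stop_if(!file.exists(path), "volume file missing for ", man$case_id[i], ": ", path)
    img <- RNifti::readNifti(path)
    suv_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
  })
  names(vols) <- man$case_id
  list(manifest = man, volumes = vols)
}
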