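#' Gray-level discretization configuration
#'
#' Absolute resampling of SUV into a fixed number of gray levels over a fixed
#' bound. With the default convention the bin width is
#' \code{(bound_max - bound_min) / (n_levels - 1)}, which for 64 levels over
#' 0-20 SUV gives 0.317 (to three decimals); the alternative
#' \code{"n"} convention divides by \code{n_levels} instead (bin 0.3125).
#'
#' @param n_levels number of gray levels (default 64, >= 2).
#' @param bound_min,bound_max SUV bounds (default 0 and 20).
#' @param convention \code{"n_minus_1"} (default) or \code{"n"}.
#' @return An object of class \code{discretization_config} with the derived
#'   \code{bin_width}.
#' @export
discretization_config <- function(n_levels = 64, bound_min = 0, bound_max = 20,
                                  convention = c("n_minus_1", "n")) {
  convention <- match.arg(convention)
  stop_if(!is_scalar_num(n_levels) || n_levels < 2, "n_levels must be >= 2")
  stop_if(bound_max <= bound_min, "bound_max must exceed bound_min")
  denom <- if (convention == "n_minus_1") n_levels - 1 else n_levels
  structure(list(n_levels = as.integer(n_levels), bound_min = bound_min,
                 bound_max = bound_max, bin_width = (bound_max - bound_min) / denom,
                 convention = convention),
            class = "discretization_config")
}

#' Discretize a VOI into gray levels
#'
#' Level assignment is \code{clamp(1 + floor((x - bound_min) / bin_width),
#' 1, n_levels)}: SUV below the lower bound maps to level 1, SUV at or above
#' the upper bound maps to the top level, and the mapping is monotone in SUV.
#'
#' @param volume an [suv_volume()].
#' @param voi a non-empty \code{lesion_voi}.
#' @param config a [discretization_config()].
#' @return A \code{discretized_voi}: integer levels per masked voxel plus the
#'   mask geometry and the configuration used.
#' @export
discretize_voi <- function(volume, voi, config = discretization_config()) {
  stopifnot(inherits(volume, "suv_volume"), inherits(voi, "lesion_voi"),
            inherits(config, "discretization_config"))
  stop_if(voi$voxel_count == 0L, "cannot discretize an empty VOI")
  x <- volume$values[voi$mask_idx]
  lev <- 1L + as.integer(floor((x - config$bound_min) / config$bin_width))
  lev <- pmin(pmax(lev, 1L), config$n_levels)
  lev[x >= config$bound_max] <- config$n_levels # guard against rounding at the top bound
  structure(list(mask_idx = voi$mask_idx, levels = lev, dim = voi$dim,
                 spacing = voi$spacing, config = config),
            class = "discretized_voi")
}

# bounding-box integer level array with NA outside the mask, plus geometry
dvoi_array <- function(dvoi) {
  ijk <- arrayInd(dvoi$mask_idx, dvoi$dim)
  lo <- apply(ijk, 2, min)
  hi <- apply(ijk, 2, max)
  nb <- hi - lo + 1L
  arr <- array(NA_integer_, nb)
  local <- sweep(ijk, 2, lo - 1L)
  arr[(local[, 3] - 1L) * nb[1] * nb[2] + (local[, 2] - 1L) * nb[1] + local[, 1]] <-
    dvoi$levels
  arr
}
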