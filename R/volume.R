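#' SUV volume container
#'
#' A 3-D grid of standardized uptake values (SUV) with voxel spacing in mm.
#' World coordinates are in mm: voxel (i, j, k) (1-based) has its center at
#' \code{origin + (c(i, j, k) - 1) * spacing}. All analysis functions in the
#' package take and return this container.
#'
#' @param values numeric 3-D array of SUV (all finite, typically >= 0).
#' @param spacing numeric length-3, voxel edge lengths in mm (> 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   center. Defaults to the grid corner at 0 mm.
#' @return An object of class \code{suv_volume}.
#' @export
suv_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stop_if(!is.array(values) || length(dim(values)) != 3L,
          "`values` must be a 3-D array")
  stop_if(any(!is.finite(values)), "SUV values must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stop_if(length(spacing) != 3L || any(spacing <= 0),
          "`spacing` must be 3 positive mm values")
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s voxels @ %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# world-mm coordinate vectors of voxel centers along each axis
axis_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

# logical array: voxel centers within `radius` mm of `center` (<=, boundary
# has measure zero)
sphere_mask <- function(vol, center, radius) {
  cx <- axis_coords(vol)
  d2 <- lapply(1:3, function(a) (cx[[a]] - center[a])^2)
  outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+") <= radius^2
}

# Separable Gaussian smoothing with replicate (clamped-index) boundaries.
# Equivalent to dense convolution with the outer-product kernel and clamped
# indexing, because clamping acts per axis.
.gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
  }
  K
}

blur_gaussian <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  arr <- array(.gauss_band(d[1], sig / spacing[1]) %*% matrix(arr, d[1]), d)
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(.gauss_band(d[2], sig / spacing[2]) %*% matrix(a2, d[2]), dim(a2))
  arr <- aperm(a2, c(2, 1, 3))
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(.gauss_band(d[3], sig / spacing[3]) %*% matrix(a3, d[3]), dim(a3))
  aperm(a3, c(2, 3, 1))
}

# The 13 unique nearest-neighbor 3-D directions (one per +/- pair).
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  unname(g[keep, , drop = FALSE])
}

# 26-connected component of `mask` containing linear voxel index `start`
connected_component_26 <- function(mask, start) {
  d <- dim(mask)
  offs <- rbind(texture_directions(), -texture_directions())
  comp <- array(FALSE, d)
  comp[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    ijk <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (o in seq_len(nrow(offs))) {
      s <- ijk + matrix(offs[o, ], nrow(ijk), 3, byrow = TRUE)
      ok <- s[, 1] >= 1 & s[, 1] <= d[1] & s[, 2] >= 1 & s[, 2] <= d[2] &
        s[, 3] >= 1 & s[, 3] <= d[3]
      if (!any(ok)) next
      lin <- (s[ok, 3] - 1) * d[1] * d[2] + (s[ok, 2] - 1) * d[1] + s[ok, 1]
      lin <- lin[mask[lin] & !comp[lin]]
      if (length(lin)) {
        comp[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
  }
  comp
}

# label all 26-connected components of a logical array; returns integer array
# (0 outside mask)
label_components_26 <- function(mask) {
  lab <- array(0L, dim(mask))
  todo <- which(mask)
  k <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    k <- k + 1L
    comp <- connected_component_26(mask, s)
    lab[comp] <- k
  }
  lab
}
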