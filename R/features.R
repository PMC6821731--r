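#' Radiomic feature panel
#'
#' The package computes a 45-name full panel of conventional, histogram,
#' shape, co-occurrence (GLCM), run-length (GLRLM), neighborhood-difference
#' (NGLDM) and size-zone (GLZLM) features. The default active registry
#' contains 42 of them: the two log10 entropy variants and the compacity
#' shape descriptor are toggled off (log2 entropies and sphericity are kept),
#' matching the size of the study's extracted parameter set. Registry order
#' is fixed.
#'
#' @return Character vector of feature names.
#' @export
petrad_full_panel <- function() {
  c("suv_min", "suv_mean", "suv_std", "suv_max", "mtv_ml", "tlg",
    "hist_skewness", "hist_kurtosis", "hist_entropy_log2", "hist_entropy_log10",
    "hist_energy",
    "shape_sphericity", "shape_compacity",
    "glcm_homogeneity", "glcm_energy", "glcm_contrast", "glcm_correlation",
    "glcm_entropy_log2", "glcm_entropy_log10", "glcm_dissimilarity",
    "glrlm_sre", "glrlm_lre", "glrlm_lgre", "glrlm_hgre", "glrlm_srlge",
    "glrlm_srhge", "glrlm_lrlge", "glrlm_lrhge", "glrlm_glnu", "glrlm_rlnu",
    "glrlm_rp",
    "ngldm_coarseness", "ngldm_contrast", "ngldm_busyness",
    "glzlm_sze", "glzlm_lze", "glzlm_lgze", "glzlm_hgze", "glzlm_szlge",
    "glzlm_szhge", "glzlm_lzlge", "glzlm_lzhge", "glzlm_glnu", "glzlm_zlnu",
    "glzlm_zp")
}

#' @rdname petrad_full_panel
#' @export
petrad_registry <- function() {
  setdiff(petrad_full_panel(),
          c("hist_entropy_log10", "glcm_entropy_log10", "shape_compacity"))
}

#' Conventional SUV features
#'
#' SUV minimum/mean/maximum, population standard deviation, metabolic tumor
#' volume (MTV, mL) and total lesion glycolysis-style product
#' TLG = SUVmean x MTV.
#'
#' @param volume an [suv_volume()].
#' @param voi a non-empty \code{lesion_voi}.
#' @return Named numeric vector.
#' @export
conventional_features <- function(volume, voi) {
  stop_if(voi$voxel_count == 0L, "conventional features need a non-empty VOI")
  v <- volume$values[voi$mask_idx]
  mtv <- voi$voxel_count * prod(voi$spacing) / 1000
  c(suv_min = min(v), suv_mean = mean(v),
    suv_std = sqrt(mean((v - mean(v))^2)), suv_max = max(v),
    mtv_ml = mtv, tlg = mean(v) * mtv)
}

#' Histogram features of the discretized VOI
#'
#' First-order statistics of the gray-level distribution: skewness and
#' kurtosis (population moments; kurtosis is non-excess, so a normal
#' distribution gives 3; both reported as 0 for a constant region), Shannon
#' entropy in bits and in base 10, and energy (sum of squared level
#' probabilities).
#'
#' @param dvoi a \code{discretized_voi}.
#' @return Named numeric vector.
#' @export
histogram_features <- function(dvoi) {
  lev <- dvoi$levels
  n <- length(lev)
  p <- tabulate(lev, dvoi$config$n_levels) / n
  p <- p[p > 0]
  m <- mean(lev)
  m2 <- mean((lev - m)^2)
  if (m2 > 0) {
    skew <- mean((lev - m)^3) / m2^1.5
    kurt <- mean((lev - m)^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  c(hist_skewness = skew, hist_kurtosis = kurt,
    hist_entropy_log2 = -sum(p * log2(p)),
    hist_entropy_log10 = -sum(p * log10(p)),
    hist_energy = sum(p^2))
}

# level pairs (source, destination) at integer offset `dvec`, both in-mask
.pair_levels <- function(arr, dvec) {
  dims <- dim(arr)
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (a in 1:3) {
    i0 <- max(1, 1 - dvec[a])
    i1 <- min(dims[a], dims[a] - dvec[a])
    if (i0 > i1) return(NULL)
    src[[a]] <- i0:i1
    dst[[a]] <- src[[a]] + dvec[a]
  }
  A <- arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
  B <- arr[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  if (!any(ok)) return(NULL)
  cbind(A[ok], B[ok])
}

.glcm_counts <- function(arr, directions, n_levels) {
  M <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(directions))) {
    pl <- .pair_levels(arr, directions[r, ])
    if (is.null(pl)) next
    idx <- c((pl[, 2] - 1L) * n_levels + pl[, 1],
             (pl[, 1] - 1L) * n_levels + pl[, 2])
    M <- M + matrix(tabulate(idx, n_levels^2), n_levels, n_levels)
  }
  M
}

.glcm_stats <- function(P) {
  L <- nrow(P)
  i <- row(P)
  j <- col(P)
  mu <- sum(i * P)
  s2 <- sum((i - mu)^2 * P)
  corr <- if (s2 == 0) {
    warning("degenerate GLCM (zero gray-level variance); correlation set to 0")
    0
  } else sum((i - mu) * (j - mu) * P) / s2
  nz <- P[P > 0]
  c(glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_energy = sum(P^2),
    glcm_contrast = sum(P * (i - j)^2),
    glcm_correlation = corr,
    glcm_entropy_log2 = -sum(nz * log2(nz)),
    glcm_entropy_log10 = -sum(nz * log10(nz)),
    glcm_dissimilarity = sum(P * abs(i - j)))
}

#' Gray-level co-occurrence features
#'
#' Co-occurrences at distance 1 voxel, counted symmetrically with both pair
#' members in-mask. In \code{"pooled"} mode (default) counts from all
#' directions are pooled into one matrix and normalized before computing
#' features; in \code{"average"} mode features are computed per direction and
#' averaged.
#'
#' @param dvoi a \code{discretized_voi}.
#' @param directions integer matrix of voxel offsets (default: the 13 unique
#'   3-D nearest-neighbor directions).
#' @param mode \code{"pooled"} or \code{"average"}.
#' @return List with \code{matrix} (the pooled probability matrix) and
#'   \code{features} (named numeric vector).
#' @export
glcm_features <- function(dvoi, directions = texture_directions(),
                          mode = c("pooled", "average")) {
  mode <- match.arg(mode)
  L <- dvoi$config$n_levels
  arr <- dvoi_array(dvoi)
  M <- .glcm_counts(arr, directions, L)
  stop_if(sum(M) == 0, "no in-mask co-occurrence pairs; GLCM features undefined")
  P <- M / sum(M)
  feats <- if (mode == "pooled") {
    .glcm_stats(P)
  } else {
    per <- lapply(seq_len(nrow(directions)), function(r) {
      Mr <- .glcm_counts(arr, directions[r, , drop = FALSE], L)
      if (sum(Mr) == 0) return(NULL)
      .glcm_stats(Mr / sum(Mr))
    })
    per <- per[!vapply(per, is.null, logical(1))]
    colMeans(do.call(rbind, per))
  }
  list(matrix = P, features = feats)
}

# shared run/zone emphasis formulas: rows = gray level i, cols = length/size l
.rlm_style_features <- function(mat, n_total, feat_names) {
  i <- row(mat)
  l <- col(mat)
  N <- sum(mat)
  f <- c(sum(mat / l^2), sum(mat * l^2), sum(mat / i^2), sum(mat * i^2),
         sum(mat / (i^2 * l^2)), sum(mat * i^2 / l^2), sum(mat * l^2 / i^2),
         sum(mat * i^2 * l^2), sum(rowSums(mat)^2), sum(colSums(mat)^2)) / N
  out <- c(f, N / n_total)
  names(out) <- feat_names
  out
}

#' Gray-level run-length features
#'
#' Maximal same-level voxel runs along each lattice direction, pooled into
#' one level-by-length matrix. Run percentage uses the pooled-direction
#' convention: each voxel counts once per direction in the denominator.
#'
#' @inheritParams glcm_features
#' @return List with \code{matrix} (level x run-length counts) and
#'   \code{features}.
#' @export
glrlm_features <- function(dvoi, directions = texture_directions()) {
  ijk <- arrayInd(dvoi$mask_idx, dvoi$dim)
  lev <- dvoi$levels
  n <- length(lev)
  L <- dvoi$config$n_levels
  acc <- list()
  maxlen <- 1L
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    a <- which(d != 0)[1]
    t <- ijk[, a] * d[a]
    base <- max(dvoi$dim) * 3 + 1
    k1 <- ijk[, 1] - t * d[1]
    k2 <- ijk[, 2] - t * d[2]
    k3 <- ijk[, 3] - t * d[3]
    key <- (k1 + base) + (2 * base) * (k2 + base) + (2 * base)^2 * (k3 + base)
    o <- order(key, t)
    kk <- key[o]
    tt <- t[o]
    ll <- lev[o]
    newrun <- c(TRUE, kk[-1] != kk[-n] | tt[-1] != tt[-n] + 1 | ll[-1] != ll[-n])
    starts <- which(newrun)
    lens <- diff(c(starts, n + 1L))
    acc[[r]] <- cbind(ll[starts], lens)
    maxlen <- max(maxlen, lens)
  }
  runs <- do.call(rbind, acc)
  mat <- matrix(0, L, maxlen)
  idx <- (runs[, 2] - 1L) * L + runs[, 1]
  tab <- tabulate(idx, L * maxlen)
  mat <- matrix(tab, L, maxlen)
  feats <- .rlm_style_features(mat, nrow(directions) * n,
                               paste0("glrlm_", c("sre", "lre", "lgre", "hgre",
                                                  "srlge", "srhge", "lrlge",
                                                  "lrhge", "glnu", "rlnu", "rp")))
  list(matrix = mat, features = feats)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal-level voxels; the zone matrix
#' counts zones by level and size. Features mirror the run-length formulas
#' with runs replaced by zones; zone percentage is the number of zones over
#' the masked voxel count.
#'
#' @param dvoi a \code{discretized_voi}.
#' @return List with \code{matrix} (level x zone-size counts) and
#'   \code{features}.
#' @export
glzlm_features <- function(dvoi) {
  arr <- dvoi_array(dvoi)
  L <- dvoi$config$n_levels
  zones <- list()
  for (lv in sort(unique(dvoi$levels))) {
    m <- !is.na(arr) & arr == lv
    lab <- label_components_26(m)
    sizes <- tabulate(lab[lab > 0])
    zones[[length(zones) + 1L]] <- cbind(lv, sizes)
  }
  zz <- do.call(rbind, zones)
  maxs <- max(zz[, 2])
  mat <- matrix(tabulate((zz[, 2] - 1L) * L + zz[, 1], L * maxs), L, maxs)
  feats <- .rlm_style_features(mat, length(dvoi$levels),
                               paste0("glzlm_", c("sze", "lze", "lgze", "hgze",
                                                  "szlge", "szhge", "lzlge",
                                                  "lzhge", "glnu", "zlnu", "zp")))
  list(matrix = mat, features = feats)
}

#' Neighborhood gray-level difference features
#'
#' For each masked voxel the absolute difference between its level and the
#' mean level of its in-mask 26-neighbors is accumulated per level (a voxel
#' with no in-mask neighbor contributes zero). Coarseness is the inverse of
#' the probability-weighted difference sum (denominator floored at 1e-6 so a
#' constant region yields the finite maximum 1e6); contrast and busyness
#' follow the standard neighborhood-difference definitions, with degenerate
#' single-level or zero denominators mapped to 0.
#'
#' @param dvoi a \code{discretized_voi}.
#' @return List with \code{matrix} (per-level counts, difference sums,
#'   probabilities) and \code{features}.
#' @export
ngldm_features <- function(dvoi) {
  arr <- dvoi_array(dvoi)
  dims <- dim(arr)
  L <- dvoi$config$n_levels
  S <- array(0, dims)
  C <- array(0L, dims)
  offs <- rbind(texture_directions(), -texture_directions())
  for (r in seq_len(nrow(offs))) {
    dvec <- offs[r, ]
    src <- vector("list", 3)
    dst <- vector("list", 3)
    bad <- FALSE
    for (a in 1:3) {
      i0 <- max(1, 1 - dvec[a])
      i1 <- min(dims[a], dims[a] - dvec[a])
      if (i0 > i1) { bad <- TRUE; break }
      src[[a]] <- i0:i1
      dst[[a]] <- src[[a]] + dvec[a]
    }
    if (bad) next
    A <- arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
    B <- arr[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    add <- ifelse(ok, B, 0L)
    S[src[[1]], src[[2]], src[[3]]] <-
      S[src[[1]], src[[2]], src[[3]], drop = FALSE] + add
    C[src[[1]], src[[2]], src[[3]]] <-
      C[src[[1]], src[[2]], src[[3]], drop = FALSE] + ok
  }
  inmask <- !is.na(arr)
  lev <- arr[inmask]
  cn <- C[inmask]
  sm <- S[inmask]
  diffv <- ifelse(cn > 0, abs(lev - sm / cn), 0)
  n <- length(lev)
  ni <- tabulate(lev, L)
  si <- rep(0, L)
  agg <- rowsum(diffv, lev)
  si[as.integer(rownames(agg))] <- agg[, 1]
  pi_ <- ni / n
  present <- which(ni > 0)
  ngp <- length(present)
  psum <- sum(pi_ * si)
  coarseness <- 1 / max(psum, 1e-6)
  contrast <- if (ngp < 2) 0 else {
    lv <- present
    pp <- pi_[present]
    (sum(outer(pp, pp) * outer(lv, lv, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(si) / n)
  }
  den <- if (ngp < 2) 0 else {
    lv <- present
    pp <- pi_[present]
    sum(abs(outer(lv * pp, lv * pp, "-")))
  }
  busyness <- if (den > 0) psum / den else 0
  list(matrix = cbind(level = seq_len(L), n = ni, s = si, p = pi_),
       features = c(ngldm_coarseness = coarseness, ngldm_contrast = contrast,
                    ngldm_busyness = busyness))
}

#' Shape features of the VOI mask
#'
#' Sphericity \eqn{\pi^{1/3} (6V)^{2/3} / A} and compacity
#' \eqn{V / (\sqrt{\pi} A^{3/2})} from the mask volume V and its voxel-face
#' surface area A (the summed area of faces between in-mask and out-of-mask
#' voxels, including grid boundaries).
#'
#' @param voi a non-empty \code{lesion_voi}.
#' @return Named numeric vector.
#' @export
shape_features <- function(voi) {
  stop_if(voi$voxel_count == 0L, "shape features need a non-empty VOI")
  m <- voi_mask(voi)
  ijk <- arrayInd(voi$mask_idx, voi$dim)
  lo <- apply(ijk, 2, min)
  hi <- apply(ijk, 2, max)
  m <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dims <- dim(m)
  sp <- voi$spacing
  n <- sum(m)
  area <- 0
  for (a in 1:3) {
    idx1 <- lapply(dims, seq_len)
    idx2 <- idx1
    idx1[[a]] <- seq_len(dims[a] - 1L)
    idx2[[a]] <- 1L + idx1[[a]]
    adj <- if (dims[a] > 1L) {
      sum(m[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE] &
            m[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE])
    } else 0
    face <- prod(sp) / sp[a]
    area <- area + (2 * n - 2 * adj) * face
  }
  V <- n * prod(sp)
  c(shape_sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / area,
    shape_compacity = V / (sqrt(pi) * area^1.5))
}

#' Extract the full feature vector for one lesion
#'
#' Discretizes once, runs every family extractor, and assembles the
#' registry-ordered vector. Undefined features are never silently imputed;
#' family failures propagate with the family name attached.
#'
#' @param volume an [suv_volume()].
#' @param voi a non-empty (kept) \code{lesion_voi}.
#' @param config a [discretization_config()].
#' @param registry character vector of active feature names (default: the
#'   42-name registry).
#' @return Named numeric vector in registry order.
#' @export
extract_features <- function(volume, voi, config = discretization_config(),
                             registry = petrad_registry()) {
  stop_if(voi$voxel_count == 0L, "cannot extract features from an empty VOI")
  unknown <- setdiff(registry, petrad_full_panel())
  stop_if(length(unknown) > 0,
          "unknown feature names in registry: ", paste(unknown, collapse = ", "))
  dvoi <- discretize_voi(volume, voi, config)
  fam <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " features failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  full <- c(fam("conventional", conventional_features(volume, voi)),
            fam("histogram", histogram_features(dvoi)),
            fam("shape", shape_features(voi)),
            fam("GLCM", glcm_features(dvoi)$features),
            fam("GLRLM", glrlm_features(dvoi)$features),
            fam("NGLDM", ngldm_features(dvoi)$features),
            fam("GLZLM", glzlm_features(dvoi)$features))
  full[registry]
}
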