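# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately naive: explicit loops, no shared code with
# the package internals.

# dense Gaussian convolution with clamped-index (replicate) boundaries
oracle_blur <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  k1d <- lapply(1:3, function(a) {
    sv <- sig / spacing[a]
    r <- max(1L, as.integer(ceiling(4 * sv)))
    w <- dnorm(seq(-r, r), sd = sv)
    list(r = r, w = w / sum(w))
  })
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in -k1d[[1]]$r:k1d[[1]]$r)
      for (b in -k1d[[2]]$r:k1d[[2]]$r)
        for (cc in -k1d[[3]]$r:k1d[[3]]$r) {
          w <- k1d[[1]]$w[a + k1d[[1]]$r + 1] * k1d[[2]]$w[b + k1d[[2]]$r + 1] *
            k1d[[3]]$w[cc + k1d[[3]]$r + 1]
          ii <- min(max(i + a, 1), d[1])
          jj <- min(max(j + b, 1), d[2])
          kk <- min(max(k + cc, 1), d[3])
          acc <- acc + w * arr[ii, jj, kk]
        }
    out[i, j, k] <- acc
  }
  out
}

all_offsets_26 <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(o[rowSums(abs(o)) > 0, ])
}

# build a discretized_voi directly from an integer array with NA outside mask
dvoi_from_array <- function(arr, n_levels = max(arr, na.rm = TRUE),
                            spacing = c(1, 1, 1)) {
  idx <- which(!is.na(arr))
  cfg <- petrad::discretization_config(n_levels = max(n_levels, 2),
                                       bound_min = 0, bound_max = max(n_levels, 2))
  structure(list(mask_idx = idx, levels = as.integer(arr[idx]), dim = dim(arr),
                 spacing = spacing, config = cfg),
            class = "discretized_voi")
}

# random small test mask: integer level array with NA holes
random_level_array <- function(seed, max_side = 6, n_levels = 4) {
  set.seed(seed)
  d <- sample(2:max_side, 3, replace = TRUE)
  arr <- array(sample(n_levels, prod(d), replace = TRUE), d)
  arr[runif(prod(d)) < 0.35] <- NA
  if (all(is.na(arr))) arr[1] <- 1L
  arr
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# GLCM by per-voxel neighbor scan over all 26 ordered offsets
oracle_glcm <- function(arr, n_levels) {
  d <- dim(arr)
  M <- matrix(0, n_levels, n_levels)
  offs <- all_offsets_26()
  for (v in which(!is.na(arr))) {
    p <- as.integer(arrayInd(v, d))
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (!in_bounds(q, d)) next
      lq <- arr[q[1], q[2], q[3]]
      if (is.na(lq)) next
      M[arr[v], lq] <- M[arr[v], lq] + 1
    }
  }
  if (sum(M) == 0) return(NULL)
  P <- M / sum(M)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  s2 <- sum((i - mu)^2 * P)
  nz <- P[P > 0]
  list(P = P,
       feats = c(glcm_homogeneity = sum(P / (1 + abs(i - j))),
                 glcm_energy = sum(P^2),
                 glcm_contrast = sum(P * (i - j)^2),
                 glcm_correlation = if (s2 == 0) 0 else sum((i - mu) * (j - mu) * P) / s2,
                 glcm_entropy_log2 = -sum(nz * log2(nz)),
                 glcm_entropy_log10 = -sum(nz * log10(nz)),
                 glcm_dissimilarity = sum(P * abs(i - j))))
}

# run/zone emphasis formulas, written out independently
oracle_rlm_feats <- function(runs, n_total, names_prefixed) {
  # runs: matrix with columns (level, length)
  N <- nrow(runs)
  i <- runs[, 1]; l <- runs[, 2]
  gl <- tapply(rep(1, N), i, sum)
  rl <- tapply(rep(1, N), l, sum)
  out <- c(sum(1 / l^2), sum(l^2), sum(1 / i^2), sum(i^2),
           sum(1 / (i * l)^2), sum(i^2 / l^2), sum(l^2 / i^2), sum((i * l)^2),
           sum(gl^2), sum(rl^2)) / N
  out <- c(out, N / n_total)
  names(out) <- names_prefixed
  out
}

# GLRLM by explicit line walking
oracle_glrlm <- function(arr, directions) {
  d <- dim(arr)
  runs <- NULL
  for (r in seq_len(nrow(directions))) {
    dv <- directions[r, ]
    for (v in which(!is.na(arr))) {
      p <- as.integer(arrayInd(v, d))
      prev <- p - dv
      lv <- arr[v]
      prev_lv <- if (in_bounds(prev, d)) arr[prev[1], prev[2], prev[3]] else NA
      if (!is.na(prev_lv) && prev_lv == lv) next # not a run start
      len <- 1
      q <- p + dv
      while (in_bounds(q, d) && !is.na(arr[q[1], q[2], q[3]]) &&
             arr[q[1], q[2], q[3]] == lv) {
        len <- len + 1
        q <- q + dv
      }
      runs <- rbind(runs, c(lv, len))
    }
  }
  runs
}

# zones by stack-based flood fill over equal-level 26-neighbors
oracle_zones <- function(arr) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  offs <- all_offsets_26()
  zones <- NULL
  for (v in which(!is.na(arr))) {
    if (seen[v]) next
    lv <- arr[v]
    stack <- v
    seen[v] <- TRUE
    size <- 0
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1
      p <- as.integer(arrayInd(cur, d))
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!in_bounds(q, d)) next
        ql <- (q[3] - 1) * d[1] * d[2] + (q[2] - 1) * d[1] + q[1]
        if (seen[ql] || is.na(arr[ql]) || arr[ql] != lv) next
        seen[ql] <- TRUE
        stack <- c(stack, ql)
      }
    }
    zones <- rbind(zones, c(lv, size))
  }
  zones
}

# NGLDM accumulators by per-voxel neighborhood loop
oracle_ngldm <- function(arr, n_levels) {
  d <- dim(arr)
  offs <- all_offsets_26()
  ni <- rep(0, n_levels)
  si <- rep(0, n_levels)
  nvox <- 0
  for (v in which(!is.na(arr))) {
    nvox <- nvox + 1
    p <- as.integer(arrayInd(v, d))
    vals <- c()
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (!in_bounds(q, d)) next
      ql <- arr[q[1], q[2], q[3]]
      if (!is.na(ql)) vals <- c(vals, ql)
    }
    lv <- arr[v]
    ni[lv] <- ni[lv] + 1
    if (length(vals)) si[lv] <- si[lv] + abs(lv - mean(vals))
  }
  pi_ <- ni / nvox
  present <- which(ni > 0)
  ngp <- length(present)
  psum <- sum(pi_ * si)
  coars <- 1 / max(psum, 1e-6)
  contr <- 0
  if (ngp >= 2) {
    s <- 0
    for (a in present) for (b in present) s <- s + pi_[a] * pi_[b] * (a - b)^2
    contr <- s / (ngp * (ngp - 1)) * sum(si) / nvox
  }
  den <- 0
  for (a in present) for (b in present) den <- den + abs(a * pi_[a] - b * pi_[b])
  busy <- if (den > 0) psum / den else 0
  c(ngldm_coarseness = coars, ngldm_contrast = contr, ngldm_busyness = busy)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

oracle_auc <- function(scores, labels, positive = "recurrence") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# small uniform-intensity VOI builder for feature unit tests
make_test_voi <- function(values, mask, spacing = c(2, 2, 2)) {
  vol <- petrad::suv_volume(values, spacing)
  petrad:::.make_voi(vol, mask, threshold_suv = 0, reference_mean = 1)
}

# lesion-sphere mask from a generated case's ground truth
sphere_mask_of <- function(cs) {
  petrad:::sphere_mask(cs$volume, cs$truth$spec$lesion_center,
                       cs$truth$spec$lesion_radius)
}
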