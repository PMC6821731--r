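test_that("discretization maps SUV to levels with the printed bin width", {
  cfg <- discretization_config()
  expect_equal(round(cfg$bin_width, 3), 0.317)
  expect_equal(discretization_config(convention = "n")$bin_width, 0.3125)

  vals <- array(1, c(16, 16, 16))
  mask <- array(FALSE, c(16, 16, 16)); mask[4:8, 4:8, 4:8] <- TRUE
  put <- function(x) {
    v <- vals; v[mask] <- x
    vol <- suv_volume(v, c(2, 2, 2))
    discretize_voi(vol, petrad:::.make_voi(vol, mask, 0.5, 1), cfg)$levels
  }
  expect_true(all(put(0) == 1L))
  expect_true(all(put(20) == 64L))
  expect_true(all(put(25) == 64L))
  expect_true(all(put(2.0) == 7L))
  expect_true(all(put(-1) == 1L))
  # monotone in SUV
  set.seed(1)
  x <- sort(runif(125, 0, 22))
  v <- vals; v[mask] <- x
  vol <- suv_volume(v, c(2, 2, 2))
  lev <- discretize_voi(vol, petrad:::.make_voi(vol, mask, 0.5, 1), cfg)$levels
  expect_true(all(diff(lev[order(v[mask])]) >= 0))
})

test_that("conventional features match hand values and a naive oracle", {
  vals <- array(0, c(10, 10, 10))
  mask <- array(FALSE, c(10, 10, 10)); mask[1:4, 1:5, 1:5] <- TRUE # 100 voxels
  vals[mask] <- 2
  vol <- suv_volume(vals, c(2, 2, 2))
  f <- conventional_features(vol, petrad:::.make_voi(vol, mask, 0, 1))
  expect_equal(unname(f[c("suv_mean", "suv_std", "mtv_ml", "tlg")]),
               c(2, 0, 0.8, 1.6))

  vals[mask] <- rep(c(1, 3), 50)
  vol <- suv_volume(vals, c(2, 2, 2))
  f <- conventional_features(vol, petrad:::.make_voi(vol, mask, 0, 1))
  expect_equal(unname(f["suv_mean"]), 2)
  expect_equal(unname(f["suv_std"]), 1)

  set.seed(2)
  vals[mask] <- runif(100, 0, 5)
  vol <- suv_volume(vals, c(1.5, 2, 2.5))
  voi <- petrad:::.make_voi(vol, mask, 0, 1)
  f <- conventional_features(vol, voi)
  v <- vals[mask]
  expect_equal(unname(f["suv_min"]), min(v), tolerance = 1e-10)
  expect_equal(unname(f["suv_std"]), sqrt(sum((v - sum(v) / 100)^2) / 100),
               tolerance = 1e-10)
  expect_equal(unname(f["mtv_ml"]), 100 * 1.5 * 2 * 2.5 / 1000, tolerance = 1e-12)
})

test_that("histogram features obey closed forms", {
  d4 <- dvoi_from_array(array(c(1, 2, 3, 4), c(4, 1, 1)), n_levels = 4)
  h <- histogram_features(d4)
  expect_equal(unname(h["hist_entropy_log2"]), 2)
  expect_equal(unname(h["hist_energy"]), 0.25)
  d1 <- dvoi_from_array(array(2L, c(3, 3, 1)), n_levels = 4)
  h1 <- histogram_features(d1)
  expect_equal(unname(h1[c("hist_entropy_log2", "hist_energy")]), c(0, 1))
  d2 <- dvoi_from_array(array(c(1, 1, 2, 2), c(4, 1, 1)), n_levels = 2)
  h2 <- histogram_features(d2)
  expect_equal(unname(h2[c("hist_energy", "hist_entropy_log2")]), c(0.5, 1))
  # kurtosis convention: a symmetric two-point distribution has kurtosis 1
  expect_equal(unname(h2["hist_kurtosis"]), 1)
})

test_that("GLCM features reproduce the collinear toy case and constant identities", {
  dv <- dvoi_from_array(array(c(1L, 1L, 2L, 2L), c(4, 1, 1)), n_levels = 2)
  g <- glcm_features(dv, directions = matrix(c(1, 0, 0), 1))$features
  expect_equal(unname(g["glcm_dissimilarity"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(g["glcm_contrast"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(g["glcm_homogeneity"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(g["glcm_energy"]), 10 / 36, tolerance = 1e-12)
  expect_equal(unname(g["glcm_entropy_log2"]),
               -(2 * (2 / 6) * log2(2 / 6) + 2 * (1 / 6) * log2(1 / 6)),
               tolerance = 1e-12)

  const <- dvoi_from_array(array(3L, c(3, 3, 3)), n_levels = 4)
  gc <- suppressWarnings(glcm_features(const)$features)
  expect_equal(unname(gc[c("glcm_dissimilarity", "glcm_contrast")]), c(0, 0))
  expect_equal(unname(gc[c("glcm_homogeneity", "glcm_energy")]), c(1, 1))
  expect_equal(unname(gc["glcm_entropy_log2"]), 0)
  expect_warning(glcm_features(const), "correlation")

  single <- dvoi_from_array(array(1L, c(1, 1, 1)), n_levels = 2)
  expect_error(glcm_features(single), "no in-mask")
})

test_that("GLCM matrix is symmetric and sums to one", {
  for (s in 1:20) {
    arr <- random_level_array(s)
    dv <- dvoi_from_array(arr)
    P <- tryCatch(glcm_features(dv)$matrix, error = function(e) NULL)
    if (is.null(P)) next
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
  }
})

test_that("GLRLM reproduces the 1-D toy run decomposition", {
  dv <- dvoi_from_array(array(c(1L, 1L, 2L, 2L, 2L), c(5, 1, 1)), n_levels = 2)
  g <- glrlm_features(dv, directions = matrix(c(1, 0, 0), 1))$features
  expect_equal(unname(g["glrlm_rp"]), 0.4)
  expect_equal(unname(g["glrlm_sre"]), (1 / 4 + 1 / 9) / 2, tolerance = 1e-12)
  expect_equal(unname(g["glrlm_lre"]), 6.5)
  expect_equal(unname(g["glrlm_hgre"]), 2.5)
  expect_equal(unname(g["glrlm_lgre"]), 0.625)

  n <- 7
  dcn <- dvoi_from_array(array(2L, c(n, 1, 1)), n_levels = 2)
  gc <- glrlm_features(dcn, directions = matrix(c(1, 0, 0), 1))$features
  expect_equal(unname(gc["glrlm_rp"]), 1 / n)
  expect_equal(unname(gc["glrlm_lre"]), n^2)
})

test_that("GLZLM reproduces the toy zone decomposition and single-zone limits", {
  dv <- dvoi_from_array(array(c(1L, 1L, 2L, 2L, 2L), c(5, 1, 1)), n_levels = 2)
  g <- glzlm_features(dv)$features
  expect_equal(unname(g["glzlm_zp"]), 0.4)
  expect_equal(unname(g["glzlm_sze"]), (1 / 4 + 1 / 9) / 2, tolerance = 1e-12)
  n <- 3 * 2 * 2
  gc <- glzlm_features(dvoi_from_array(array(1L, c(3, 2, 2)), n_levels = 2))$features
  expect_equal(unname(gc["glzlm_zp"]), 1 / n)
  expect_equal(unname(gc["glzlm_lze"]), n^2)
})

test_that("NGLDM constant-region identities hold", {
  const <- dvoi_from_array(array(2L, c(4, 4, 2)), n_levels = 4)
  f <- ngldm_features(const)$features
  expect_equal(unname(f["ngldm_contrast"]), 0)
  # coarseness is maximal for a constant mask of the same geometry
  set.seed(3)
  arr <- array(sample(1:4, 32, TRUE), c(4, 4, 2))
  fr <- ngldm_features(dvoi_from_array(arr, n_levels = 4))$features
  expect_gt(unname(f["ngldm_coarseness"]), unname(fr["ngldm_coarseness"]))
})

test_that("every texture family matches its brute-force oracle on random masks", {
  dirs <- petrad:::texture_directions()
  for (s in 1:25) {
    arr <- random_level_array(s, max_side = 5)
    nl <- 4
    dv <- dvoi_from_array(arr, n_levels = nl)
    og <- oracle_glcm(arr, nl)
    if (!is.null(og)) {
      got <- glcm_features(dv)$features
      expect_equal(got, og$feats, tolerance = 1e-10)
    }
    runs <- oracle_glrlm(arr, dirs)
    want <- oracle_rlm_feats(runs, nrow(dirs) * sum(!is.na(arr)), names(glrlm_features(dv)$features))
    expect_equal(glrlm_features(dv)$features, want, tolerance = 1e-10)
    zz <- oracle_zones(arr)
    wantz <- oracle_rlm_feats(zz, sum(!is.na(arr)), names(glzlm_features(dv)$features))
    expect_equal(glzlm_features(dv)$features, wantz, tolerance = 1e-10)
    expect_equal(ngldm_features(dv)$features, oracle_ngldm(arr, nl), tolerance = 1e-10)
  }
})

test_that("shape features follow the voxel-face surface convention", {
  # single voxel: cube closed form, independent of voxel size
  vals <- array(1, c(12, 12, 12))
  mk <- array(FALSE, c(12, 12, 12)); mk[6, 6, 6] <- TRUE
  f1 <- shape_features(make_test_voi(vals, mk))
  expect_equal(unname(f1["shape_sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)

  # elongated bar is less spherical than a digital ball of similar volume
  bar <- array(FALSE, c(40, 12, 12)); bar[1:33, 6, 6] <- TRUE
  fbar <- shape_features(make_test_voi(array(1, c(40, 12, 12)), bar))
  vol0 <- suv_volume(array(1, c(12, 12, 12)), c(2, 2, 2))
  ball <- petrad:::sphere_mask(vol0, c(11, 11, 11), 4.1)
  fball <- shape_features(make_test_voi(array(1, c(12, 12, 12)), ball))
  expect_lt(unname(fbar["shape_sphericity"]), unname(fball["shape_sphericity"]))
  expect_lt(unname(fbar["shape_compacity"]), unname(fball["shape_compacity"]))
})

test_that("the assembled vector is registry-ordered, deterministic and order-invariant", {
  ph <- generate_phantom(phantom_spec(), seed = 77)
  ref <- measure_cortex_reference(ph$volume, reference_sphere(ph$truth$cortex_center))
  voi <- contour_lesion(ph$volume,
                        reference_sphere(ph$truth$seed_sphere_center,
                                         radius = ph$truth$seed_sphere_radius), ref)
  fv <- extract_features(ph$volume, voi)
  expect_length(fv, 42)
  expect_identical(names(fv), petrad_registry())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(ph$volume, voi))
  # permuting stored voxel order changes nothing
  voi2 <- voi
  set.seed(1)
  voi2$mask_idx <- sample(voi$mask_idx)
  expect_equal(extract_features(ph$volume, voi2), fv, tolerance = 1e-12)
  expect_length(extract_features(ph$volume, voi, registry = petrad_full_panel()), 45)
  expect_error(extract_features(ph$volume, voi, registry = c("suv_max", "nope")),
               "unknown feature")
})
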