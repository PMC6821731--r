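#' Pipeline configuration
#'
#' Aggregates all stage settings: the cohort to simulate (or a manifest of
#' existing volumes), segmentation factor and small-VOI bound,
#' discretization, and the classifier configuration. The global seed
#' deterministically derives the classifier seed; the cohort specification
#' carries its own seed because it defines the fixture, not the analysis
#' randomness.
#'
#' @param cohort a [cohort_spec()], or \code{NULL} when \code{manifest} is
#'   given.
#' @param manifest optional path to an existing cohort manifest CSV.
#' @param outdir output directory for all persisted artifacts.
#' @param seed global analysis seed.
#' @param factor contouring threshold multiplier (default 1.3).
#' @param min_voxels inclusive small-VOI exclusion bound (default 64).
#' @param disc a [discretization_config()].
#' @param rf an [rf_config()]; its seed is re-derived from \code{seed}.
#' @param tune logical: run the ntree grid search before evaluation.
#' @param write_masks logical: persist VOI masks as NIfTI.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_spec(), manifest = NULL,
                            outdir = tempfile("petrad_run_"), seed = 1,
                            factor = 1.3, min_voxels = 64,
                            disc = discretization_config(),
                            rf = rf_config(), tune = FALSE,
                            write_masks = TRUE) {
  stop_if(is.null(cohort) && is.null(manifest),
          "either a cohort spec or a manifest path is required")
  rf$seed <- derive_seed(seed, "classify")
  structure(list(cohort = cohort, manifest = manifest, outdir = outdir,
                 seed = as.integer(seed), factor = factor,
                 min_voxels = min_voxels, disc = disc, rf = rf, tune = tune,
                 write_masks = write_masks),
            class = "pipeline_config")
}

#' Pipeline stage: simulate
#'
#' Generates the cohort and persists volumes plus manifest under
#' \code{file.path(outdir, "cohort")}.
#'
#' @param cohort a [cohort_spec()].
#' @param outdir run directory.
#' @return Path to the manifest CSV.
#' @export
stage_simulate <- function(cohort, outdir) {
  cases <- generate_cohort(cohort)
  write_cohort(cases, file.path(outdir, "cohort"), cohort = cohort)
}

#' Pipeline stage: segment
#'
#' For every manifest case: cortex reference SUVmean from a 1.0-cm^3 sphere,
#' threshold contouring inside the seed sphere, exclusion rules, T/N ratio.
#' Writes \code{segmentation/vois.csv}, \code{segmentation/exclusions.csv}
#' and (optionally) per-case VOI masks as NIfTI byte volumes.
#'
#' @param manifest path to a cohort manifest CSV.
#' @param outdir run directory.
#' @param factor threshold multiplier.
#' @param min_voxels inclusive small-VOI bound.
#' @param write_masks persist VOI masks.
#' @return The per-case VOI summary data frame, invisibly.
#' @export
stage_segment <- function(manifest, outdir, factor = 1.3, min_voxels = 64,
                          write_masks = TRUE) {
  coh <- read_cohort(manifest)
  man <- coh$manifest
  segdir <- file.path(outdir, "segmentation")
  dir.create(segdir, recursive = TRUE, showWarnings = FALSE)
  vois <- vector("list", nrow(man))
  names(vois) <- man$case_id
  refs <- numeric(nrow(man))
  for (i in seq_len(nrow(man))) {
    vol <- coh$volumes[[man$case_id[i]]]
    ref <- measure_cortex_reference(vol, reference_sphere(
      c(man$cortex_x_mm[i], man$cortex_y_mm[i], man$cortex_z_mm[i])))
    refs[i] <- ref
    seedsp <- reference_sphere(c(man$seed_x_mm[i], man$seed_y_mm[i], man$seed_z_mm[i]),
                               radius = man$seed_radius_mm[i])
    vois[[i]] <- contour_lesion(vol, seedsp, ref, factor)
  }
  excl <- apply_exclusions(vois, min_voxels)
  df <- data.frame(case_id = man$case_id, label = man$label,
                   status = excl$cases$status,
                   reference_mean = refs,
                   threshold_suv = vapply(vois, function(v) v$threshold_suv, numeric(1)),
                   voxel_count = vapply(vois, function(v) v$voxel_count, integer(1)),
                   volume_ml = vapply(vois, function(v) v$volume_ml, numeric(1)),
                   suv_max = vapply(vois, function(v) v$suv_max, numeric(1)),
                   suv_mean = vapply(vois, function(v) v$suv_mean, numeric(1)),
                   suv_sd = vapply(vois, function(v) v$suv_sd, numeric(1)),
                   stringsAsFactors = FALSE)
  df$tn_ratio <- ifelse(df$voxel_count > 0, df$suv_max / df$reference_mean, NA_real_)
  utils::write.csv(df, file.path(segdir, "vois.csv"), row.names = FALSE)
  utils::write.csv(excl$cases, file.path(segdir, "exclusions.csv"), row.names = FALSE)
  if (write_masks) {
    for (i in seq_len(nrow(man))) {
      if (df$status[i] != "kept") next
      v <- vois[[i]]
      img <- RNifti::asNifti(array(as.integer(voi_mask(v)), v$dim))
      RNifti::pixdim(img) <- v$spacing
      RNifti::writeNifti(img, file.path(segdir, paste0(man$case_id[i], "_mask.nii")))
    }
  }
  invisible(df)
}

#' Pipeline stage: extract
#'
#' Reads the persisted volumes, VOI masks and segmentation summaries, and
#' writes the per-lesion feature table \code{features.csv} (case id, label,
#' registry features, T/N ratio) with a JSON sidecar recording the
#' discretization configuration and registry.
#'
#' @param outdir run directory containing \code{cohort/} and
#'   \code{segmentation/}.
#' @param disc a [discretization_config()].
#' @param registry active feature registry.
#' @return The feature table, invisibly.
#' @export
stage_extract <- function(outdir, disc = discretization_config(),
                          registry = petrad_registry()) {
  coh <- read_cohort(file.path(outdir, "cohort", "manifest.csv"))
  seg <- utils::read.csv(file.path(outdir, "segmentation", "vois.csv"),
                         stringsAsFactors = FALSE)
  kept <- seg[seg$status == "kept", ]
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    cid <- kept$case_id[i]
    vol <- coh$volumes[[cid]]
    mpath <- file.path(outdir, "segmentation", paste0(cid, "_mask.nii"))
    stop_if(!file.exists(mpath), "VOI mask missing for ", cid, ": ", mpath)
    mask <- as.array(RNifti::readNifti(mpath)) > 0
    voi <- .make_voi(vol, mask, kept$threshold_suv[i], kept$reference_mean[i])
    fv <- extract_features(vol, voi, disc, registry)
    cbind(data.frame(case_id = cid, label = kept$label[i], stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)), data.frame(tn_ratio = kept$tn_ratio[i]))
  })
  feat <- do.call(rbind, rows)
  utils::write.csv(feat, file.path(outdir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(list(discretization = unclass(disc), registry = registry),
                       file.path(outdir, "features_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(feat)
}

#' Pipeline stage: classify
#'
#' Optional ntree-grid tuning, repeated stratified cross-validation and
#' Gini importance on the feature table. Writes \code{predictions.csv},
#' \code{importance.csv} and (when tuning) \code{tuning_trace.csv}.
#'
#' @param outdir run directory containing \code{features.csv}.
#' @param rf an [rf_config()].
#' @param tune logical; when TRUE the tuned ntree replaces \code{rf$ntree}.
#' @param registry feature registry (columns used for classification).
#' @return The \code{petrad_cv} object, invisibly.
#' @export
stage_classify <- function(outdir, rf = rf_config(), tune = FALSE,
                           registry = petrad_registry()) {
  feat <- utils::read.csv(file.path(outdir, "features.csv"),
                          stringsAsFactors = FALSE)
  x <- as.matrix(feat[, registry])
  labels <- feat$label
  if (tune) {
    tf <- tune_forest(x, labels, rf)
    rf$ntree <- tf$ntree
    utils::write.csv(tf$trace, file.path(outdir, "tuning_trace.csv"),
                     row.names = FALSE)
  }
  cv <- cross_validate(x, labels, rf, case_ids = feat$case_id)
  utils::write.csv(cv$predictions, file.path(outdir, "predictions.csv"),
                   row.names = FALSE)
  imp <- gini_importance(x, labels, rf)
  utils::write.csv(imp, file.path(outdir, "importance.csv"), row.names = FALSE)
  invisible(cv)
}

# per-repeat confusion + AUC metrics from a predictions data frame,
# averaged over repeats (the package-wide aggregation convention)
.metrics_from_predictions <- function(pred, positive = "recurrence") {
  per <- lapply(split(pred, pred$rep), function(pr) {
    cm <- confusion_from_predictions(pr$label, pr$predicted, positive)
    roc <- roc_auc(pr$probability, pr$label, positive)
    c(unlist(confusion_metrics(cm)), auc = roc$auc)
  })
  per <- do.call(rbind, per)
  colMeans(per)
}

#' Pipeline stage: evaluate
#'
#' Builds both evaluation arms from the persisted intermediates: the
#' radiomics arm (averaged out-of-fold confusion metrics and AUC over
#' repeats) and the T/N-ratio arm (ROC over the kept lesions' T/N ratios,
#' Youden-optimal cutoff, confusion at that cutoff), plus the per-feature
#' group comparison. Writes \code{metrics.json},
#' \code{roc_radiomics.csv}, \code{roc_tn_ratio.csv} and
#' \code{group_comparison.csv}.
#'
#' @param outdir run directory containing \code{features.csv} and
#'   \code{predictions.csv}.
#' @param smote_mode provenance string recorded with the radiomics arm.
#' @param registry feature registry used for the group comparison.
#' @return List with both arms' summaries, invisibly.
#' @export
stage_evaluate <- function(outdir, smote_mode = "inside_cv",
                           registry = petrad_registry()) {
  feat <- utils::read.csv(file.path(outdir, "features.csv"),
                          stringsAsFactors = FALSE)
  pred <- utils::read.csv(file.path(outdir, "predictions.csv"),
                          stringsAsFactors = FALSE)
  rad <- as.list(.metrics_from_predictions(pred))
  rad$arm <- "radiomics"
  rad$smote_mode <- smote_mode
  pooled_roc <- roc_auc(pred$probability, pred$label)
  tn_roc <- roc_auc(feat$tn_ratio, feat$label)
  tn_pred <- ifelse(feat$tn_ratio >= tn_roc$cutoff, "recurrence", "necrosis")
  tn <- confusion_metrics(confusion_from_predictions(feat$label, tn_pred))
  tn$auc <- tn_roc$auc
  tn$cutoff <- tn_roc$cutoff
  tn$arm <- "tn_ratio"
  grp <- compare_groups(as.matrix(feat[, registry]), feat$label)
  utils::write.csv(data.frame(threshold = pooled_roc$thresholds,
                              fpr = pooled_roc$fpr, tpr = pooled_roc$tpr),
                   file.path(outdir, "roc_radiomics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(threshold = tn_roc$thresholds,
                              fpr = tn_roc$fpr, tpr = tn_roc$tpr),
                   file.path(outdir, "roc_tn_ratio.csv"), row.names = FALSE)
  utils::write.csv(grp, file.path(outdir, "group_comparison.csv"), row.names = FALSE)
  metrics <- list(radiomics = rad, tn_ratio = tn)
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}

#' Run the full pipeline
#'
#' simulate -> segment -> extract -> classify -> evaluate, persisting every
#' intermediate under \code{config$outdir}. Re-running with the same
#' configuration and seed reproduces all CSV/JSON artifacts byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return An object of class \code{petrad_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (!is.null(config$manifest)) config$manifest
              else stage_simulate(config$cohort, outdir)
  seg <- stage_segment(manifest, outdir, config$factor, config$min_voxels,
                       write_masks = TRUE)
  feat <- stage_extract(outdir, config$disc)
  cv <- stage_classify(outdir, config$rf, tune = config$tune)
  metrics <- stage_evaluate(outdir, smote_mode = config$rf$smote_mode)
  imp <- utils::read.csv(file.path(outdir, "importance.csv"),
                         stringsAsFactors = FALSE)
  report <- list(
    version = as.character(utils::packageVersion("petrad")),
    seed = config$seed,
    config = list(factor = config$factor, min_voxels = config$min_voxels,
                  discretization = unclass(config$disc),
                  rf = unclass(config$rf), tune = config$tune,
                  cohort = if (!is.null(config$cohort)) unclass(config$cohort)["seed"]),
    exclusions = as.list(table(seg$status)),
    n_kept = sum(seg$status == "kept"),
    n_features = length(petrad_registry()),
    metrics = metrics,
    importance_top5 = utils::head(imp, 5),
    files = list(manifest = file.path("cohort", "manifest.csv"),
                 vois = file.path("segmentation", "vois.csv"),
                 features = "features.csv",
                 predictions = "predictions.csv",
                 importance = "importance.csv",
                 metrics = "metrics.json"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(report, class = "petrad_report")
}

#' @export
print.petrad_report <- function(x, ...) {
  cat("<petrad_report>\n")
  cat(sprintf("  lesions kept: %d (of %d candidates)\n", x$n_kept,
              sum(unlist(x$exclusions))))
  r <- x$metrics$radiomics
  t <- x$metrics$tn_ratio
  cat(sprintf("  radiomics arm (smote: %s): sens %.3f spec %.3f acc %.3f AUC %.3f\n",
              r$smote_mode, r$sensitivity, r$specificity, r$accuracy, r$auc))
  cat(sprintf("  T/N-ratio arm: sens %.3f spec %.3f acc %.3f AUC %.3f (cutoff %.3f)\n",
              t$sensitivity, t$specificity, t$accuracy, t$auc, t$cutoff))
  cat("  top features by mean decrease in Gini:\n")
  print(x$importance_top5)
  invisible(x)
}
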