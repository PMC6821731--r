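#' Random-forest pipeline configuration
#'
#' Hyperparameters for the SMOTE-balanced random-forest stage. Defaults
#' mirror the study's printed settings: the ntree tuning grid
#' (100, 250, 500, 750, 1000, 1500) with the selected operating point
#' ntree = 100, mtry = 1; 10-fold cross-validation with 100 tuning repeats
#' and 10 evaluation repeats; SMOTE with 5 minority nearest neighbors.
#'
#' @param ntree_grid candidate tree counts for tuning.
#' @param ntree tree count used for evaluation when not tuning.
#' @param mtry features tried per split.
#' @param n_folds folds per repeat (>= 2).
#' @param n_tune_repeats,n_eval_repeats repeats for tuning and evaluation.
#' @param smote_k SMOTE neighbor count.
#' @param smote_mode \code{"inside_cv"} applies standardization and SMOTE to
#'   the training folds only (leak-free default); \code{"before_cv"} balances
#'   the whole cohort first (replication mode: synthetic copies then cross
#'   fold boundaries and inflate apparent performance).
#' @param positive_class label treated as positive (default "recurrence").
#' @param seed integer master seed for folding, SMOTE and forest fits.
#' @return An object of class \code{rf_config}.
#' @export
rf_config <- function(ntree_grid = c(100, 250, 500, 750, 1000, 1500),
                      ntree = 100, mtry = 1, n_folds = 10,
                      n_tune_repeats = 100, n_eval_repeats = 10,
                      smote_k = 5, smote_mode = c("inside_cv", "before_cv"),
                      positive_class = "recurrence", seed = 1) {
  smote_mode <- match.arg(smote_mode)
  stop_if(length(ntree_grid) == 0, "ntree_grid must be nonempty")
  stop_if(n_folds < 2, "n_folds must be >= 2")
  stop_if(mtry < 1, "mtry must be >= 1")
  structure(list(ntree_grid = ntree_grid, ntree = ntree, mtry = mtry,
                 n_folds = n_folds, n_tune_repeats = n_tune_repeats,
                 n_eval_repeats = n_eval_repeats, smote_k = smote_k,
                 smote_mode = smote_mode, positive_class = positive_class,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Center and scale a feature matrix
#'
#' Each column is centered to mean 0 and scaled to sample standard deviation
#' 1 on the fitting set. Constant columns are left unscaled (divisor 1) with
#' a warning. The returned parameters can be re-applied to held-out data with
#' [apply_center_scale()].
#'
#' @param x numeric matrix or data frame (rows = lesions).
#' @return List with \code{x} (standardized matrix), \code{center},
#'   \code{scale}.
#' @export
center_scale <- function(x) {
  x <- as.matrix(x)
  stop_if(nrow(x) < 2, "center_scale needs at least 2 rows")
  if (any(is.na(x))) {
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    stop("missing values in feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    warning("constant feature column(s) left unscaled: ",
            paste(colnames(x)[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' @rdname center_scale
#' @param params list with \code{center} and \code{scale} from a fitted
#'   [center_scale()].
#' @export
apply_center_scale <- function(x, params) {
  sweep(sweep(as.matrix(x), 2, params$center), 2, params$scale, "/")
}

#' SMOTE class balancing
#'
#' Oversamples the minority class up to the majority size with synthetic
#' rows: each synthetic point is a convex combination
#' \eqn{x + u (x_{nn} - x)}, \eqn{u \sim U(0,1)}, of a minority row and one
#' of its k nearest minority neighbors (Euclidean distance, intended for
#' standardized features). Original rows are preserved unchanged; the result
#' is deterministic given the seed.
#'
#' @param x numeric feature matrix.
#' @param labels factor or character class labels (two classes).
#' @param k neighbor count (clipped with a warning if it exceeds minority
#'   size minus 1).
#' @param seed integer seed.
#' @return List with \code{x}, \code{labels}, and logical \code{synthetic}.
#' @export
smote_balance <- function(x, labels, k = 5, seed = 1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  tab <- table(labels)
  stop_if(length(tab) != 2, "smote_balance expects exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab)
  n_syn <- max(tab) - n_min
  if (n_syn == 0) {
    return(list(x = x, labels = labels, synthetic = rep(FALSE, nrow(x))))
  }
  stop_if(n_min < 2, "minority class must have at least 2 members for SMOTE")
  if (k > n_min - 1) {
    warning("smote k clipped from ", k, " to ", n_min - 1)
    k <- n_min - 1
  }
  set.seed(as.integer(seed))
  mi <- which(labels == minority)
  xm <- x[mi, , drop = FALSE]
  dmat <- as.matrix(stats::dist(xm))
  diag(dmat) <- Inf
  nn <- matrix(apply(dmat, 1, function(r) order(r)[seq_len(k)]),
               nrow = n_min, ncol = k, byrow = TRUE)
  base <- rep_len(sample(n_min), n_syn)
  pick <- nn[cbind(base, sample(k, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  syn <- xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  list(x = rbind(x, syn),
       labels = c(labels, rep(minority, n_syn)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_syn)))
}

# stratified folds balanced overall (sizes differ by <= 1) and within class
# (class counts per fold differ by <= 1); deterministic given seed
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(as.integer(seed))
  n <- length(labels)
  stop_if(n < n_folds, "fewer lesions than folds; reduce n_folds")
  fold <- integer(n)
  totals <- integer(n_folds)
  for (cl in names(sort(table(labels), decreasing = TRUE))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      f <- order(totals, seq_len(n_folds))[1]
      fold[i] <- f
      totals[f] <- totals[f] + 1L
    }
  }
  fold
}

# one repeat of out-of-fold random-forest predictions
.cv_one_repeat <- function(x, labels, config, ntree, rep_seed) {
  n <- length(labels)
  fold <- stratified_folds(labels, config$n_folds, rep_seed)
  prob <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(unique(labels[tr])) < 2) {
      stop("a training fold lost a class; cohort too small for ",
           config$n_folds, "-fold CV", call. = FALSE)
    }
    cs <- center_scale(x[tr, , drop = FALSE])
    xtr <- cs$x
    ytr <- labels[tr]
    if (config$smote_mode == "inside_cv") {
      sm <- smote_balance(xtr, ytr, config$smote_k,
                          derive_seed(rep_seed, "smote", f))
      xtr <- sm$x
      ytr <- sm$labels
    }
    xte <- apply_center_scale(x[te, , drop = FALSE], cs)
    set.seed(derive_seed(rep_seed, "rf", f))
    fit <- randomForest::randomForest(x = xtr, y = factor(ytr),
                                      ntree = ntree, mtry = config$mtry)
    prob[te] <- stats::predict(fit, xte, type = "prob")[, config$positive_class]
  }
  list(prob = prob, fold = fold)
}

#' Repeated stratified cross-validation of the SMOTE random forest
#'
#' Repeated stratified 10-fold cross-validation with per-fold
#' standardization. In the default \code{inside_cv} mode SMOTE is applied to
#' the training folds only; \code{before_cv} balances the whole cohort
#' before splitting (replication mode, flagged in the result). Out-of-fold
#' class probabilities for the positive class are recorded for every lesion
#' in every repeat; hard labels use the 0.5 probability threshold.
#'
#' @param x feature matrix (rows = lesions, columns = registry features).
#' @param labels class labels (two classes).
#' @param config an [rf_config()].
#' @param case_ids optional case identifiers.
#' @return An object of class \code{petrad_cv}: a predictions data frame
#'   (case_id, repeat, fold, probability, predicted, label), per-repeat and
#'   averaged metrics, and the configuration.
#' @export
cross_validate <- function(x, labels, config = rf_config(), case_ids = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stop_if(length(unique(labels)) != 2, "both classes must be present")
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_along(labels))
  if (config$smote_mode == "before_cv") {
    cs <- center_scale(x)
    sm <- smote_balance(cs$x, labels, config$smote_k,
                        derive_seed(config$seed, "smote_global"))
    x <- sm$x
    labels <- sm$labels
    case_ids <- c(case_ids, sprintf("synthetic_%03d", seq_len(sum(sm$synthetic))))
  }
  pos <- config$positive_class
  neg <- setdiff(unique(labels), pos)
  reps <- vector("list", config$n_eval_repeats)
  metr <- vector("list", config$n_eval_repeats)
  for (r in seq_len(config$n_eval_repeats)) {
    rs <- derive_seed(config$seed, "eval", r)
    cv <- .cv_one_repeat(x, labels, config, config$ntree, rs)
    pred <- ifelse(cv$prob >= 0.5, pos, neg)
    reps[[r]] <- data.frame(case_id = case_ids, rep = r, fold = cv$fold,
                            probability = cv$prob, predicted = pred,
                            label = labels, stringsAsFactors = FALSE)
    cm <- confusion_from_predictions(labels, pred, positive = pos)
    roc <- roc_auc(cv$prob, labels, positive = pos)
    metr[[r]] <- c(unlist(confusion_metrics(cm)), auc = roc$auc)
  }
  per_repeat <- do.call(rbind, metr)
  structure(list(predictions = do.call(rbind, reps),
                 per_repeat = per_repeat,
                 metrics = colMeans(per_repeat),
                 smote_mode = config$smote_mode,
                 config = config),
            class = "petrad_cv")
}

#' @export
print.petrad_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<petrad_cv> %d repeats x %d-fold (smote: %s)\n",
              x$config$n_eval_repeats, x$config$n_folds, x$smote_mode))
  cat(sprintf("  mean sensitivity %.3f, specificity %.3f, accuracy %.3f, AUC %.3f\n",
              m["sensitivity"], m["specificity"], m["accuracy"], m["auc"]))
  invisible(x)
}

#' @export
summary.petrad_cv <- function(object, ...) {
  cat("Averaged out-of-fold metrics over repeats:\n")
  print(round(object$metrics, 4))
  cat("\nPer-repeat metrics:\n")
  print(round(object$per_repeat, 4))
  invisible(object$metrics)
}

#' Tune the forest over the ntree grid
#'
#' Mean cross-validated accuracy over repeats and folds per grid point;
#' the grid arg-max is returned with ties broken toward the smaller ntree.
#'
#' @inheritParams cross_validate
#' @return List with \code{ntree}, \code{mtry}, and the \code{trace} data
#'   frame of per-grid-point mean accuracy.
#' @export
tune_forest <- function(x, labels, config = rf_config()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stop_if(length(unique(labels)) != 2, "both classes must be present")
  pos <- config$positive_class
  neg <- setdiff(unique(labels), pos)
  acc <- vapply(config$ntree_grid, function(nt) {
    accs <- vapply(seq_len(config$n_tune_repeats), function(r) {
      rs <- derive_seed(config$seed, "tune", nt, r)
      cv <- .cv_one_repeat(x, labels, config, nt, rs)
      mean(ifelse(cv$prob >= 0.5, pos, neg) == labels)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  grid <- sort(config$ntree_grid)
  acc <- acc[order(config$ntree_grid)]
  best <- grid[which.max(acc)] # which.max takes the first (smallest) maximum
  list(ntree = best, mtry = config$mtry,
       trace = data.frame(ntree = grid, mean_cv_accuracy = acc))
}

#' Mean-decrease-Gini feature importance
#'
#' Fits the forest on the full standardized, SMOTE-balanced cohort (the
#' "trained model") and reports each feature's mean decrease in Gini
#' impurity with its rank.
#'
#' @inheritParams cross_validate
#' @return Data frame (feature, mean_decrease_gini, rank), sorted by rank.
#' @export
gini_importance <- function(x, labels, config = rf_config()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cs <- center_scale(x)
  sm <- smote_balance(cs$x, labels, config$smote_k,
                      derive_seed(config$seed, "smote_imp"))
  set.seed(derive_seed(config$seed, "rf_imp"))
  fit <- randomForest::randomForest(x = sm$x, y = factor(sm$labels),
                                    ntree = config$ntree, mtry = config$mtry,
                                    importance = FALSE)
  g <- randomForest::importance(fit, type = 2)[, 1]
  out <- data.frame(feature = names(g), mean_decrease_gini = unname(g),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_gini), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
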