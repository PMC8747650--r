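# Evaluation layer: accuracy from confusion counts, stratified splitting,
# single-assay ROC/AUC, and the leave-one-out jackknife comparison of ML
# arms against the Gaussian baseline.

#' Confusion counts for a binary prediction
#'
#' The positive class is UFR; the choice is immaterial to accuracy and is
#' recorded here for report columns.
#'
#' @param truth,predicted Character vectors of `"FR"`/`"UFR"`.
#' @param positive Positive class, default `"UFR"`.
#' @return A list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive = "UFR") {
  stopifnot(length(truth) == length(predicted))
  pos <- truth == positive
  ppos <- predicted == positive
  list(tp = sum(pos & ppos), tn = sum(!pos & !ppos),
       fp = sum(!pos & ppos), fn = sum(pos & !ppos))
}

#' Classification accuracy
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN).
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("no evaluated samples")
  (counts$tp + counts$tn) / total
}

#' Split configuration
#'
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.5, the half/half design).
#' @param cv_folds Folds for grid-search cross-validation on the training
#'   half (default 3).
#' @param seed Integer seed driving the split (and, derived from it, model
#'   training).
#' @return An object of class `split_config`.
#' @export
split_config <- function(train_fraction = 0.5, cv_folds = 3L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2L)
  structure(list(train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "split_config")
}

#' Random stratified train/test split
#'
#' Each label is split separately: ceiling(fraction * n_label) samples to
#' training (the larger half at 0.5), the rest to testing. The split is a
#' disjoint, exhaustive partition and is deterministic given the seed.
#'
#' @param dataset A validated assay data frame with both labels present.
#' @param config A [split_config()].
#' @return A list with data frames `train` and `test`.
#' @export
stratified_split <- function(dataset, config = split_config()) {
  validate_assay_data(dataset, require_both_labels = TRUE)
  set.seed(config$seed)
  train_idx <- integer(0)
  for (lab in LABELS) {
    idx <- which(dataset$label == lab)
    n_tr <- ceiling(config$train_fraction * length(idx))
    train_idx <- c(train_idx, idx[sample.int(length(idx))][seq_len(n_tr)])
  }
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[-train_idx, , drop = FALSE])
}

#' ROC curve for a single assay/solvent feature
#'
#' Sweeps every distinct observed value as a decision threshold and
#' computes true- and false-positive rates for the positive class UFR.
#' The orientation (whether high or low values indicate UFR) is chosen so
#' that the AUC is at least 0.5 and is recorded. AUC is computed by
#' trapezoidal integration, which equals the Mann-Whitney pair count with
#' ties counted one half.
#'
#' @param dataset A validated assay data frame with both labels.
#' @param assay One of `"TPC"`, `"TEAC"`, `"FRAP"`.
#' @param solvent `"water"` or `"methanol"`.
#' @return An object of class `roc_result` with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `orientation`, and a `degenerate` flag (constant
#'   feature).
#' @export
assay_roc <- function(dataset, assay, solvent = c("water", "methanol")) {
  validate_assay_data(dataset, require_both_labels = TRUE)
  assay <- match.arg(toupper(assay), ASSAYS)
  solvent <- match.arg(solvent)
  col <- paste0(tolower(assay), if (solvent == "water") "_water" else "_meoh")
  v <- dataset[[col]]
  pos <- dataset$label == "UFR"
  thresholds <- sort(unique(v))
  degenerate <- length(thresholds) < 2L
  idx <- match(v, thresholds)
  pos_counts <- tabulate(idx[pos], nbins = length(thresholds))
  neg_counts <- tabulate(idx[!pos], nbins = length(thresholds))
  # higher-is-UFR sweep: classify UFR when value >= threshold
  tpr_hi <- rev(cumsum(rev(pos_counts))) / sum(pos)
  fpr_hi <- rev(cumsum(rev(neg_counts))) / sum(!pos)
  auc_trap <- function(fpr, tpr) {
    o <- order(fpr, tpr)
    fp <- c(0, fpr[o], 1)
    tp <- c(0, tpr[o], 1)
    sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)) / 2)
  }
  auc_hi <- if (degenerate) 0.5 else auc_trap(fpr_hi, tpr_hi)
  if (auc_hi >= 0.5) {
    orientation <- "higher-is-UFR"
    tpr <- tpr_hi; fpr <- fpr_hi; auc <- auc_hi
  } else {
    orientation <- "lower-is-UFR"
    tpr <- cumsum(pos_counts) / sum(pos)
    fpr <- cumsum(neg_counts) / sum(!pos)
    auc <- auc_trap(fpr, tpr)
  }
  structure(list(assay = assay, solvent = solvent, thresholds = thresholds,
                 tpr = tpr, fpr = fpr, auc = auc, orientation = orientation,
                 degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC %s / %s: AUC = %.4f (%s%s)\n", x$assay, x$solvent, x$auc,
              x$orientation, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Evaluate one classifier on one stratified split
#'
#' Splits the dataset, fits the requested classifier on the training half
#' (the baseline via [gaussian_baseline()], an ML arm via [train_arm()]
#' with grid-search cross-validation), predicts the held-out half, and
#' returns the test accuracy. For a given config seed the baseline and
#' every ML method see the identical split, so accuracy differences are
#' paired. `fit_on_test = TRUE` fits the baseline's Gaussian parameters on
#' the held-out half instead (a literal variant of the published
#' description; see the vignette).
#'
#' @param dataset A validated assay data frame with both labels.
#' @param spec A [feature_set()].
#' @param method `"baseline"`, `"LR"`, `"SVM"`, `"RF"` or `"KNN"`.
#' @param config A [split_config()].
#' @param grids Optional named list overriding [default_grids()].
#' @param fit_on_test Baseline only: fit Gaussian parameters on the test
#'   half.
#' @return Test accuracy in \[0, 1\].
#' @export
evaluate_once <- function(dataset, spec, method = "baseline",
                          config = split_config(), grids = NULL,
                          fit_on_test = FALSE) {
  method <- match.arg(method, c("baseline", "LR", "SVM", "RF", "KNN"))
  halves <- stratified_split(dataset, config)
  tr <- extract_features(halves$train, spec)
  te <- extract_features(halves$test, spec)
  if (method == "baseline") {
    fit_half <- if (fit_on_test) te else tr
    fit <- gaussian_baseline(fit_half$x, fit_half$labels, spec = spec)
    pred <- predict(fit, te$x)
  } else {
    grid <- if (!is.null(grids)) grids[[method]] else NULL
    arm <- train_arm(ml_spec(method, grid = grid,
                             seed = config$seed + 1L),
                     tr$x, tr$labels, cv_folds = config$cv_folds)
    pred <- predict(arm, te$x)
  }
  accuracy(confusion_counts(te$labels, pred))
}

#' Jackknife standard error from leave-one-out statistics
#'
#' SE = sqrt((n - 1) / n * sum((theta_i - mean(theta))^2)).
#'
#' @param theta Numeric vector of leave-one-out statistics.
#' @return The jackknife standard error.
#' @export
jackknife_se <- function(theta) {
  n <- length(theta)
  if (n < 2L) stop("need at least 2 leave-one-out statistics")
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

#' Leave-one-out jackknife of an arbitrary statistic
#'
#' Recomputes `statistic` on each leave-one-out subset. For the sample
#' mean, the jackknife SE equals the classical s / sqrt(n) exactly.
#'
#' @param x Numeric vector.
#' @param statistic Function of a numeric vector returning a scalar.
#' @return A list with `estimates` (length n), `estimate` (their mean) and
#'   `se`.
#' @export
jackknife <- function(x, statistic = mean) {
  n <- length(x)
  theta <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  list(estimates = theta, estimate = mean(theta), se = jackknife_se(theta))
}

# deterministic per-replicate seed below 2^31, spreading replicates across
# the seed space
replicate_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 97561 * 21557 + as.numeric(i) * 7919) %%
               2147483647) + 1L
}

#' Jackknife comparison of one ML arm against the baseline
#'
#' For each sample i, drops it, then evaluates the baseline and the ML arm
#' on the reduced dataset with a replicate-derived seed (fresh stratified
#' split shared by both classifiers, and a fresh grid-search optimization
#' for the arm). The statistic is the per-replicate accuracy difference
#' ML - baseline; the point estimate is its mean, the error bar is
#' `error_bar_multiplier` (default 2) jackknife standard errors, and the
#' difference is flagged significant when zero lies outside the error bar.
#'
#' @param dataset A validated assay data frame, n >= 10, both labels.
#' @param spec A [feature_set()].
#' @param method `"LR"`, `"SVM"`, `"RF"` or `"KNN"`.
#' @param config A [split_config()]; its seed is the jackknife master seed.
#' @param grids Optional grid override (see [default_grids()]).
#' @param error_bar_multiplier Half-width of the error bar in jackknife
#'   SEs.
#' @return An object of class `comparison_result`.
#' @export
jackknife_compare <- function(dataset, spec, method,
                              config = split_config(), grids = NULL,
                              error_bar_multiplier = 2) {
  validate_assay_data(dataset, require_both_labels = TRUE)
  n <- nrow(dataset)
  if (n < 10L) stop("need at least 10 samples for the jackknife")
  base_acc <- ml_acc <- numeric(n)
  for (i in seq_len(n)) {
    reduced <- dataset[-i, , drop = FALSE]
    cfg <- split_config(config$train_fraction, config$cv_folds,
                        replicate_seed(config$seed, i))
    base_acc[i] <- evaluate_once(reduced, spec, "baseline", cfg)
    ml_acc[i] <- evaluate_once(reduced, spec, method, cfg, grids = grids)
  }
  theta <- ml_acc - base_acc
  se <- jackknife_se(theta)
  diff <- mean(theta)
  structure(list(feature_set = spec, method = method,
                 baseline_accuracy = mean(base_acc),
                 ml_accuracy = mean(ml_acc),
                 accuracy_difference = diff,
                 jackknife_se = se,
                 error_bar_halfwidth = error_bar_multiplier * se,
                 significant = abs(diff) > error_bar_multiplier * se,
                 n_replicates = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs baseline on {%s}/%s: diff = %+.4f +/- %.4f (%ssignificant)\n",
              x$method, paste(x$feature_set$assays, collapse = ","),
              x$feature_set$scope, x$accuracy_difference,
              x$error_bar_halfwidth, if (x$significant) "" else "not "))
  invisible(x)
}

#' Full 21 x 4 comparison of ML arms against the baseline
#'
#' Iterates all 21 feature sets; for each, runs the leave-one-out jackknife
#' once, computing the baseline accuracy and every requested ML arm's
#' accuracy on shared per-replicate splits. Returns 21 baseline rows (mean
#' accuracy with jackknife SE) and one comparison row per (feature set,
#' method). Deterministic given the config seed.
#'
#' @param dataset A validated assay data frame.
#' @param config A [split_config()].
#' @param methods Subset of `c("LR", "SVM", "RF", "KNN")`.
#' @param specs List of feature sets, default [enumerate_feature_sets()].
#' @param grids Optional grid override.
#' @param error_bar_multiplier Error-bar half-width in jackknife SEs.
#' @param verbose Log per-feature-set progress via `message()`.
#' @return A list with data frames `baseline` (one row per feature set) and
#'   `comparisons` (one row per feature set x method).
#' @export
run_full_comparison <- function(dataset, config = split_config(),
                                methods = c("LR", "SVM", "RF", "KNN"),
                                specs = enumerate_feature_sets(),
                                grids = NULL, error_bar_multiplier = 2,
                                verbose = FALSE) {
  validate_assay_data(dataset, require_both_labels = TRUE)
  n <- nrow(dataset)
  base_rows <- list()
  comp_rows <- list()
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    if (verbose)
      message("feature set ", s, "/", length(specs), ": {",
              paste(spec$assays, collapse = ","), "}/", spec$scope)
    base_acc <- numeric(n)
    ml_acc <- matrix(0, n, length(methods), dimnames = list(NULL, methods))
    for (i in seq_len(n)) {
      reduced <- dataset[-i, , drop = FALSE]
      cfg <- split_config(config$train_fraction, config$cv_folds,
                          replicate_seed(config$seed, i))
      base_acc[i] <- evaluate_once(reduced, spec, "baseline", cfg)
      for (m in methods)
        ml_acc[i, m] <- evaluate_once(reduced, spec, m, cfg, grids = grids)
    }
    base_rows[[s]] <- data.frame(
      assays = paste(spec$assays, collapse = "+"), scope = spec$scope,
      accuracy = mean(base_acc), jackknife_se = jackknife_se(base_acc),
      stringsAsFactors = FALSE)
    for (m in methods) {
      theta <- ml_acc[, m] - base_acc
      se <- jackknife_se(theta)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        assays = paste(spec$assays, collapse = "+"), scope = spec$scope,
        method = m, baseline_accuracy = mean(base_acc),
        ml_accuracy = mean(ml_acc[, m]), accuracy_difference = mean(theta),
        jackknife_se = se,
        error_bar_halfwidth = error_bar_multiplier * se,
        significant = abs(mean(theta)) > error_bar_multiplier * se,
        n_replicates = n, stringsAsFactors = FALSE)
    }
  }
  list(baseline = do.call(rbind, base_rows),
       comparisons = do.call(rbind, comp_rows))
}

#' Number of scheduled grid-search optimizations
#'
#' Each leave-one-out replicate of each (feature set, ML method) cell
#' requires its own grid-search optimization, so the schedule size is the
#' product dataset_size x n_feature_sets x n_methods — 8232 under the
#' defaults (98 x 21 x 4).
#'
#' @param dataset_size,n_feature_sets,n_methods Non-negative integers.
#' @return The product, as a double.
#' @export
count_scheduled_optimizations <- function(dataset_size, n_feature_sets,
                                          n_methods) {
  stopifnot(dataset_size >= 0, n_feature_sets >= 0, n_methods >= 0)
  as.numeric(dataset_size) * n_feature_sets * n_methods
}
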