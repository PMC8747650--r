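# The four machine-learning comparison arms (LR, SVM, RF, kNN) behind one
# estimator contract: exhaustive grid search selected by mean stratified
# cross-validated accuracy, refit on the full training set.
#
# Fits delegate to glmnet (ridge-penalized logistic regression), e1071::svm
# and randomForest. kNN is implemented internally so that both uniform and
# inverse-distance neighbour weights are available.

#' Default hyperparameter grids
#'
#' Small standard grids, overridable per arm. `LR`: inverse regularization
#' strength C (mapped to glmnet lambda = 1 / (n C)). `SVM`: cost, kernel
#' (linear / radial), and RBF width gamma (`"scale"` = 1 / (d Var(x)), or a
#' number). `RF`: number of trees and maximum depth (`Inf` = unrestricted,
#' mapped to a maxnodes cap). `KNN`: number of neighbours and vote
#' weighting.
#'
#' @return Named list of per-method candidate lists.
#' @export
default_grids <- function() {
  list(
    LR = list(C = c(0.01, 0.1, 1, 10, 100)),
    SVM = list(C = c(0.01, 0.1, 1, 10, 100),
               kernel = c("linear", "radial"),
               gamma = c("scale", "0.1", "1")),
    RF = list(ntree = c(100, 300), max_depth = c(2, 4, Inf)),
    KNN = list(k = c(1, 3, 5, 7, 9), weights = c("uniform", "distance"))
  )
}

#' Specify a machine-learning arm
#'
#' @param method One of `"LR"`, `"SVM"`, `"RF"`, `"KNN"`.
#' @param grid Named list of finite candidate vectors; defaults to the
#'   method's entry in [default_grids()].
#' @param standardize Z-score features using training statistics before
#'   fitting. Defaults to `TRUE` except for RF, which is scale-invariant.
#'   Assay scales differ by an order of magnitude (TEAC ~2400 vs TPC ~280),
#'   so distance- and margin-based methods need comparable scales.
#' @param seed Integer seed making training deterministic.
#' @return An object of class `ml_spec`.
#' @export
ml_spec <- function(method = c("LR", "SVM", "RF", "KNN"), grid = NULL,
                    standardize = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.null(grid)) grid <- default_grids()[[method]]
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("grid must list at least one candidate per hyperparameter")
  if (is.null(standardize)) standardize <- method != "RF"
  structure(list(method = method, grid = grid,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "ml_spec")
}

# grid rows in deterministic order; row 1 is the tie-break winner
.expand_grid <- function(grid) {
  g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g[, names(grid), drop = FALSE]
}

.standardize_params <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

.apply_standardize <- function(x, sp) {
  sweep(sweep(x, 2L, sp$center, "-"), 2L, sp$scale, "/")
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lab in levels(y)) {
    idx <- which(y == lab)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_candidate <- function(method, params, x, y) {
  d <- ncol(x)
  if (method == "LR") {
    # glmnet needs >= 2 columns; pad 1-feature problems with a zero column
    pad <- d < 2L
    xg <- if (pad) cbind(x, .pad = 0) else x
    lam <- 1 / (params$C * nrow(x))
    # small CV folds in the half-split jackknife regime routinely trip
    # lognet's fewer-than-8-observations warning; the regime is intentional
    fit <- suppressWarnings(
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE))
    list(kind = "LR", fit = fit, pad = pad, lambda = lam)
  } else if (method == "SVM") {
    gamma <- params$gamma
    if (identical(gamma, "scale")) {
      gamma <- 1 / (d * mean(apply(x, 2L, stats::var)))
      if (!is.finite(gamma) || gamma <= 0) gamma <- 1 / d
    } else gamma <- as.numeric(gamma)
    fit <- e1071::svm(x = x, y = y, type = "C-classification",
                      kernel = params$kernel, cost = params$C, gamma = gamma,
                      scale = FALSE)
    list(kind = "SVM", fit = fit)
  } else if (method == "RF") {
    maxnodes <- if (is.finite(params$max_depth)) 2^params$max_depth else NULL
    fit <- randomForest::randomForest(x = x, y = y, ntree = params$ntree,
                                      maxnodes = maxnodes)
    list(kind = "RF", fit = fit)
  } else {
    list(kind = "KNN", x = x, y = y, k = params$k, weights = params$weights)
  }
}

.predict_candidate <- function(handle, xq) {
  if (handle$kind == "LR") {
    if (handle$pad) xq <- cbind(xq, .pad = 0)
    as.character(stats::predict(handle$fit, newx = xq, type = "class",
                                s = handle$lambda))
  } else if (handle$kind %in% c("SVM", "RF")) {
    as.character(stats::predict(handle$fit, xq))
  } else {
    .knn_predict(handle$x, handle$y, xq, handle$k, handle$weights)
  }
}

# kNN with uniform or inverse-distance vote weights; a query coinciding
# with training points is decided by those points alone. Vote ties go to
# the first class level.
.knn_predict <- function(xtrain, ytrain, xq, k, weights) {
  k <- min(k, nrow(xtrain))
  lvls <- levels(ytrain)
  out <- character(nrow(xq))
  for (i in seq_len(nrow(xq))) {
    d <- sqrt(colSums((t(xtrain) - xq[i, ])^2))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    w <- if (identical(weights, "distance")) {
      if (any(dn == 0)) as.numeric(dn == 0) else 1 / dn
    } else rep(1, k)
    votes <- vapply(lvls, function(l) sum(w[ytrain[nn] == l]), numeric(1))
    out[i] <- lvls[which.max(votes)]   # tie -> first level (FR)
  }
  out
}

#' Train a machine-learning arm with grid search
#'
#' Runs exhaustive grid search over the spec's hyperparameter grid,
#' selecting by mean accuracy under stratified k-fold cross-validation on
#' the training data (ties broken by grid order), then refits on the full
#' training set with the chosen candidate. A single-candidate grid skips
#' cross-validation and degenerates to a plain fit. Standardization
#' statistics are learned from the training folds during selection and from
#' the full training set for the final model. Deterministic given
#' `spec$seed`.
#'
#' @param spec An [ml_spec()].
#' @param x Numeric n x d training feature matrix.
#' @param labels Character `"FR"`/`"UFR"` training labels.
#' @param cv_folds Number of cross-validation folds (default 3).
#' @return An object of class `ml_arm`.
#' @export
train_arm <- function(spec, x, labels, cv_folds = 3L) {
  stopifnot(inherits(spec, "ml_spec"))
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(labels, levels = LABELS)
  if (any(is.na(y))) stop("labels must be FR or UFR")
  if (length(unique(labels)) < 2L)
    stop("training data contain a single class")
  if (nrow(x) < cv_folds)
    stop("need at least cv_folds = ", cv_folds, " samples; got ", nrow(x))
  set.seed(spec$seed)
  grid_df <- .expand_grid(spec$grid)
  if (nrow(grid_df) > 1L) {
    fold <- .stratified_folds(y, cv_folds)
    cv_acc <- numeric(nrow(grid_df))
    for (g in seq_len(nrow(grid_df))) {
      params <- as.list(grid_df[g, , drop = FALSE])
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L || !any(!tr)) next
        xtr <- x[tr, , drop = FALSE]
        xva <- x[!tr, , drop = FALSE]
        if (spec$standardize) {
          sp <- .standardize_params(xtr)
          xtr <- .apply_standardize(xtr, sp)
          xva <- .apply_standardize(xva, sp)
        }
        h <- .fit_candidate(spec$method, params, xtr, y[tr])
        correct <- correct + sum(.predict_candidate(h, xva) ==
                                   as.character(y[!tr]))
      }
      cv_acc[g] <- correct / nrow(x)
    }
    best <- which.max(cv_acc)   # first maximum = grid-order tie-break
  } else {
    cv_acc <- NA_real_
    best <- 1L
  }
  chosen <- as.list(grid_df[best, , drop = FALSE])
  sp <- if (spec$standardize) .standardize_params(x) else NULL
  xfit <- if (spec$standardize) .apply_standardize(x, sp) else x
  handle <- .fit_candidate(spec$method, chosen, xfit, y)
  structure(list(method = spec$method, spec = spec,
                 chosen = chosen, cv_accuracy = cv_acc,
                 standardization = sp, handle = handle,
                 d = ncol(x), cv_folds = as.integer(cv_folds)),
            class = "ml_arm")
}

#' Predict class labels with a trained arm
#'
#' Applies the stored standardization (if any), then the fitted model.
#' Deterministic.
#'
#' @param object A trained [train_arm()] result.
#' @param newdata An m x d matrix with the training dimensionality.
#' @param ... Unused.
#' @return Character vector of `"FR"`/`"UFR"` predictions.
#' @export
predict.ml_arm <- function(object, newdata, ...) {
  xq <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(xq) != object$d)
    stop("query has ", ncol(xq), " features; model expects ", object$d)
  colnames(xq) <- paste0("f", seq_len(ncol(xq)))
  if (!is.null(object$standardization))
    xq <- .apply_standardize(xq, object$standardization)
  .predict_candidate(object$handle, xq)
}

#' @export
print.ml_arm <- function(x, ...) {
  cat(x$method, " arm (", x$d, " feature", if (x$d > 1L) "s",
      ", standardize = ", !is.null(x$standardization), ")\n", sep = "")
  cat("  chosen hyperparameters: ",
      paste(names(x$chosen), unlist(lapply(x$chosen, format)),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
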