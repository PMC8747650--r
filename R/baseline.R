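#' Gaussian minimum-Mahalanobis-distance baseline classifier
#'
#' Fits a Gaussian model to each class (maximum-likelihood mean and sample
#' covariance, divisor n - 1) and classifies a point to the class with the
#' smaller multivariate Z-score, i.e. the smaller Mahalanobis distance
#' sqrt((x - mu_c)' Sigma_c^-1 (x - mu_c)). This is the statistical
#' benchmark against which the machine-learning arms are compared.
#'
#' Small training halves can leave a class covariance near-singular
#' (up to 6 features on ~25 training samples per class). By default a ridge
#' `ridge * mean(diag(Sigma_c)) * I` is added, with `ridge` escalated from
#' 1e-8 by decades until both class covariances have condition number below
#' 1e8. Pass `ridge = 0` to forbid regularization (well-conditioned data
#' only).
#'
#' The decision rule compares Mahalanobis distances only; it omits the
#' log-determinant term of the full Gaussian log-likelihood, which matters
#' when class covariances differ. `rule = "loglik"` enables the
#' log-likelihood variant for sensitivity analysis.
#'
#' @param x Numeric n x d feature matrix.
#' @param labels Character vector of `"FR"`/`"UFR"`, length n.
#' @param spec Optional [feature_set()] recorded in the fit.
#' @param ridge `NULL` for automatic escalation (default), or a fixed
#'   non-negative scalar (0 disables regularization).
#' @param rule `"mahalanobis"` (default) or `"loglik"`.
#' @return An object of class `gaussian_baseline` with per-class `mean`,
#'   `cov`, `n`, the `ridge` actually applied, and the decision `rule`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 3), ncol = 2))
#' y <- rep(c("FR", "UFR"), each = 30)
#' fit <- gaussian_baseline(x, y)
#' table(predict(fit, x), y)
#' @export
gaussian_baseline <- function(x, labels, spec = NULL, ridge = NULL,
                              rule = c("mahalanobis", "loglik")) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  d <- ncol(x)
  if (nrow(x) != length(labels)) stop("x and labels lengths differ")
  if (!all(labels %in% LABELS)) stop("labels must be FR or UFR")
  classes <- list()
  for (lab in LABELS) {
    xi <- x[labels == lab, , drop = FALSE]
    if (nrow(xi) < d + 2L)
      stop("class ", lab, " has ", nrow(xi), " samples; need at least ",
           d + 2L, " for ", d, " features")
    classes[[lab]] <- list(mean = colMeans(xi), cov = stats::cov(xi),
                           n = nrow(xi))
  }
  cond_ok <- function(sigma, r) {
    s <- sigma + r * mean(diag(sigma)) * diag(d)
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > 0 && max(ev) / min(ev) < 1e8
  }
  if (is.null(ridge)) {
    ridge <- 0
    if (!all(vapply(classes, function(cl) cond_ok(cl$cov, 0), logical(1)))) {
      ridge <- 1e-8
      while (!all(vapply(classes, function(cl) cond_ok(cl$cov, ridge),
                         logical(1)))) {
        ridge <- ridge * 10
        if (ridge > 1) stop("covariance cannot be conditioned; degenerate data")
      }
    }
  } else {
    stopifnot(ridge >= 0)
  }
  for (lab in LABELS)
    classes[[lab]]$cov <- classes[[lab]]$cov +
      ridge * mean(diag(classes[[lab]]$cov)) * diag(d)
  structure(list(classes = classes, ridge = ridge, rule = rule,
                 d = d, feature_spec = spec,
                 feature_names = colnames(x)),
            class = "gaussian_baseline")
}

#' Mahalanobis distance to a fitted class
#'
#' @param model A fitted [gaussian_baseline()].
#' @param class `"FR"` or `"UFR"`.
#' @param x A d-vector or an m x d matrix of query points.
#' @return Non-negative distance(s) sqrt((x - mu_c)' Sigma_c^-1 (x - mu_c)).
#' @export
mahalanobis_distance <- function(model, class, x) {
  stopifnot(inherits(model, "gaussian_baseline"))
  class <- match.arg(class, LABELS)
  pts <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(pts) != model$d)
    stop("query has ", ncol(pts), " features; model expects ", model$d)
  cl <- model$classes[[class]]
  unname(sqrt(stats::mahalanobis(pts, cl$mean, cl$cov)))
}

#' Classify points with the fitted baseline
#'
#' Assigns each point to the class with the smaller Mahalanobis distance
#' (or larger Gaussian log-density when the model was fitted with
#' `rule = "loglik"`). Exact ties go to FR, a fixed deterministic rule;
#' ties have probability zero for continuous data.
#'
#' @param object A fitted `gaussian_baseline`.
#' @param newdata A d-vector or m x d matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.gaussian_baseline <- function(object, newdata, ...) {
  pts <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(pts) != object$d)
    stop("query has ", ncol(pts), " features; model expects ", object$d)
  if (object$rule == "mahalanobis") {
    d_fr <- mahalanobis_distance(object, "FR", pts)
    d_ufr <- mahalanobis_distance(object, "UFR", pts)
    ifelse(d_fr <= d_ufr, "FR", "UFR")
  } else {
    ll <- function(lab) {
      cl <- object$classes[[lab]]
      -0.5 * stats::mahalanobis(pts, cl$mean, cl$cov) -
        0.5 * determinant(cl$cov, logarithm = TRUE)$modulus
    }
    ifelse(ll("FR") >= ll("UFR"), "FR", "UFR")
  }
}

#' @export
print.gaussian_baseline <- function(x, ...) {
  cat("Gaussian minimum-Mahalanobis baseline (", x$d, " feature",
      if (x$d > 1L) "s", ", rule = ", x$rule, ")\n", sep = "")
  for (lab in LABELS)
    cat(sprintf("  %-3s n = %d, mean = (%s)\n", lab, x$classes[[lab]]$n,
                paste(sprintf("%.4g", x$classes[[lab]]$mean), collapse = ", ")))
  cat(sprintf("  ridge applied: %g\n", x$ridge))
  invisible(x)
}

#' @export
summary.gaussian_baseline <- function(object, ...) {
  cond <- vapply(object$classes, function(cl) {
    ev <- eigen(cl$cov, symmetric = TRUE, only.values = TRUE)$values
    max(ev) / min(ev)
  }, numeric(1))
  out <- list(model = object, condition_numbers = cond)
  class(out) <- "summary.gaussian_baseline"
  out
}

#' @export
print.summary.gaussian_baseline <- function(x, ...) {
  print(x$model)
  cat(sprintf("  covariance condition numbers: FR %.3g, UFR %.3g\n",
              x$condition_numbers[["FR"]], x$condition_numbers[["UFR"]]))
  invisible(x)
}

#' Class mean vectors of a fitted baseline
#'
#' @param object A fitted `gaussian_baseline`.
#' @param ... Unused.
#' @return A 2 x d matrix of class means (rows FR, UFR).
#' @export
coef.gaussian_baseline <- function(object, ...) {
  m <- rbind(FR = object$classes$FR$mean, UFR = object$classes$UFR$mean)
  colnames(m) <- object$feature_names
  m
}
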