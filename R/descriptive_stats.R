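# Descriptive layer: per-group summary statistics, pairwise Pearson
# correlations with classical uncertainty, and 95% confidence ellipses for
# bivariate scatter.

#' Per-group summary statistics
#'
#' Computes min, max, median and mean for each of the 12 groups
#' (2 labels x 2 solvents x 3 assays). The median of an even-sized group is
#' the midpoint of the two central order statistics.
#'
#' @param dataset A validated assay data frame containing both labels.
#' @return A data frame with columns `label`, `solvent`, `assay`, `min`,
#'   `max`, `median`, `mean`; 12 rows.
#' @export
summarize_assays <- function(dataset) {
  validate_assay_data(dataset, require_both_labels = TRUE)
  solvents <- c(water = "_water", methanol = "_meoh")
  rows <- list()
  for (lab in LABELS) {
    sub <- dataset[dataset$label == lab, , drop = FALSE]
    for (solv in names(solvents)) {
      for (assay in ASSAYS) {
        v <- sub[[paste0(tolower(assay), solvents[[solv]])]]
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, solvent = solv, assay = assay,
          min = min(v), max = max(v),
          median = stats::median(v), mean = mean(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlation with classical uncertainty
#'
#' Computes the Pearson correlation r, the signed squared correlation
#' sign(r) * r^2, the classical standard error
#' sqrt((1 - r^2) / (n - 2)), and a two-sided p-value from the t statistic
#' r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. The signed
#' squared form keeps both the strength and the direction of association in
#' one number.
#'
#' @param x,y Numeric vectors of equal length n >= 4, neither constant.
#' @return An object of class `correlation_estimate`: a list with `r`,
#'   `signed_r2`, `sigma`, `p_value`, `n`.
#' @export
pairwise_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  one_minus_r2 <- max(0, 1 - r^2)
  sigma <- sqrt(one_minus_r2 / (n - 2))
  if (one_minus_r2 == 0) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / one_minus_r2)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(r = r, signed_r2 = sign(r) * r^2, sigma = sigma,
                 p_value = p, n = n),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (signed r^2 = %.4f), SE = %.4f, p = %.3g, n = %d\n",
              x$r, x$signed_r2, x$sigma, x$p_value, x$n))
  invisible(x)
}

#' Correlation table across assay pairs, labels and solvents
#'
#' Applies [pairwise_correlation()] to all 12 within-solvent assay pairs
#' (3 pairs x 2 labels x 2 solvents).
#'
#' @param dataset A validated assay data frame containing both labels.
#' @return A data frame with one row per comparison.
#' @export
correlation_table <- function(dataset) {
  validate_assay_data(dataset, require_both_labels = TRUE)
  pairs <- list(c("TPC", "TEAC"), c("TPC", "FRAP"), c("TEAC", "FRAP"))
  solvents <- c(water = "_water", methanol = "_meoh")
  rows <- list()
  for (solv in names(solvents)) {
    for (lab in LABELS) {
      sub <- dataset[dataset$label == lab, , drop = FALSE]
      for (p in pairs) {
        est <- pairwise_correlation(
          sub[[paste0(tolower(p[1]), solvents[[solv]])]],
          sub[[paste0(tolower(p[2]), solvents[[solv]])]])
        rows[[length(rows) + 1L]] <- data.frame(
          var1 = p[1], var2 = p[2], label = lab, solvent = solv,
          r = est$r, signed_r2 = est$signed_r2, sigma = est$sigma,
          p_value = est$p_value, n = est$n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Confidence ellipse for bivariate scatter
#'
#' Builds the level set of the Mahalanobis quadratic form at the
#' chi-squared (2 df) quantile of the requested level, from the sample mean
#' and sample covariance (divisor n - 1). For bivariate Gaussian data with
#' population parameters, the ellipse encloses the stated fraction of
#' probability mass.
#'
#' @param points An n x 2 numeric matrix, n >= 3, non-degenerate scatter.
#' @param level Coverage probability, default 0.95.
#' @return An object of class `confidence_ellipse` with fields `center`,
#'   `covariance`, `level`, `chi2_quantile`.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have exactly 2 columns")
  if (nrow(points) < 3L) stop("need at least 3 points")
  center <- colMeans(points)
  covariance <- stats::cov(points)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1e-300))
    stop("degenerate scatter: covariance is rank-deficient")
  ellipse_from_params(center, covariance, level)
}

#' Construct a confidence ellipse from known parameters
#'
#' Same object as [confidence_ellipse()] but from a given center and
#' covariance (e.g. population parameters in a coverage study).
#'
#' @param center Length-2 numeric center.
#' @param covariance 2 x 2 symmetric positive-definite matrix.
#' @param level Coverage probability.
#' @return A `confidence_ellipse` object.
#' @export
ellipse_from_params <- function(center, covariance, level = 0.95) {
  stopifnot(length(center) == 2L, all(dim(covariance) == 2L),
            level > 0, level < 1)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("covariance must be positive-definite")
  structure(list(center = as.numeric(center), covariance = covariance,
                 level = level,
                 chi2_quantile = stats::qchisq(level, df = 2)),
            class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% confidence ellipse: center (%.4g, %.4g), chi2 threshold %.4f\n",
              100 * x$level, x$center[1], x$center[2], x$chi2_quantile))
  invisible(x)
}

#' Test whether points fall inside a confidence ellipse
#'
#' A point is contained iff its Mahalanobis quadratic form with respect to
#' the ellipse center and covariance is at most the chi-squared threshold;
#' boundary points count as contained.
#'
#' @param ellipse A `confidence_ellipse`.
#' @param point A length-2 vector or an n x 2 matrix of points.
#' @return Logical vector, one verdict per point.
#' @export
ellipse_contains <- function(ellipse, point) {
  stopifnot(inherits(ellipse, "confidence_ellipse"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  d2 <- stats::mahalanobis(pts, ellipse$center, ellipse$covariance)
  unname(d2 <= ellipse$chi2_quantile)
}
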