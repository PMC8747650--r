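test_that("class means and covariances match direct computation", {
  x_fr <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))         # symmetric about 0
  x_ufr <- rbind(c(0, 1), c(2, 1), c(1, 0), c(1, 2))          # symmetric about (1,1)
  x <- rbind(x_fr, x_ufr)
  labels <- rep(c("FR", "UFR"), each = 4)
  fit <- gaussian_baseline(x, labels, ridge = 0)
  expect_equal(unname(fit$classes$FR$mean), c(0, 0))
  expect_equal(unname(fit$classes$UFR$mean), c(1, 1))

  # brute-force covariance oracle
  oracle_cov <- function(m) {
    mu <- colMeans(m)
    acc <- matrix(0, 2, 2)
    for (i in seq_len(nrow(m)))
      acc <- acc + tcrossprod(m[i, ] - mu)
    acc / (nrow(m) - 1)
  }
  expect_equal(fit$classes$FR$cov, oracle_cov(x_fr), tolerance = 1e-12)
  expect_equal(fit$classes$UFR$cov, oracle_cov(x_ufr), tolerance = 1e-12)

  expect_error(gaussian_baseline(x[c(1, 2, 3, 5:8), ],
                                 labels[c(1, 2, 3, 5:8)]),
               "class FR has 3 samples")
})

test_that("ridge escalation conditions a duplicated feature column", {
  set.seed(10)
  base <- rnorm(40)
  x <- cbind(base, base)          # perfectly correlated pair
  labels <- rep(c("FR", "UFR"), each = 20)
  fit <- gaussian_baseline(x, labels)
  expect_gt(fit$ridge, 0)
  for (lab in c("FR", "UFR")) {
    ev <- eigen(fit$classes[[lab]]$cov, symmetric = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lt(max(ev) / min(ev), 1e8)
  }
  expect_type(predict(fit, c(0, 0)), "character")
})

test_that("mahalanobis distance matches the quadratic form", {
  set.seed(11)
  x <- rbind(MASS::mvrnorm(30, c(0, 0, 0), diag(3)),
             MASS::mvrnorm(30, c(2, 2, 2), diag(3)))
  labels <- rep(c("FR", "UFR"), each = 30)
  fit <- gaussian_baseline(x, labels, ridge = 0)

  expect_equal(mahalanobis_distance(fit, "FR", fit$classes$FR$mean), 0)

  for (i in 1:20) {
    q <- rnorm(3, sd = 3)
    d <- q - fit$classes$UFR$mean
    oracle <- sqrt(as.numeric(t(d) %*% solve(fit$classes$UFR$cov, d)))
    expect_equal(mahalanobis_distance(fit, "UFR", q), oracle,
                 tolerance = 1e-10)
  }

  # identity covariance reduces to Euclidean distance
  fit_id <- fit
  fit_id$classes$FR$cov <- diag(3)
  q <- c(1, 2, 3)
  expect_equal(mahalanobis_distance(fit_id, "FR", q),
               sqrt(sum((q - fit_id$classes$FR$mean)^2)), tolerance = 1e-12)

  expect_error(mahalanobis_distance(fit, "FR", c(1, 2)), "2 features")
})

test_that("classification follows minimum distance with the FR tie-break", {
  # mirrored clouds: identical sample covariances, so the minimum-distance
  # rule coincides exactly with the equal-prior Gaussian density ratio
  set.seed(12)
  cloud <- MASS::mvrnorm(50, c(0, 0), matrix(c(1, 0.3, 0.3, 1), 2))
  shift <- c(3, 1)
  x <- rbind(cloud, sweep(cloud, 2, shift, "+"))
  labels <- rep(c("FR", "UFR"), each = 50)
  fit <- gaussian_baseline(x, labels, ridge = 0)

  expect_equal(predict(fit, fit$classes$FR$mean), "FR")
  expect_equal(predict(fit, fit$classes$UFR$mean), "UFR")

  # equidistant query -> FR by the documented tie rule
  mid <- (fit$classes$FR$mean + fit$classes$UFR$mean) / 2
  expect_equal(predict(fit, mid), "FR")

  queries <- MASS::mvrnorm(200, (fit$classes$FR$mean + shift / 2), diag(2) * 4)
  got <- predict(fit, queries)
  sig <- fit$classes$FR$cov
  dens <- function(mu) {
    apply(queries, 1, function(q) {
      d <- q - mu
      exp(-0.5 * as.numeric(t(d) %*% solve(sig, d))) /
        (2 * pi * sqrt(det(sig)))
    })
  }
  oracle <- ifelse(dens(fit$classes$FR$mean) >= dens(fit$classes$UFR$mean),
                   "FR", "UFR")
  expect_identical(got, oracle)
})

test_that("the decision rule is invariant under joint affine maps", {
  set.seed(13)
  x <- rbind(MASS::mvrnorm(40, c(0, 0), diag(2)),
             MASS::mvrnorm(40, c(2, 1), matrix(c(1, 0.4, 0.4, 2), 2)))
  labels <- rep(c("FR", "UFR"), each = 40)
  queries <- MASS::mvrnorm(100, c(1, 0.5), diag(2) * 3)

  fit <- gaussian_baseline(x, labels, ridge = 0)
  a_mat <- matrix(c(3, -0.2, 0.7, 1.5), 2)
  b_vec <- c(-4, 9)
  fit_t <- gaussian_baseline(t(a_mat %*% t(x) + b_vec), labels, ridge = 0)
  expect_identical(predict(fit_t, t(a_mat %*% t(queries) + b_vec)),
                   predict(fit, queries))
})

test_that("test accuracy approaches Phi(delta/2) for equal-covariance classes", {
  set.seed(14)
  delta <- 1.5
  n <- 10000L
  train_x <- rbind(MASS::mvrnorm(n, c(0, 0), diag(2)),
                   MASS::mvrnorm(n, c(delta, 0), diag(2)))
  labels <- rep(c("FR", "UFR"), each = n)
  fit <- gaussian_baseline(train_x, labels, ridge = 0)
  test_x <- rbind(MASS::mvrnorm(n, c(0, 0), diag(2)),
                  MASS::mvrnorm(n, c(delta, 0), diag(2)))
  acc <- mean(predict(fit, test_x) == labels)
  expect_lt(abs(acc - pnorm(delta / 2)), 0.01)
})

test_that("log-likelihood variant differs only when covariances differ", {
  set.seed(15)
  x <- rbind(MASS::mvrnorm(60, c(0, 0), diag(2)),
             MASS::mvrnorm(60, c(1, 0), diag(2) * 16))
  labels <- rep(c("FR", "UFR"), each = 60)
  queries <- MASS::mvrnorm(200, c(0.5, 0), diag(2) * 9)
  pred_m <- predict(gaussian_baseline(x, labels, ridge = 0), queries)
  pred_l <- predict(gaussian_baseline(x, labels, ridge = 0, rule = "loglik"),
                    queries)
  expect_false(identical(pred_m, pred_l))  # log-determinant term matters
})
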