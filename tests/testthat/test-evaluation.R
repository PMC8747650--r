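test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy(list(tp = 3, tn = 2, fp = 1, fn = 0)), 5 / 6)
  expect_equal(accuracy(list(tp = 4, tn = 6, fp = 0, fn = 0)), 1)
  expect_equal(accuracy(list(tp = 0, tn = 0, fp = 3, fn = 2)), 0)
  expect_error(accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "no evaluated")

  set.seed(30)
  truth <- sample(c("FR", "UFR"), 50, replace = TRUE)
  pred <- sample(c("FR", "UFR"), 50, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 50)
  expect_equal(accuracy(cc), 1 - (cc$fp + cc$fn) / 50)
  expect_equal(accuracy(cc), mean(truth == pred))
})

test_that("stratified split partitions each class with ceiling-to-train", {
  d <- generate_assay_data(default_gen_params(seed = 31L))
  sp <- stratified_split(d, split_config(seed = 5L))
  expect_equal(sum(sp$train$label == "FR"), 26L)
  expect_equal(sum(sp$train$label == "UFR"), 24L)
  expect_equal(sum(sp$test$label == "FR"), 25L)
  expect_equal(sum(sp$test$label == "UFR"), 23L)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), d$sample_id)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0L)

  sp2 <- stratified_split(d, split_config(seed = 5L))
  expect_identical(sp, sp2)
  sp3 <- stratified_split(d, split_config(seed = 6L))
  expect_false(identical(sp$train$sample_id, sp3$train$sample_id))
})

test_that("ROC/AUC matches the Mann-Whitney oracle and pROC", {
  # 20 listed values with deliberate ties across classes
  d <- make_dataset(10L, 10L, seed = 32L)
  d$tpc_water <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8,      # FR
                   4, 5, 6, 6, 7, 8, 9, 9, 10, 11)    # UFR
  r <- assay_roc(d, "TPC", "water")
  pos <- d$tpc_water[d$label == "UFR"]
  neg <- d$tpc_water[d$label == "FR"]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  expect_equal(r$orientation, "higher-is-UFR")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = d$label, predictor = d$tpc_water, levels = c("FR", "UFR"),
    direction = "<", quiet = TRUE)))
  expect_equal(r$auc, proc_auc, tolerance = 1e-12)

  # invariance under strictly monotone transforms; flip under negation
  d_exp <- d; d_exp$tpc_water <- exp(d$tpc_water / 4)
  expect_equal(assay_roc(d_exp, "TPC", "water")$auc, r$auc, tolerance = 1e-12)
  d_neg <- d; d_neg$tpc_water <- max(d$tpc_water) - d$tpc_water
  r_neg <- assay_roc(d_neg, "TPC", "water")
  expect_equal(r_neg$auc, r$auc, tolerance = 1e-12)
  expect_equal(r_neg$orientation, "lower-is-UFR")

  # perfect separation and the degenerate constant feature
  d_sep <- d; d_sep$teac_meoh <- ifelse(d$label == "UFR", 100, 1)
  expect_equal(assay_roc(d_sep, "TEAC", "methanol")$auc, 1)
  d_const <- d; d_const$frap_water <- 5
  rc <- assay_roc(d_const, "FRAP", "water")
  expect_equal(rc$auc, 0.5)
  expect_true(rc$degenerate)
})

test_that("single-feature AUC approaches Phi(delta/sqrt(2))", {
  for (delta in c(0, 1, 2)) {
    d <- make_signal_dataset(10000L, delta, seed = 33L + delta)
    r <- assay_roc(d, "TPC", "water")
    expect_lt(abs(r$auc - pnorm(delta / sqrt(2))), 0.01)
  }
})

test_that("jackknife of the mean reproduces s/sqrt(n) exactly", {
  set.seed(34)
  x <- rnorm(37, sd = 3)
  jk <- jackknife(x, mean)
  expect_equal(jk$se, sd(x) / sqrt(length(x)), tolerance = 1e-12)
  expect_equal(jk$estimate, mean(x), tolerance = 1e-12)
  expect_equal(jackknife_se(rep(0.3, 10)), 0)
})

test_that("single-split evaluation behaves on easy and null problems", {
  # widely separated classes: accuracy >= 0.95 (Phi(delta/2) with delta >= 4)
  d_easy <- make_signal_dataset(60L, 4, seed = 35L)
  spec <- feature_set("TPC", "water")
  acc <- evaluate_once(d_easy, spec, "baseline", split_config(seed = 1L))
  expect_gte(acc, 0.95)

  # labels independent of features: accuracy near one half
  d_null <- make_signal_dataset(49L, 0, seed = 36L)
  acc0 <- evaluate_once(d_null, spec, "baseline", split_config(seed = 2L))
  expect_lt(abs(acc0 - 0.5), 0.2)

  expect_identical(
    evaluate_once(d_easy, spec, "baseline", split_config(seed = 3L)),
    evaluate_once(d_easy, spec, "baseline", split_config(seed = 3L)))
  expect_identical(
    evaluate_once(d_easy, spec, "KNN", split_config(seed = 3L),
                  grids = small_grids()),
    evaluate_once(d_easy, spec, "KNN", split_config(seed = 3L),
                  grids = small_grids()))
})

test_that("jackknife comparison of the baseline against itself is null", {
  d <- make_signal_dataset(12L, 2, seed = 37L)
  res <- jackknife_compare(d, feature_set("TPC", "water"), "baseline",
                           split_config(seed = 4L))
  expect_equal(res$accuracy_difference, 0)
  expect_equal(res$jackknife_se, 0)
  expect_false(res$significant)
  expect_equal(res$n_replicates, 24L)
})

test_that("the full comparison enumerates every cell deterministically", {
  d <- make_signal_dataset(12L, 1.5, seed = 38L)
  specs <- enumerate_feature_sets()[c(1, 8)]
  r1 <- run_full_comparison(d, split_config(seed = 9L), methods = c("LR", "KNN"),
                            specs = specs, grids = small_grids())
  expect_equal(nrow(r1$baseline), 2L)
  expect_equal(nrow(r1$comparisons), 4L)
  expect_true(all(r1$comparisons$baseline_accuracy >= 0 &
                    r1$comparisons$ml_accuracy <= 1))
  r2 <- run_full_comparison(d, split_config(seed = 9L), methods = c("LR", "KNN"),
                            specs = specs, grids = small_grids())
  expect_identical(r1, r2)
})

test_that("scheduled optimization count is the plain product", {
  expect_equal(count_scheduled_optimizations(98, 21, 4), 8232)
  expect_equal(count_scheduled_optimizations(1, 1, 1), 1)
  expect_equal(count_scheduled_optimizations(0, 21, 4), 0)
})
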