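# Shared fixture builders; all data are generated in code.

# small assay dataset with independent uniform measurements
make_dataset <- function(n_fr = 6L, n_ufr = 5L, seed = 1L) {
  set.seed(seed)
  n <- n_fr + n_ufr
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    label = c(rep("FR", n_fr), rep("UFR", n_ufr)),
    tpc_water = runif(n, 150, 550), teac_water = runif(n, 1600, 5100),
    frap_water = runif(n, 300, 1300), tpc_meoh = runif(n, 190, 420),
    teac_meoh = runif(n, 1200, 2900), frap_meoh = runif(n, 450, 1500),
    stringsAsFactors = FALSE)
}

# dataset whose tpc_water column carries a two-class Gaussian signal and the
# other columns are uninformative
make_signal_dataset <- function(n_per_class, delta, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  lab <- rep(c("FR", "UFR"), each = n_per_class)
  feat <- 100 + 10 * (rnorm(n) + ifelse(lab == "UFR", delta, 0))
  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)), label = lab,
    tpc_water = feat, teac_water = 100 + runif(n), frap_water = 100 + runif(n),
    tpc_meoh = 100 + runif(n), teac_meoh = 100 + runif(n),
    frap_meoh = 100 + runif(n), stringsAsFactors = FALSE)
}

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per_class = 30L, d = 2L, sep = 10, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  list(x = x, labels = rep(c("FR", "UFR"), each = n_per_class))
}

small_grids <- function() {
  list(LR = list(C = 1),
       SVM = list(C = 1, kernel = "linear", gamma = "scale"),
       RF = list(ntree = 100, max_depth = Inf),
       KNN = list(k = 5, weights = "uniform"))
}
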