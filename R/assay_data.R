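#' @keywords internal
ASSAYS <- c("TPC", "TEAC", "FRAP")

#' @keywords internal
SOLVENT_SCOPES <- c("water", "methanol", "both")

#' @keywords internal
LABELS <- c("FR", "UFR")

# fixed CSV schema shared by every stage; wide layout so feature sets can
# mix solvents without joins
ASSAY_COLUMNS <- c("tpc_water", "teac_water", "frap_water",
                   "tpc_meoh", "teac_meoh", "frap_meoh")
CSV_HEADER <- c("sample_id", "label", ASSAY_COLUMNS)

#' Validate an assay dataset
#'
#' Checks that a data frame conforms to the assay-table contract: the fixed
#' column set (`sample_id`, `label`, then the six measurement columns
#' `tpc_water`, `teac_water`, `frap_water`, `tpc_meoh`, `teac_meoh`,
#' `frap_meoh`), labels restricted to the exact strings `"FR"` / `"UFR"`,
#' finite non-negative measurements, and unique sample ids.
#'
#' @param dataset A data frame of assay measurements, one row per sample.
#' @param require_both_labels If `TRUE`, additionally require at least one
#'   sample of each label (needed for classification).
#' @return The validated data frame, invisibly.
#' @export
validate_assay_data <- function(dataset, require_both_labels = FALSE) {
  if (!is.data.frame(dataset)) stop("dataset must be a data frame")
  missing_cols <- setdiff(CSV_HEADER, names(dataset))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  extra_cols <- setdiff(names(dataset), CSV_HEADER)
  if (length(extra_cols) > 0L)
    stop("unexpected column(s): ", paste(extra_cols, collapse = ", "))
  bad_label <- which(!dataset$label %in% LABELS)
  if (length(bad_label) > 0L)
    stop("row ", bad_label[1L], ": label \"", dataset$label[bad_label[1L]],
         "\" is not one of {FR, UFR}")
  for (col in ASSAY_COLUMNS) {
    v <- dataset[[col]]
    if (!is.numeric(v)) stop("column ", col, " is not numeric")
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L)
      stop("row ", bad[1L], ": column ", col,
           " has a non-finite or negative value")
  }
  if (anyDuplicated(dataset$sample_id))
    stop("duplicate sample_id: ",
         dataset$sample_id[anyDuplicated(dataset$sample_id)])
  if (require_both_labels) {
    absent <- setdiff(LABELS, unique(dataset$label))
    if (length(absent) > 0L)
      stop("label ", absent[1L], " absent from dataset")
  }
  invisible(dataset)
}

#' Read an assay dataset from CSV
#'
#' Reads a UTF-8 comma-separated table with the exact header
#' `sample_id,label,tpc_water,teac_water,frap_water,tpc_meoh,teac_meoh,frap_meoh`
#' and returns a validated data frame, preserving file row order.
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per sample.
#' @seealso [write_assay_csv()]
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(raw), CSV_HEADER))
    stop("CSV header mismatch; expected exactly: ",
         paste(CSV_HEADER, collapse = ","), call. = FALSE)
  for (col in ASSAY_COLUMNS) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L)
      stop("row ", bad[1L], ": column ", col, " value \"",
           raw[[col]][bad[1L]], "\" is not numeric")
    raw[[col]] <- v
  }
  validate_assay_data(raw)
  raw
}

#' Write an assay dataset to CSV
#'
#' Writes the fixed wide schema used throughout the package. Floating-point
#' values are written with full precision (15 significant digits), so a
#' read/write round trip is the identity on values.
#'
#' @param dataset A validated assay data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(dataset, path) {
  if (nrow(dataset) == 0L) stop("refusing to write an empty dataset")
  validate_assay_data(dataset)
  out <- dataset[, CSV_HEADER]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Define a classifier feature set
#'
#' A feature set is a non-empty subset of the three assays (TPC, TEAC, FRAP)
#' paired with a solvent scope (`water`, `methanol`, or `both`). Feature
#' order is canonical: assays in the order TPC, TEAC, FRAP; under scope
#' `both`, the water block precedes the methanol block. There are
#' 7 assay subsets x 3 scopes = 21 distinct feature sets.
#'
#' @param assays Character vector, subset of `c("TPC", "TEAC", "FRAP")`.
#' @param scope One of `"water"`, `"methanol"`, `"both"`.
#' @return An object of class `feature_set`.
#' @examples
#' feature_set(c("TPC", "TEAC"), "methanol")
#' @export
feature_set <- function(assays, scope = c("water", "methanol", "both")) {
  scope <- match.arg(scope)
  assays <- unique(toupper(assays))
  if (length(assays) == 0L) stop("assays must be a non-empty subset")
  if (!all(assays %in% ASSAYS))
    stop("unknown assay(s): ", paste(setdiff(assays, ASSAYS), collapse = ", "))
  assays <- ASSAYS[ASSAYS %in% assays]   # canonical order
  structure(list(assays = assays, scope = scope), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set: {", paste(x$assays, collapse = ", "), "} / ",
      x$scope, " (", length(feature_columns(x)), " feature",
      if (length(feature_columns(x)) > 1L) "s", ")\n", sep = "")
  invisible(x)
}

#' Column names selected by a feature set
#'
#' @param spec A [feature_set()].
#' @return Character vector of dataset column names, in canonical order.
#' @export
feature_columns <- function(spec) {
  stopifnot(inherits(spec, "feature_set"))
  water <- paste0(tolower(spec$assays), "_water")
  meoh <- paste0(tolower(spec$assays), "_meoh")
  switch(spec$scope,
         water = water,
         methanol = meoh,
         both = c(water, meoh))
}

#' Enumerate all 21 classifier feature sets
#'
#' The 7 non-empty subsets of {TPC, TEAC, FRAP} crossed with the 3 solvent
#' scopes.
#'
#' @return A list of 21 distinct [feature_set()] objects.
#' @export
enumerate_feature_sets <- function() {
  subsets <- list("TPC", "TEAC", "FRAP",
                  c("TPC", "TEAC"), c("TPC", "FRAP"), c("TEAC", "FRAP"),
                  c("TPC", "TEAC", "FRAP"))
  out <- list()
  for (scope in SOLVENT_SCOPES)
    for (s in subsets)
      out[[length(out) + 1L]] <- feature_set(s, scope)
  out
}

#' Extract a feature matrix and labels from a dataset
#'
#' @param dataset A validated assay data frame.
#' @param spec A [feature_set()].
#' @return A list with `x` (numeric matrix, rows in dataset order, columns
#'   in canonical feature order) and `labels` (character vector of
#'   `"FR"`/`"UFR"`).
#' @export
extract_features <- function(dataset, spec) {
  validate_assay_data(dataset)
  if (nrow(dataset) == 0L) stop("dataset is empty")
  cols <- feature_columns(spec)
  x <- as.matrix(dataset[, cols, drop = FALSE])
  rownames(x) <- NULL
  list(x = x, labels = dataset$label)
}
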