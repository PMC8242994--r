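# Reading, validating, imputing, and modality-splitting of 47-feature drug
# tables: 13 chemical columns (10 molecular properties + 3 drug-likeness
# rule outcomes), 34 target-based columns (30 tissue-expression medians +
# degree + betweenness + loss-of-function frequency), and a binary outcome.

N_CHEMICAL <- 13L
N_TARGET <- 34L

#' Feature schema of a bimodal drug table
#'
#' Describes which CSV columns form the chemical modality (13 columns), the
#' target-based modality (34 columns), and the outcome, and how raw label
#' values map to the binary classes (1 = approved/positive,
#' 0 = failed/negative).
#'
#' @param chemical_columns Character vector of 13 column names.
#' @param target_columns Character vector of 34 column names.
#' @param label_column Name of the outcome column.
#' @param positive_label,negative_label Raw values mapped to 1 and 0.
#' @param id_column Optional name of an identifier column.
#' @return An object of class `"feature_schema"`.
#' @export
feature_schema <- function(chemical_columns, target_columns, label_column,
                           positive_label = "approved",
                           negative_label = "failed",
                           id_column = NULL) {
  chemical_columns <- as.character(chemical_columns)
  target_columns <- as.character(target_columns)
  if (length(chemical_columns) != N_CHEMICAL) {
    opcnn_stop(sprintf("schema requires %d chemical columns, got %d",
                       N_CHEMICAL, length(chemical_columns)), "schema_error")
  }
  if (length(target_columns) != N_TARGET) {
    opcnn_stop(sprintf("schema requires %d target columns, got %d",
                       N_TARGET, length(target_columns)), "schema_error")
  }
  feats <- c(chemical_columns, target_columns)
  if (anyDuplicated(feats) || label_column %in% feats) {
    opcnn_stop("feature columns must be disjoint and exclude the label",
               "schema_error")
  }
  structure(list(chemical_columns = chemical_columns,
                 target_columns = target_columns,
                 label_column = as.character(label_column),
                 positive_label = as.character(positive_label),
                 negative_label = as.character(negative_label),
                 id_column = id_column),
            class = "feature_schema")
}

#' Default schema for the synthetic 47-feature layout
#'
#' Column names mirror the structure of the PrOCTOR-style drug table: ten
#' molecular properties, three drug-likeness rule outcomes, thirty
#' tissue-expression medians, two network centralities, and the target
#' loss-of-function frequency.
#'
#' @return A [feature_schema()].
#' @export
default_schema <- function() {
  feature_schema(
    chemical_columns = c("molecular_weight", "xlogp", "polar_surface_area",
                         "h_bond_donors", "h_bond_acceptors", "formal_charge",
                         "ring_count", "rotatable_bonds", "refractivity",
                         "logp_solubility", "rule_lipinski", "rule_veber",
                         "rule_ghose"),
    target_columns = c(sprintf("tissue_median_%02d", 1:30),
                       "degree", "betweenness", "lof_frequency",
                       "target_count"),
    label_column = "outcome",
    id_column = "drug_id"
  )
}

#' @rdname feature_schema
#' @param path File path of a schema JSON file.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) {
    opcnn_stop(sprintf("schema file not found: %s", path), "schema_error")
  }
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_schema(js$chemical_columns, js$target_columns, js$label_column,
                 js$positive_label %||% "approved",
                 js$negative_label %||% "failed",
                 js$id_column)
}

#' @rdname feature_schema
#' @param schema A `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Construct a bimodal dataset
#'
#' The in-memory container used throughout the package: one row per drug,
#' with the chemical feature matrix `x1` (n x 13), the target-based feature
#' matrix `x2` (n x 34), and binary labels `y` (1 = approved). Missing
#' feature values are represented as `NA` until [impute_median()] is
#' applied; models and the modality splitter refuse residual `NA`s.
#'
#' @param x1,x2 Numeric matrices with equal row counts (`NA` = missing).
#' @param y Binary (0/1) label vector.
#' @param ids Optional character row identifiers.
#' @param provenance `"real"` or `"synthetic"`.
#' @param synthetic Optional logical vector flagging oversampled rows.
#' @return An object of class `"bimodal_dataset"`.
#' @export
bimodal_dataset <- function(x1, x2, y, ids = NULL,
                            provenance = c("real", "synthetic"),
                            synthetic = NULL) {
  provenance <- match.arg(provenance)
  x1 <- as.matrix(x1); storage.mode(x1) <- "double"
  x2 <- as.matrix(x2); storage.mode(x2) <- "double"
  y <- check_binary(y, "y")
  n <- length(y)
  if (nrow(x1) != n || nrow(x2) != n) {
    opcnn_stop("x1, x2, and y must have matching row counts",
               "dimension_error")
  }
  ids <- as.character(ids %||% sprintf("row_%04d", seq_len(n)))
  synthetic <- synthetic %||% rep(FALSE, n)
  structure(list(x1 = x1, x2 = x2, y = as.integer(y), ids = ids,
                 provenance = provenance, synthetic = synthetic),
            class = "bimodal_dataset")
}

#' @export
print.bimodal_dataset <- function(x, ...) {
  cb <- tryCatch(class_balance(x), opcnn_error = function(e) NULL)
  cat(sprintf("<bimodal_dataset> %d rows (%s): x1 %d cols, x2 %d cols\n",
              length(x$y), x$provenance, ncol(x$x1), ncol(x$x2)))
  if (!is.null(cb)) {
    cat(sprintf("  classes: %d positive / %d negative (ratio %.3f)\n",
                cb$n_pos, cb$n_neg, cb$ratio))
  }
  nm <- n_missing(x)
  if (nm > 0) cat(sprintf("  %d missing cells awaiting imputation\n", nm))
  invisible(x)
}

n_missing <- function(ds) sum(is.na(ds$x1)) + sum(is.na(ds$x2))

#' Subset a bimodal dataset by row index
#'
#' @param ds A [bimodal_dataset()].
#' @param idx Integer row indices.
#' @return A `bimodal_dataset` with the selected rows, order preserved.
#' @export
subset_rows <- function(ds, idx) {
  stopifnot(inherits(ds, "bimodal_dataset"))
  bimodal_dataset(ds$x1[idx, , drop = FALSE], ds$x2[idx, , drop = FALSE],
                  ds$y[idx], ds$ids[idx], ds$provenance, ds$synthetic[idx])
}

#' Read a drug feature table from CSV
#'
#' Parses an RFC-4180 CSV with a header row against a [feature_schema()].
#' Rows are kept in file order; labels are mapped to 0/1; empty or
#' non-numeric feature cells are recorded as missing (`NA`), never as zero.
#'
#' @param path CSV file path.
#' @param schema A [feature_schema()].
#' @return A [bimodal_dataset()] (possibly containing `NA` cells).
#' @export
read_feature_table <- function(path, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  if (!file.exists(path)) {
    opcnn_stop(sprintf("file not found: %s", path), "data_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  needed <- c(schema$chemical_columns, schema$target_columns,
              schema$label_column)
  absent <- setdiff(needed, names(df))
  if (length(absent) > 0) {
    opcnn_stop(sprintf("schema column(s) missing from file: %s",
                       paste(absent, collapse = ", ")), "schema_error")
  }
  ids <- if (!is.null(schema$id_column) && schema$id_column %in% names(df)) {
    as.character(df[[schema$id_column]])
  } else {
    sprintf("row_%04d", seq_len(nrow(df)))
  }
  raw <- as.character(df[[schema$label_column]])
  y <- ifelse(raw == schema$positive_label, 1L,
              ifelse(raw == schema$negative_label, 0L, NA_integer_))
  if (anyNA(y)) {
    bad <- which(is.na(y))[1]
    opcnn_stop(sprintf("unmappable label value '%s' at row id %s",
                       raw[bad], ids[bad]), "data_error")
  }
  num_mat <- function(cols) {
    m <- vapply(cols, function(cn) suppressWarnings(as.numeric(df[[cn]])),
                numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df),
                dimnames = list(NULL, cols))
    m
  }
  bimodal_dataset(num_mat(schema$chemical_columns),
                  num_mat(schema$target_columns), y, ids,
                  provenance = "real")
}

#' Write a dataset back to CSV in schema order
#'
#' @param ds A [bimodal_dataset()].
#' @param path Output CSV path.
#' @param schema A [feature_schema()] providing column names and raw labels.
#' @export
write_feature_table <- function(ds, path, schema) {
  stopifnot(inherits(ds, "bimodal_dataset"), inherits(schema, "feature_schema"))
  x1 <- ds$x1; x2 <- ds$x2
  colnames(x1) <- schema$chemical_columns
  colnames(x2) <- schema$target_columns
  df <- data.frame(id = ds$ids, x1, x2,
                   label = ifelse(ds$y == 1, schema$positive_label,
                                  schema$negative_label),
                   check.names = FALSE)
  names(df)[1] <- schema$id_column %||% "drug_id"
  names(df)[ncol(df)] <- schema$label_column
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

fit_medians <- function(ds, fit_rows) {
  med_of <- function(m, prefix) {
    vapply(seq_len(ncol(m)), function(j) {
      v <- m[fit_rows, j]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        nm <- colnames(m)[j] %||% sprintf("%s[%d]", prefix, j)
        opcnn_stop(sprintf(
          "feature '%s' has no observed value among the fit rows", nm),
          "imputation_error")
      }
      stats::median(v)
    }, numeric(1))
  }
  list(x1 = med_of(ds$x1, "x1"), x2 = med_of(ds$x2, "x2"))
}

apply_medians <- function(ds, medians) {
  fill <- function(m, med) {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (any(miss)) m[miss, j] <- med[j]
    }
    m
  }
  ds$x1 <- fill(ds$x1, medians$x1)
  ds$x2 <- fill(ds$x2, medians$x2)
  ds
}

#' Median imputation of missing feature values
#'
#' Replaces every missing cell of a feature by the median of that feature
#' computed over `fit_rows` (the training rows, to avoid leakage; pass all
#' rows for whole-table imputation). The median of an even count is the mean
#' of the two central values. Non-missing entries are left bit-identical and
#' the operation is idempotent.
#'
#' @param ds A [bimodal_dataset()].
#' @param fit_rows Integer indices of rows used to fit the medians
#'   (default: all rows).
#' @return The dataset with no remaining `NA` cells.
#' @export
impute_median <- function(ds, fit_rows = seq_along(ds$y)) {
  stopifnot(inherits(ds, "bimodal_dataset"))
  apply_medians(ds, fit_medians(ds, fit_rows))
}

#' Class balance of a dataset
#'
#' @param ds A [bimodal_dataset()].
#' @return List with `n`, `n_pos`, `n_neg`, and
#'   `ratio = max(n_pos, n_neg) / min(n_pos, n_neg)`.
#' @export
class_balance <- function(ds) {
  stopifnot(inherits(ds, "bimodal_dataset"))
  n <- length(ds$y)
  if (n == 0) opcnn_stop("dataset is empty", "data_error")
  n_pos <- sum(ds$y == 1L)
  n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0) {
    opcnn_stop("imbalance ratio undefined: one class is absent",
               "balance_error")
  }
  list(n = n, n_pos = n_pos, n_neg = n_neg,
       ratio = max(n_pos, n_neg) / min(n_pos, n_neg))
}

#' Split a dataset into its two modality matrices
#'
#' Returns the chemical matrix, the target-based matrix, and the label
#' vector, with columns ordered as in `schema` (when the dataset carries
#' column names) and rows in dataset order. Refuses residual missing
#' values — run [impute_median()] first.
#'
#' @param ds A fully imputed [bimodal_dataset()].
#' @param schema Optional [feature_schema()] dictating column order.
#' @return List with `x1` (n x 13), `x2` (n x 34), and `y`.
#' @export
split_modalities <- function(ds, schema = NULL) {
  stopifnot(inherits(ds, "bimodal_dataset"))
  for (part in c("x1", "x2")) {
    m <- ds[[part]]
    if (anyNA(m)) {
      w <- which(is.na(m), arr.ind = TRUE)[1, ]
      opcnn_stop(sprintf("missing value remains at %s[%d, %d]; impute first",
                         part, w[1], w[2]), "data_error")
    }
  }
  x1 <- ds$x1; x2 <- ds$x2
  if (!is.null(schema)) {
    stopifnot(inherits(schema, "feature_schema"))
    if (!is.null(colnames(x1))) x1 <- x1[, schema$chemical_columns, drop = FALSE]
    if (!is.null(colnames(x2))) x2 <- x2[, schema$target_columns, drop = FALSE]
  }
  list(x1 = x1, x2 = x2, y = ds$y)
}
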