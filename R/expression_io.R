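# Expression matrix / sample-sheet I/O and normalization.
#
# Expression TSV dialect: first column "symbol", remaining columns sample IDs,
# tab-separated, UTF-8, "." decimal, empty cells = missing.
# Sample sheet dialect: columns sample_id, patient_id, tissue (tumor|control).

#' Paired expression set
#'
#' Container for a matched tumor/control cohort: two log2 expression matrices
#' (features x patients) sharing the same feature symbols and patient order.
#'
#' @param symbols Character vector of unique feature symbols (miRNAs and/or
#'   gene mRNAs).
#' @param patients Character vector of unique patient identifiers.
#' @param control,tumor Numeric matrices of log2 intensities with
#'   `length(symbols)` rows and `length(patients)` columns.
#' @return An object of class `paired_expression_set`.
#' @export
paired_expression_set <- function(symbols, patients, control, tumor) {
  symbols <- as.character(symbols)
  patients <- as.character(patients)
  if (anyDuplicated(symbols)) {
    stopf("duplicate feature symbol: %s",
          paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  if (anyDuplicated(patients)) stopf("duplicate patient IDs")
  control <- as.matrix(control)
  tumor <- as.matrix(tumor)
  if (!identical(dim(control), dim(tumor))) {
    stopf("control and tumor matrices must have identical dimensions")
  }
  if (nrow(control) != length(symbols) || ncol(control) != length(patients)) {
    stopf("matrix dimensions do not match symbols/patients")
  }
  if (any(is.infinite(control)) || any(is.infinite(tumor))) {
    stopf("expression values must be finite or missing (NA)")
  }
  dimnames(control) <- list(symbols, patients)
  dimnames(tumor) <- list(symbols, patients)
  structure(
    list(symbols = symbols, patients = patients,
         control = control, tumor = tumor),
    class = "paired_expression_set"
  )
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat(sprintf("Paired expression set: %d features x %d matched patients\n",
              length(x$symbols), length(x$patients)))
  cat(sprintf("  conditions: control, tumor (log2 intensities)\n"))
  na <- sum(is.na(x$control)) + sum(is.na(x$tumor))
  if (na > 0) cat(sprintf("  missing values: %d\n", na))
  invisible(x)
}

read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (ncol(df) < 2 || tolower(names(df)[1]) != "symbol") {
    stopf("expression TSV must have a 'symbol' first column: %s", path)
  }
  sym <- as.character(df[[1]])
  if (anyDuplicated(sym)) {
    stopf("duplicate feature symbol: %s",
          paste(unique(sym[duplicated(sym)]), collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- sym
  mat
}

read_samplesheet_tsv <- function(path) {
  ss <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% names(ss))) {
    stopf("sample sheet must have columns %s", paste(need, collapse = ", "))
  }
  ss$tissue <- tolower(ss$tissue)
  if (!all(ss$tissue %in% c("tumor", "control"))) {
    stopf("tissue must be 'tumor' or 'control'")
  }
  ss
}

#' Load a matched tumor/control expression set from TSV files
#'
#' Reads an expression matrix (rows = features, columns = samples) and a sample
#' sheet pairing tumor and control samples per patient, and returns the two
#' aligned matrices. Patients lacking either tissue are dropped with a warning;
#' a patient with two samples of the same tissue is an error. Features missing
#' in more than `max_missing` of samples are dropped with a warning; remaining
#' missing values are kept as `NA` and handled pairwise-complete downstream.
#' Values are assumed to be log scale already when the matrix maximum is below
#' 30; otherwise `log2(x + 1)` is applied with a warning.
#'
#' @param matrix_path Path to the expression TSV (first column `symbol`).
#' @param samplesheet_path Path to the sample sheet TSV (columns `sample_id`,
#'   `patient_id`, `tissue`).
#' @param max_missing Maximum tolerated fraction of missing values per feature
#'   (default 0.2).
#' @return A [paired_expression_set()].
#' @export
load_paired_set <- function(matrix_path, samplesheet_path, max_missing = 0.2) {
  mat <- read_expression_tsv(matrix_path)
  ss <- read_samplesheet_tsv(samplesheet_path)

  missing_cols <- setdiff(ss$sample_id, colnames(mat))
  if (length(missing_cols) > 0) {
    stopf("sample sheet references missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  dup <- ss[duplicated(ss[, c("patient_id", "tissue")]), , drop = FALSE]
  if (nrow(dup) > 0) {
    stopf("patient %s has two %s samples", dup$patient_id[1], dup$tissue[1])
  }

  tum <- ss[ss$tissue == "tumor", ]
  ctl <- ss[ss$tissue == "control", ]
  paired <- intersect(tum$patient_id, ctl$patient_id)
  # preserve sample-sheet patient order
  paired <- unique(ss$patient_id)[unique(ss$patient_id) %in% paired]
  unpaired <- setdiff(unique(ss$patient_id), paired)
  if (length(unpaired) > 0) {
    warnf("dropping unpaired patients: %s", paste(unpaired, collapse = ", "))
  }
  if (length(paired) == 0) stopf("no complete tumor/control pairs")

  tum_cols <- tum$sample_id[match(paired, tum$patient_id)]
  ctl_cols <- ctl$sample_id[match(paired, ctl$patient_id)]

  if (max(mat, na.rm = TRUE) >= 30) {
    warnf("matrix maximum >= 30: assuming raw intensities, applying log2(x + 1)")
    mat <- log2(mat + 1)
  }

  frac_na <- rowMeans(is.na(mat[, c(tum_cols, ctl_cols), drop = FALSE]))
  drop <- frac_na > max_missing
  if (any(drop)) {
    warnf("dropping %d feature(s) with > %.0f%% missing values: %s",
          sum(drop), 100 * max_missing,
          paste(head(rownames(mat)[drop], 5), collapse = ", "))
    mat <- mat[!drop, , drop = FALSE]
  }

  paired_expression_set(
    symbols = rownames(mat), patients = paired,
    control = mat[, ctl_cols, drop = FALSE],
    tumor = mat[, tum_cols, drop = FALSE]
  )
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution: after
#' normalization the sorted value vector of every column is identical and the
#' within-column ranks are preserved. Ties receive the mean of the reference
#' values at their rank positions. For a paired set, tumor and control columns
#' are normalized jointly so the two conditions stay on a common scale.
#'
#' @param x A numeric matrix (features x samples) or a
#'   [paired_expression_set()].
#' @return An object of the same class as `x`.
#' @export
quantile_normalize <- function(x) UseMethod("quantile_normalize")

#' @export
quantile_normalize.matrix <- function(x) {
  if (ncol(x) < 2) stopf("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
quantile_normalize.paired_expression_set <- function(x) {
  np <- length(x$patients)
  combined <- cbind(x$control, x$tumor)
  norm <- quantile_normalize(combined)
  paired_expression_set(
    x$symbols, x$patients,
    control = norm[, seq_len(np), drop = FALSE],
    tumor = norm[, np + seq_len(np), drop = FALSE]
  )
}

write_expression_tsv <- function(mat, path) {
  # 17 significant digits so doubles round-trip exactly through the TSV
  chr <- matrix(sprintf("%.17g", mat), nrow(mat))
  chr[is.na(mat)] <- ""
  df <- data.frame(symbol = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("symbol", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_samplesheet_tsv <- function(ss, path) {
  write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
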