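# Core omics containers: mass-feature tables and expression matrices.
#
# A FeatureTable holds LC-MS mass features (feature_id, m/z, optional
# retention time) with a features x samples abundance matrix; an
# ExpressionMatrix holds transcripts x samples normalized expression.
# Both are plain lists with a matrix payload so that downstream stages can
# use ordinary linear algebra.

#' Construct a mass-feature table
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param mz positive mass-to-charge values (Da/e), one per feature.
#' @param abundance numeric matrix, features x samples, nonnegative;
#'   column names are sample ids.
#' @param rt optional retention times (seconds).
#' @return object of class `FeatureTable`.
#' @export
feature_table <- function(feature_id, mz, abundance, rt = NULL) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) {
    dup <- unique(feature_id[duplicated(feature_id)])
    stop2("duplicate feature_id: %s", paste(dup, collapse = ", "))
  }
  mz <- as.numeric(mz)
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop2("all m/z values must be positive finite numbers")
  }
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (nrow(abundance) != length(feature_id)) {
    stop2("abundance must have one row per feature")
  }
  if (is.null(colnames(abundance))) {
    stop2("abundance matrix needs sample ids as column names")
  }
  bad <- which(abundance < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop2("negative abundance for feature '%s' (sample '%s')",
          feature_id[bad[1, 1]], colnames(abundance)[bad[1, 2]])
  }
  rownames(abundance) <- feature_id
  if (!is.null(rt)) {
    rt <- as.numeric(rt)
    stopifnot(length(rt) == length(feature_id))
  }
  structure(list(feature_id = feature_id, mz = mz, rt = rt,
                 abundance = abundance),
            class = "FeatureTable")
}

#' Construct an expression matrix
#'
#' @param values numeric matrix, transcripts x samples, with transcript ids
#'   as row names and sample ids as column names.
#' @return object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop2("transcript ids required as rownames")
  if (is.null(colnames(values))) stop2("sample ids required as colnames")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop2("duplicate transcript_id: %s", paste(dup, collapse = ", "))
  }
  structure(list(transcript_id = rownames(values), values = values),
            class = "ExpressionMatrix")
}

#' Sample ids of an omics container
#' @param x a `FeatureTable` or `ExpressionMatrix`.
#' @return character vector of sample ids, in column order.
#' @export
samples <- function(x) UseMethod("samples")

#' @export
samples.FeatureTable <- function(x) colnames(x$abundance)

#' @export
samples.ExpressionMatrix <- function(x) colnames(x$values)

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features x %d samples\n",
              length(x$feature_id), ncol(x$abundance)))
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a mass-feature table from CSV
#'
#' Sample columns are detected by exclusion of the declared metadata
#' columns, mirroring the usual layout of processed metabolomics exports
#' (feature id, m/z, retention time, then one abundance column per sample).
#'
#' @param path CSV file path.
#' @param id_col,mz_col,rt_col metadata column names; `rt_col` is optional
#'   and ignored when absent.
#' @param extra_meta_cols further non-sample columns to exclude.
#' @param sep field separator.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, id_col = "feature_id", mz_col = "mz",
                               rt_col = "rt", extra_meta_cols = character(),
                               sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop2("no features in %s", path)
  for (col in c(id_col, mz_col)) {
    if (!col %in% names(df)) stop2("missing column '%s' in %s", col, path)
  }
  meta <- c(id_col, mz_col, intersect(rt_col, names(df)), extra_meta_cols)
  sample_cols <- setdiff(names(df), meta)
  if (length(sample_cols) == 0) stop2("no sample columns in %s", path)
  ab <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(ab)) stop2("non-numeric abundance values in %s", path)
  feature_table(df[[id_col]], df[[mz_col]], ab,
                rt = if (rt_col %in% names(df)) df[[rt_col]] else NULL)
}

#' Write a mass-feature table to CSV (full precision)
#' @param x a `FeatureTable`.
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(feature_id = x$feature_id, mz = fmt_num(x$mz),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(x$rt)) df$rt <- fmt_num(x$rt)
  ab <- apply(x$abundance, 2, fmt_num)
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1,
                                     dimnames = list(NULL,
                                                     colnames(x$abundance)))
  utils::write.csv(cbind(df, ab), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a transcript expression matrix from CSV
#'
#' First column holds transcript ids; remaining columns are samples with
#' normalized counts. Sample order is preserved.
#'
#' @param path CSV file path.
#' @param sep field separator.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop2("no transcripts in %s", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop2("non-numeric value at row %d, column '%s' of %s",
            bad, names(vals)[j], path)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m)
}

#' Write an expression matrix to CSV (full precision)
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  vals <- apply(x$values, 2, fmt_num)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL,
                                                         colnames(x$values)))
  df <- cbind(data.frame(transcript_id = x$transcript_id,
                         stringsAsFactors = FALSE), vals)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Align a feature table and an expression matrix on shared samples
#'
#' Both containers are restricted to the intersection of their sample ids,
#' reordered lexicographically so the pairing is deterministic regardless
#' of input column order. Correlation needs at least 3 shared samples.
#'
#' @param features a `FeatureTable`.
#' @param expr an `ExpressionMatrix`.
#' @return list with elements `features` and `expr`, sample-aligned.
#' @export
align_samples <- function(features, expr) {
  shared <- lex_sort(intersect(samples(features), samples(expr)))
  if (length(shared) < 3) {
    stop2("only %d shared sample(s); need at least 3 for correlation",
          length(shared))
  }
  f2 <- features
  f2$abundance <- features$abundance[, shared, drop = FALSE]
  e2 <- expression_matrix(expr$values[, shared, drop = FALSE])
  list(features = f2, expr = e2)
}
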