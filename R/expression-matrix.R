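#' Construct an expression matrix object
#'
#' The canonical container for expression data throughout the package:
#' a numeric matrix with samples in rows and features (TFs, miRNAs, outcome
#' genes) in columns, together with per-feature class labels, optional
#' per-sample tissue labels, and a scale tag distinguishing raw abundances
#' (counts, FPKM-UQ, TPM, RPM) from log2-transformed values.
#'
#' @param values numeric matrix, samples x features. Row names are taken as
#'   sample ids and column names as feature ids unless given explicitly.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique feature identifiers.
#' @param feature_class character vector (recycled "GENE" by default), one of
#'   `"TF"`, `"MIRNA"`, `"GENE"` per feature.
#' @param tissue optional character vector of per-sample tissue labels.
#' @param scale `"log2"` or `"raw"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              feature_ids = colnames(values),
                              feature_class = NULL, tissue = NULL,
                              scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) must equal ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("values contains non-finite entries; complete matrices are required")
  if (is.null(feature_class)) feature_class <- rep("GENE", ncol(values))
  feature_class <- rep_len(as.character(feature_class), ncol(values))
  bad <- setdiff(unique(feature_class), c("TF", "MIRNA", "GENE"))
  if (length(bad))
    stop("unknown feature class: ", paste(bad, collapse = ", "))
  if (!is.null(tissue)) {
    tissue <- rep_len(as.character(tissue), nrow(values))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, feature_class = feature_class,
                 tissue = tissue, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cls <- table(factor(x$feature_class, levels = c("TF", "MIRNA", "GENE")))
  cat(sprintf("ExpressionMatrix: %d samples x %d features [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  feature classes: TF=%d MIRNA=%d GENE=%d\n",
              cls[["TF"]], cls[["MIRNA"]], cls[["GENE"]]))
  if (!is.null(x$tissue))
    cat(sprintf("  tissues: %d distinct\n", length(unique(x$tissue))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by sample and/or feature
#'
#' @param x an `ExpressionMatrix`.
#' @param samples sample indices or ids (default: all).
#' @param features feature indices or ids (default: all).
#' @return An `ExpressionMatrix` restricted to the selection.
#' @export
em_subset <- function(x, samples = NULL, features = NULL) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  fi <- if (is.null(features)) seq_along(x$feature_ids) else {
    if (is.character(features)) match(features, x$feature_ids) else features
  }
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(fi)) stop("unknown feature id(s)")
  expression_matrix(x$values[si, fi, drop = FALSE],
                    sample_ids = x$sample_ids[si],
                    feature_ids = x$feature_ids[fi],
                    feature_class = x$feature_class[fi],
                    tissue = if (!is.null(x$tissue)) x$tissue[si],
                    scale = x$scale)
}

#' Feature catalog: which ids are TFs and which are miRNAs
#'
#' @param tf_ids character vector of transcription-factor ids.
#' @param mirna_ids character vector of miRNA ids.
#' @return A `FeatureCatalog` (list with `tf_ids`, `mirna_ids`).
#' @export
feature_catalog <- function(tf_ids = character(), mirna_ids = character()) {
  tf_ids <- unique(as.character(tf_ids))
  mirna_ids <- unique(as.character(mirna_ids))
  both <- intersect(tf_ids, mirna_ids)
  if (length(both))
    stop("ids listed as both TF and miRNA: ", paste(both, collapse = ", "))
  structure(list(tf_ids = tf_ids, mirna_ids = mirna_ids),
            class = "FeatureCatalog")
}

#' Log2-transform a raw-scale expression matrix
#'
#' Applies `log2(x + pseudocount)` entrywise. The pseudocount depends on the
#' upstream normalization dialect: 1 is conventional for count-like data,
#' 0.001 matches the `log2(TPM + 0.001)` convention of the Xena browser.
#'
#' @param matrix raw-scale `ExpressionMatrix`, all values nonnegative.
#' @param pseudocount positive offset added before taking logs.
#' @return A log2-scale `ExpressionMatrix`.
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw")
    stop("matrix is already on log2 scale")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  neg <- which(matrix$values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative value for feature ",
         matrix$feature_ids[neg[1, 2]], " (sample ",
         matrix$sample_ids[neg[1, 1]], "); raw abundances must be >= 0")
  out <- matrix
  out$values <- log2(matrix$values + pseudocount)
  out$scale <- "log2"
  out
}

#' Remove miRNAs that are zero in most samples
#'
#' A miRNA feature is dropped when the fraction of samples with a zero read
#' count is at least `zero_fraction_cutoff` (inclusive). TF and GENE features
#' are never touched and survivor order is preserved. Must run on the raw
#' scale, where zeros are still identifiable.
#'
#' @param matrix raw-scale `ExpressionMatrix`.
#' @param zero_fraction_cutoff fraction in (0, 1]; default 0.75.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_zero_heavy_mirnas <- function(matrix, zero_fraction_cutoff = 0.75) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw")
    stop("zero filter requires raw scale (zeros are not identifiable after log2)")
  if (!is.numeric(zero_fraction_cutoff) || zero_fraction_cutoff <= 0 ||
      zero_fraction_cutoff > 1)
    stop("zero_fraction_cutoff must lie in (0, 1]")
  n <- nrow(matrix$values)
  zero_frac <- colMeans(matrix$values == 0)
  drop <- matrix$feature_class == "MIRNA" & zero_frac >= zero_fraction_cutoff
  if (!any(drop)) return(matrix)
  em_subset(matrix, features = which(!drop))
}

#' Split a matrix into regulator and outcome sub-matrices
#'
#' Regulators are the TF and miRNA columns (classes taken from the catalog
#' when supplied, else from the matrix's own feature classes); outcomes are
#' the remaining GENE columns.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param catalog optional `FeatureCatalog`; ids absent from the matrix are
#'   skipped with a warning.
#' @return A list with `regulators` and `outcomes` (both `ExpressionMatrix`).
#' @export
partition_features <- function(matrix, catalog = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  cls <- matrix$feature_class
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "FeatureCatalog"))
    missing_ids <- setdiff(c(catalog$tf_ids, catalog$mirna_ids),
                           matrix$feature_ids)
    if (length(missing_ids))
      warning("catalog ids absent from matrix, skipped: ",
              paste(utils::head(missing_ids, 5), collapse = ", "),
              if (length(missing_ids) > 5) ", ...")
    cls <- rep("GENE", length(matrix$feature_ids))
    cls[matrix$feature_ids %in% catalog$tf_ids] <- "TF"
    cls[matrix$feature_ids %in% catalog$mirna_ids] <- "MIRNA"
  }
  reg_idx <- which(cls %in% c("TF", "MIRNA"))
  if (length(reg_idx) == 0)
    stop("empty regulator set: no TF or miRNA features found")
  out_idx <- which(cls == "GENE")
  m <- matrix
  m$feature_class <- cls
  list(regulators = em_subset(m, features = reg_idx),
       outcomes = em_subset(m, features = out_idx))
}

# -- delimited-file I/O ------------------------------------------------------

.guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row and a leading id column. Files in
#' features-by-samples orientation are transposed into the canonical
#' samples-by-features layout.
#'
#' @param path TSV/CSV file (delimiter guessed from the extension unless
#'   `sep` is given).
#' @param orientation `"samples-by-features"` (default) or
#'   `"features-by-samples"`.
#' @param feature_class,tissue optional vectors passed through to
#'   [expression_matrix()] (in canonical orientation).
#' @param scale scale tag for the values.
#' @param sep field delimiter override.
#' @return An `ExpressionMatrix`.
#' @export
read_matrix <- function(path,
                        orientation = c("samples-by-features",
                                        "features-by-samples"),
                        feature_class = NULL, tissue = NULL,
                        scale = c("log2", "raw"), sep = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  sep <- .guess_sep(path, sep)
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file needs a header and one data row")
  nfield <- lengths(strsplit(lines, sep, fixed = TRUE))
  # header has one fewer field when the id-column header cell is omitted
  if (any(nfield[-1] != nfield[2]))
    stop("ragged row at line ", which(nfield[-1] != nfield[2])[1] + 1)
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate id '", ids[duplicated(ids)][1], "' at line ",
         which(duplicated(ids))[1] + 1)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (orientation == "features-by-samples") vals <- t(vals)
  expression_matrix(vals, feature_class = feature_class, tissue = tissue,
                    scale = scale)
}

#' Write an expression matrix as delimited text
#'
#' @param matrix an `ExpressionMatrix`.
#' @param path output TSV/CSV path (delimiter from extension unless `sep`).
#' @param sep field delimiter override.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, sep = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  sep <- .guess_sep(path, sep)
  df <- data.frame(sample_id = matrix$sample_ids,
                   matrix$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature catalog from a two-column TSV (feature_id, class)
#'
#' @param path two-column delimited file with header; class values are
#'   `TF`/`MIRNA` (anything else is ignored as GENE).
#' @param sep delimiter override.
#' @return A `FeatureCatalog`.
#' @export
read_catalog <- function(path, sep = NULL) {
  sep <- .guess_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  cls <- toupper(df[[2]])
  feature_catalog(tf_ids = df[[1]][cls == "TF"],
                  mirna_ids = df[[1]][cls == "MIRNA"])
}

#' Read per-sample tissue labels from a two-column TSV (sample_id, tissue)
#'
#' @param path two-column delimited file with header.
#' @param sep delimiter override.
#' @return Named character vector, names = sample ids.
#' @export
read_tissues <- function(path, sep = NULL) {
  sep <- .guess_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
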