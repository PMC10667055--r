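# Expression matrix container and unit conversions.
#
# An expr_matrix is a genes x samples numeric matrix plus a unit tag
# (FPKM, TPM or LOG2). Gene and sample identifiers live in dimnames and
# must be unique; FPKM/TPM values must be finite and non-negative.

EXPR_UNITS <- c("FPKM", "TPM", "LOG2")

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param unit One of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @return An object of class `expr_matrix`: the matrix with a `unit`
#'   attribute.
#' @export
expr_matrix <- function(values, unit = c("FPKM", "TPM", "LOG2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene (row) and sample (column) names are required", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite (missing values are not supported)",
         call. = FALSE)
  }
  if (unit %in% c("FPKM", "TPM") && any(values < 0)) {
    stop(sprintf("%s values must be non-negative", unit), call. = FALSE)
  }
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param x An `expr_matrix`.
#' @return The unit string.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("not an expr_matrix: no unit tag", call. = FALSE)
  u
}

# Accept either an expr_matrix or a bare named numeric matrix.
.expr_values <- function(x) {
  v <- unclass(x)
  attr(v, "unit") <- NULL
  if (!is.matrix(v) || !is.numeric(v)) {
    stop("expected an expression matrix", call. = FALSE)
  }
  v
}

#' Read a genes-by-samples expression table
#'
#' The first column holds gene identifiers and the header row holds sample
#' identifiers. Duplicate gene rows are collapsed by their mean (with a
#' warning naming the genes). Non-numeric cells raise an error naming the
#' offending row and column.
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`.
#' @param unit Declared unit of the stored values.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv"),
                            unit = c("FPKM", "TPM", "LOG2")) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      comment.char = "#", check.names = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("empty or malformed expression file: %s (%s)",
                   path, conditionMessage(e)), call. = FALSE)
    })
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop(sprintf("empty or malformed expression file: %s", path),
         call. = FALSE)
  }
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric expression value at gene '%s', sample '%s'",
      genes[bad[["row"]]], colnames(vals)[bad[["col"]]]), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning(sprintf("collapsed %d duplicated gene id(s) by row mean: %s",
                    length(dups), paste(utils::head(dups, 5L), collapse = ", ")),
            call. = FALSE)
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(df[[1L]])
  }
  rownames(num) <- genes
  expr_matrix(num, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' Emits a header comment line recording the unit, then a tab-separated
#' table with gene ids in the first column.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  v <- .expr_values(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m6aTME expression matrix; unit=%s", expr_unit(x)), con)
  writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' TPM rescales each sample so that its values sum to one million:
#' `tpm[i, j] = fpkm[i, j] / sum_i fpkm[i, j] * 1e6`.
#'
#' @param m An `expr_matrix` with unit FPKM.
#' @return An `expr_matrix` with unit TPM.
#' @export
fpkm_to_tpm <- function(m) {
  if (expr_unit(m) != "FPKM") {
    stop("fpkm_to_tpm expects an FPKM matrix", call. = FALSE)
  }
  v <- .expr_values(m)
  cs <- colSums(v)
  if (any(cs <= 0)) {
    stop(sprintf("all-zero expression column(s): %s",
                 paste(colnames(v)[cs <= 0], collapse = ", ")), call. = FALSE)
  }
  expr_matrix(sweep(v, 2L, cs, "/") * 1e6, unit = "TPM")
}

#' Log2(x + 1) transform
#'
#' @param m An `expr_matrix` on the FPKM or TPM scale.
#' @return An `expr_matrix` with unit LOG2.
#' @export
log_transform <- function(m) {
  u <- expr_unit(m)
  if (u == "LOG2") {
    stop("matrix is already on the LOG2 scale (double-transform guard)",
         call. = FALSE)
  }
  expr_matrix(log2(.expr_values(m) + 1), unit = "LOG2")
}
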