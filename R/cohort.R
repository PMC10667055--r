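# Clinical tables, sample alignment and cohort merging with batch
# correction. A cohort bundle pairs one expression matrix with one clinical
# table (plus optional mutation / CNV tables and per-sample batch labels);
# it is the unit of pipeline execution.

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time` (months, > 0) and `os_event`
#' (0 = censored, 1 = dead). Optional columns (`pfs_time`, `pfs_event`,
#' `age`, `sex`, ...) are carried through untouched.
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`.
#' @return A `data.frame`, one row per sample.
#' @export
read_clinical <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param df A data frame with at least `sample_id`, `os_time`, `os_event`.
#' @return The validated data frame (invisible checks, visible value).
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("clinical table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("clinical table has duplicated sample ids", call. = FALSE)
  }
  .assert_pos_times(df$os_time)
  .assert_binary(df$os_event, "os_event")
  if ("pfs_time" %in% names(df)) .assert_pos_times(df$pfs_time)
  if ("pfs_event" %in% names(df)) .assert_binary(df$pfs_event, "pfs_event")
  df
}

#' Write a clinical table as TSV
#' @param df Clinical data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# m6aTME clinical table; times in months", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle expression and clinical data for one cohort
#'
#' @param expression An [expr_matrix()].
#' @param clinical A clinical data frame (see [validate_clinical()]).
#' @param mutations Optional mutation table (see [read_mutations()]).
#' @param cnv Optional CNV call table.
#' @param batch Optional per-sample batch label vector (recycled scalar ok).
#' @return A `cohort` object (list).
#' @export
cohort_bundle <- function(expression, clinical, mutations = NULL, cnv = NULL,
                          batch = NULL) {
  clinical <- validate_clinical(clinical)
  ids <- colnames(expression)
  if (!setequal(ids, clinical$sample_id)) {
    stop("expression and clinical samples differ; use align_samples()",
         call. = FALSE)
  }
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  if (is.null(batch)) batch <- rep("batch1", length(ids))
  if (length(batch) == 1L) batch <- rep(batch, length(ids))
  stopifnot(length(batch) == length(ids))
  structure(list(expression = expression, clinical = clinical,
                 mutations = mutations, cnv = cnv,
                 batch = as.character(batch)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples, %d genes [%s], %d batch(es)%s%s\n",
              ncol(x$expression), nrow(x$expression),
              expr_unit(x$expression), length(unique(x$batch)),
              if (is.null(x$mutations)) "" else ", mutations",
              if (is.null(x$cnv)) "" else ", cnv"))
  invisible(x)
}

#' Align expression columns with clinical rows
#'
#' Keeps the intersection of sample ids; output column order follows the
#' clinical row order. Dropped ids are reported in a warning.
#'
#' @param expr An [expr_matrix()].
#' @param clinical Clinical data frame.
#' @inheritParams cohort_bundle
#' @return A `cohort` bundle on the shared samples.
#' @export
align_samples <- function(expr, clinical, mutations = NULL, cnv = NULL,
                          batch = NULL) {
  clinical <- validate_clinical(clinical)
  shared <- intersect(clinical$sample_id, colnames(expr))
  if (length(shared) == 0L) {
    stop("no samples shared between expression and clinical data",
         call. = FALSE)
  }
  drop_e <- setdiff(colnames(expr), shared)
  drop_c <- setdiff(clinical$sample_id, shared)
  if (length(drop_e) || length(drop_c)) {
    warning(sprintf("dropped %d expression-only and %d clinical-only sample(s)",
                    length(drop_e), length(drop_c)), call. = FALSE)
  }
  keep <- clinical$sample_id[clinical$sample_id %in% shared]
  if (!is.null(batch) && length(batch) == ncol(expr)) {
    batch <- batch[match(keep, colnames(expr))]
  }
  ex <- expr_matrix(.expr_values(expr)[, keep, drop = FALSE],
                    unit = expr_unit(expr))
  cohort_bundle(ex, clinical[match(keep, clinical$sample_id), , drop = FALSE],
                mutations = mutations, cnv = cnv, batch = batch)
}

# Exact per-gene, per-batch location-scale equalization. Each batch's gene
# mean is mapped to the pooled mean and its gene SD to the pooled
# within-batch SD, making the correction idempotent and the cross-batch
# means exactly equal.
.equalize_batches <- function(v, batch) {
  batches <- unique(batch)
  m_pool <- rowMeans(v)
  ss <- 0; dfree <- 0
  stats_b <- lapply(batches, function(b) {
    xb <- v[, batch == b, drop = FALSE]
    list(m = rowMeans(xb), s2 = apply(xb, 1L, stats::var), n = ncol(xb))
  })
  names(stats_b) <- batches
  for (b in batches) {
    ss <- ss + stats_b[[b]]$s2 * (stats_b[[b]]$n - 1L)
    dfree <- dfree + stats_b[[b]]$n - 1L
  }
  s_pool <- sqrt(ss / dfree)
  out <- v
  for (b in batches) {
    i <- batch == b
    sb <- sqrt(stats_b[[b]]$s2)
    scale_fac <- ifelse(sb > 0, s_pool / sb, 1)
    out[, i] <- (v[, i, drop = FALSE] - stats_b[[b]]$m) * scale_fac + m_pool
  }
  out
}

#' Merge cohorts with batch correction
#'
#' Intersects gene sets across bundles (dropped genes are reported),
#' concatenates samples, and removes per-gene batch effects in location and
#' scale. The default `"equalize"` method standardizes each batch's
#' per-gene mean and SD to the pooled targets exactly, so cross-batch gene
#' means are equal after correction and re-running the correction is a
#' no-op. `"combat"` applies parametric empirical-Bayes shrinkage of the
#' per-batch location/scale estimates (via \pkg{sva}), preferable when
#' batches are very small.
#'
#' @param bundles List of two or more `cohort` objects on the LOG2 scale.
#' @param method `"equalize"` (default) or `"combat"`.
#' @return A single merged `cohort` with batch labels retained.
#' @export
merge_cohorts <- function(bundles, method = c("equalize", "combat")) {
  method <- match.arg(method)
  stopifnot(is.list(bundles), length(bundles) >= 2L)
  units <- vapply(bundles, function(b) expr_unit(b$expression), character(1))
  if (any(units != "LOG2")) {
    stop("all cohorts must be on the LOG2 scale before merging", call. = FALSE)
  }
  gene_sets <- lapply(bundles, function(b) rownames(b$expression))
  shared <- Reduce(intersect, gene_sets)
  n_drop <- length(unique(unlist(gene_sets))) - length(shared)
  if (length(shared) < 50L) {
    stop(sprintf("only %d genes shared across cohorts (need >= 50)",
                 length(shared)), call. = FALSE)
  }
  if (n_drop > 0L) {
    message(sprintf("merge_cohorts: dropped %d gene(s) absent from some cohort",
                    n_drop))
  }
  mats <- lapply(bundles, function(b)
    .expr_values(b$expression)[shared, , drop = FALSE])
  v <- do.call(cbind, mats)
  if (anyDuplicated(colnames(v))) {
    stop("duplicate sample ids across cohorts", call. = FALSE)
  }
  batch <- unlist(lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]$batch
    if (length(unique(b)) == 1L && b[1L] == "batch1") {
      rep(sprintf("cohort%d", i), ncol(bundles[[i]]$expression))
    } else b
  }), use.names = FALSE)
  if (any(table(batch) < 2L)) {
    stop("each batch needs at least two samples (variance inestimable)",
         call. = FALSE)
  }
  corrected <- switch(method,
    equalize = .equalize_batches(v, batch),
    combat = {
      cm <- sva::ComBat(dat = v, batch = batch)
      dimnames(cm) <- dimnames(v)
      cm
    })
  clin_cols <- Reduce(intersect, lapply(bundles, function(b) names(b$clinical)))
  clinical <- do.call(rbind, lapply(bundles, function(b)
    b$clinical[, clin_cols, drop = FALSE]))
  rownames(clinical) <- NULL
  cohort_bundle(expr_matrix(corrected, unit = "LOG2"), clinical, batch = batch)
}
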