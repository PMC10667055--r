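# The per-patient m6A score: correlation-PCA over the prognostic
# phenotype genes, score = PC1 projection + PC2 projection, dichotomized
# at the maximally-selected survival cutpoint and correlated with immune
# features.

#' Partition signature genes by their correlation with the reference axis
#'
#' Each prognostic gene goes to set A when it correlates positively with
#' the reference axis (default: the first principal component of the
#' prognostic-gene submatrix) and to set B otherwise. Zero-variance genes
#' are excluded with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param prognostic_genes Genes defining the signature (>= 2).
#' @param reference Optional numeric reference axis per sample; defaults
#'   to the PC1 sample scores of the prognostic-gene submatrix.
#' @return A `signature_partition`: list with `A`, `B` and the per-gene
#'   correlation `statistic`.
#' @export
partition_signature <- function(expr, prognostic_genes, reference = NULL) {
  v <- .expr_values(expr)
  genes <- intersect(prognostic_genes, rownames(v))
  if (length(genes) < 2L) stop("need at least 2 prognostic genes",
                               call. = FALSE)
  sub <- v[genes, , drop = FALSE]
  flat <- apply(sub, 1L, stats::var) == 0
  if (any(flat)) {
    warning(sprintf("excluded zero-variance gene(s): %s",
                    paste(genes[flat], collapse = ", ")), call. = FALSE)
    sub <- sub[!flat, , drop = FALSE]
    genes <- genes[!flat]
  }
  if (is.null(reference)) {
    reference <- pca_embed(sub)$scores[, 1L]
  }
  stopifnot(length(reference) == ncol(sub))
  stat <- apply(sub, 1L, stats::cor, y = reference)
  A <- genes[stat >= 0]
  B <- genes[stat < 0]
  if (!length(B)) {
    warning("all genes positively correlated with the reference; set B empty",
            call. = FALSE)
  }
  structure(list(A = A, B = B, statistic = stat), class = "signature_partition")
}

#' @export
print.signature_partition <- function(x, ...) {
  cat(sprintf("<signature_partition> |A| = %d, |B| = %d\n",
              length(x$A), length(x$B)))
  invisible(x)
}

#' Compute the m6A score
#'
#' Genes are z-scored across samples (correlation PCA), the samples x
#' genes matrix is decomposed by SVD, and each sample's score is the sum
#' of its projections on the first two components:
#' `score_j = pc1_j + pc2_j = sum_i (v1_i + v2_i) * z_ij`.
#' Each component is oriented so its largest-magnitude gene loading is
#' positive (removing the SVD sign ambiguity independently of sample
#' order); the positively-associated gene set A is defined from the
#' oriented PC1, so PC1 correlates positively with A's mean profile by
#' construction.
#'
#' @param expr Expression matrix (genes x samples, >= 3 samples).
#' @param prognostic_genes Genes entering the signature (>= 2 with
#'   positive variance).
#' @return An `m6a_score` object: data frame-like list with per-sample
#'   `pc1`, `pc2`, `score`, plus `loadings`, `explained` and `partition`.
#' @export
compute_score <- function(expr, prognostic_genes) {
  v <- .expr_values(expr)
  genes <- intersect(prognostic_genes, rownames(v))
  if (length(genes) < 2L) stop("need at least 2 signature genes",
                               call. = FALSE)
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  sub <- v[genes, , drop = FALSE]
  vars <- apply(sub, 1L, stats::var)
  if (any(vars == 0)) {
    warning(sprintf("excluded zero-variance gene(s): %s",
                    paste(genes[vars == 0], collapse = ", ")), call. = FALSE)
    sub <- sub[vars > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 genes with variance > 0",
                           call. = FALSE)
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  x <- t(z)                                  # samples x genes
  s <- svd(x)
  if (sum(s$d > max(dim(x)) * .Machine$double.eps * s$d[1L]) < 2L) {
    stop("standardized signature matrix has rank < 2", call. = FALSE)
  }
  v1 <- s$v[, 1L]; v2 <- s$v[, 2L]
  # orientation: each component's largest-magnitude loading is made
  # positive (a sample-order-independent rule); set A is then the genes
  # positively correlated with the oriented PC1, so PC1 correlates
  # positively with the mean profile of A by construction
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  if (v2[which.max(abs(v2))] < 0) v2 <- -v2
  pc1 <- drop(x %*% v1); pc2 <- drop(x %*% v2)
  part <- partition_signature(v, rownames(sub), reference = pc1)
  loadings <- cbind(PC1 = v1, PC2 = v2)
  rownames(loadings) <- rownames(sub)
  structure(list(sample_id = colnames(sub), pc1 = pc1, pc2 = pc2,
                 score = pc1 + pc2, loadings = loadings,
                 explained = s$d^2 / sum(s$d^2), partition = part,
                 cutpoint = NULL, group = NULL),
            class = "m6a_score")
}

#' @export
print.m6a_score <- function(x, ...) {
  cat(sprintf("<m6a_score> %d samples; PC1+PC2 capture %.1f%% of variance\n",
              length(x$score), 100 * sum(x$explained[1:2])))
  if (!is.null(x$group)) {
    cat(sprintf("  cutpoint %.4g: %d high / %d low\n", x$cutpoint,
                sum(x$group == "high"), sum(x$group == "low")))
  }
  invisible(x)
}

#' @export
as.data.frame.m6a_score <- function(x, ...) {
  out <- data.frame(sample_id = x$sample_id, pc1 = x$pc1, pc2 = x$pc2,
                    m6a_score = x$score)
  if (!is.null(x$group)) out$group <- x$group
  out
}

#' Dichotomize the m6A score at the maximally-selected survival cutpoint
#'
#' @param score An `m6a_score` (or numeric vector named by sample).
#' @param clinical Clinical table covering the scored samples.
#' @param minprop Minimum group fraction for the cutpoint search.
#' @return The `m6a_score` object with `cutpoint` and `group`
#'   (`"high"`/`"low"`) filled in (a fresh object when given a vector).
#' @export
dichotomize_score <- function(score, clinical, minprop = 0.1) {
  clinical <- validate_clinical(clinical)
  if (inherits(score, "m6a_score")) {
    obj <- score
    s <- stats::setNames(obj$score, obj$sample_id)
  } else {
    s <- score
    if (is.null(names(s))) stop("score vector must be named by sample",
                                call. = FALSE)
    obj <- structure(list(sample_id = names(s), pc1 = NULL, pc2 = NULL,
                          score = unname(s), loadings = NULL,
                          explained = NULL, partition = NULL,
                          cutpoint = NULL, group = NULL),
                     class = "m6a_score")
  }
  idx <- match(names(s), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table does not cover all scored samples",
                       call. = FALSE)
  cp <- optimal_cutpoint(clinical$os_time[idx], clinical$os_event[idx],
                         unname(s), minprop = minprop)
  obj$cutpoint <- cp$cutpoint
  obj$cut_statistic <- cp$statistic
  obj$group <- ifelse(unname(s) > cp$cutpoint, "high", "low")
  obj
}

#' Correlate the m6A score with immune features
#'
#' Spearman correlation of the score against every row of an enrichment
#' (or fraction) matrix, BH-adjusted. Constant rows give NA with a
#' warning.
#'
#' @param score An `m6a_score` or named numeric vector.
#' @param enrichment Sets/cell types x samples matrix.
#' @return Data frame: `feature`, `rho`, `p`, `adj_p`.
#' @export
correlate_immune <- function(score, enrichment) {
  s <- if (inherits(score, "m6a_score")) {
    stats::setNames(score$score, score$sample_id)
  } else score
  m <- as.matrix(unclass(enrichment))
  shared <- intersect(names(s), colnames(m))
  if (length(shared) < 10L) stop("need at least 10 shared samples",
                                 call. = FALSE)
  s <- s[shared]; m <- m[, shared, drop = FALSE]
  rows <- lapply(rownames(m), function(f) {
    x <- m[f, ]
    if (stats::sd(x) == 0) {
      warning(sprintf("constant feature '%s': correlation undefined", f),
              call. = FALSE)
      return(data.frame(feature = f, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(s, x, method = "spearman"))
    data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- !is.na(out$p)
  out$adj_p <- NA_real_
  out$adj_p[ok] <- bh_adjust(out$p[ok])
  out
}

#' Joined per-sample stratification table
#'
#' One row per sample carrying the m6A cluster, gene cluster, score group
#' and vital status — the data behind an alluvial/Sankey view of the
#' stratification.
#'
#' @param score A dichotomized `m6a_score`.
#' @param m6a_cluster Named cluster labels (samples).
#' @param gene_cluster Named cluster labels (samples).
#' @param clinical Clinical table.
#' @return Data frame with one row per scored sample.
#' @export
sankey_table <- function(score, m6a_cluster, gene_cluster, clinical) {
  stopifnot(inherits(score, "m6a_score"), !is.null(score$group))
  clinical <- validate_clinical(clinical)
  ids <- score$sample_id
  data.frame(
    sample_id = ids,
    m6a_cluster = unname(m6a_cluster[ids]),
    gene_cluster = unname(gene_cluster[ids]),
    score_group = score$group,
    status = ifelse(clinical$os_event[match(ids, clinical$sample_id)] == 1,
                    "dead", "alive"))
}
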