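# Single-sample gene-set scoring: rank-weighted running-sum ssGSEA for
# immune-infiltration panels, and kernel-CDF GSVA-style scoring for
# pathway activity, plus group comparisons of the resulting score
# matrices. Both scorers are implemented here in full (no enrichment
# package stands behind them).

.match_sets <- function(sets, genes, allow_full = FALSE) {
  matched <- lapply(sets, function(s) intersect(unique(s), genes))
  empty <- vapply(matched, length, integer(1)) == 0L
  if (any(empty)) {
    message(sprintf("dropped %d gene set(s) with no genes in the matrix: %s",
                    sum(empty),
                    paste(utils::head(names(sets)[empty], 5L), collapse = ", ")))
    matched <- matched[!empty]
  }
  if (!length(matched)) stop("no gene set overlaps the matrix", call. = FALSE)
  if (!allow_full) {
    full <- vapply(matched, length, integer(1)) == length(genes)
    if (any(full)) {
      stop(sprintf("gene set(s) equal to the whole gene universe: %s",
                   paste(names(matched)[full], collapse = ", ")),
           call. = FALSE)
    }
  }
  matched
}

#' Single-sample GSEA enrichment scores
#'
#' Per sample, genes are ranked by expression (average ranks for ties)
#' and walked in decreasing order; the enrichment score of a set is the
#' sum over all positions of the difference between the rank-weighted
#' in-set ECDF (weights `rank^alpha`) and the unweighted out-of-set ECDF
#' (the running-sum integral). With `normalize = TRUE` the whole score
#' matrix is min-max rescaled to `[0, 1]`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene_sets Named list of gene-id vectors; sets without any gene
#'   in the matrix are dropped with a message.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Min-max normalize the score matrix (default TRUE).
#' @return An `enrichment_matrix`: sets x samples matrix with `method`
#'   and `normalized` attributes.
#' @export
ssgsea_score <- function(expr, gene_sets, alpha = 0.25, normalize = TRUE) {
  v <- .expr_values(expr)
  genes <- rownames(v)
  n_genes <- length(genes)
  sets <- .match_sets(gene_sets, genes)
  scores <- matrix(NA_real_, length(sets), ncol(v),
                   dimnames = list(names(sets), colnames(v)))
  set_idx <- lapply(sets, function(s) match(s, genes))
  for (j in seq_len(ncol(v))) {
    r <- rank(v[, j], ties.method = "average")     # high expression = high rank
    ord <- order(v[, j], decreasing = TRUE)
    r_ord <- r[ord]
    w <- abs(r_ord)^alpha
    for (si in seq_along(sets)) {
      in_set <- logical(n_genes)
      in_set[set_idx[[si]]] <- TRUE
      in_ord <- in_set[ord]
      p_in <- cumsum(w * in_ord) / sum(w[in_ord])
      p_out <- cumsum(!in_ord) / (n_genes - sum(in_ord))
      scores[si, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1L]) / diff(rng)
  }
  structure(scores, method = "ssgsea", normalized = normalize,
            class = c("enrichment_matrix", "matrix", "array"))
}

# Kernel CDF per gene across samples: Gaussian kernel with bandwidth
# sd/4, or the empirical CDF. Zero-variance genes get the midrank value.
.kcdf <- function(v, kernel) {
  n <- ncol(v)
  z <- matrix(0.5, nrow(v), n, dimnames = dimnames(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    s <- stats::sd(x)
    if (s == 0) next                          # midrank for flat genes
    if (kernel == "gaussian") {
      h <- s / 4
      z[i, ] <- colMeans(stats::pnorm(outer(x, x, function(a, b)
        (b - a) / h)))
    } else {
      z[i, ] <- (rank(x, ties.method = "average") - 0.5) / n
    }
  }
  z
}

#' GSVA-style enrichment scores
#'
#' Per gene, an expression-level statistic is computed as a kernel CDF
#' across samples (Gaussian kernel, bandwidth = SD/4, or the empirical
#' CDF). Genes are then ranked within each sample, the ranks are folded
#' into a symmetric statistic `|n_genes/2 - rank|`, and each set is
#' scored by a Kolmogorov-style weighted running sum; the score is the
#' signed sum of the maximum positive and maximum negative deviations.
#'
#' @param expr Expression matrix (genes x samples, >= 3 samples).
#' @param gene_sets Named list of gene-id vectors.
#' @param kernel `"gaussian"` or `"ecdf"`.
#' @param tau Weight exponent on the symmetric rank statistic (default 1).
#' @return An `enrichment_matrix` (sets x samples).
#' @export
gsva_score <- function(expr, gene_sets, kernel = c("gaussian", "ecdf"),
                       tau = 1) {
  kernel <- match.arg(kernel)
  v <- .expr_values(expr)
  if (ncol(v) < 3L) stop("GSVA needs at least 3 samples", call. = FALSE)
  genes <- rownames(v)
  n_genes <- length(genes)
  flat <- apply(v, 1L, stats::sd) == 0
  if (any(flat)) {
    warning(sprintf("%d zero-variance gene(s) assigned midrank", sum(flat)),
            call. = FALSE)
  }
  z <- .kcdf(v, kernel)
  sets <- .match_sets(gene_sets, genes)
  set_idx <- lapply(sets, function(s) match(s, genes))
  scores <- matrix(NA_real_, length(sets), ncol(v),
                   dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(ncol(v))) {
    rk <- rank(z[, j], ties.method = "average")      # ascending rank
    r_sym <- abs(n_genes / 2 - rk)
    ord <- order(z[, j], decreasing = TRUE)
    r_ord <- r_sym[ord]^tau
    for (si in seq_along(sets)) {
      in_set <- logical(n_genes)
      in_set[set_idx[[si]]] <- TRUE
      in_ord <- in_set[ord]
      denom_in <- sum(r_ord[in_ord])
      p_in <- if (denom_in > 0) cumsum(r_ord * in_ord) / denom_in
              else cumsum(in_ord) / sum(in_ord)
      p_out <- cumsum(!in_ord) / (n_genes - sum(in_ord))
      walk <- p_in - p_out
      scores[si, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  if (all(flat)) scores[] <- 0          # no variation anywhere: no signal
  structure(scores, method = "gsva", normalized = FALSE,
            class = c("enrichment_matrix", "matrix", "array"))
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> %d sets x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}

#' Compare enrichment scores (or any per-sample score rows) across groups
#'
#' Two groups are compared by the two-sided Wilcoxon rank-sum test, three
#' or more by Kruskal-Wallis; p-values are BH-adjusted across sets.
#' Groups with fewer than 2 samples are excluded with a warning.
#'
#' @param scores Sets x samples matrix (e.g. an `enrichment_matrix`).
#' @param labels Group label per sample.
#' @return Data frame: `set`, per-group medians, `statistic`, `p`,
#'   `adj_p`, `stars`.
#' @export
compare_scores_by_group <- function(scores, labels) {
  m <- as.matrix(unclass(scores))
  stopifnot(ncol(m) == length(labels))
  g <- factor(labels)
  small <- names(which(table(g) < 2L))
  if (length(small)) {
    warning(sprintf("excluded group(s) with < 2 samples: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(g %in% small)
    m <- m[, keep, drop = FALSE]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("need at least two usable groups", call. = FALSE)
  rows <- lapply(rownames(m), function(s) {
    x <- m[s, ]
    med <- tapply(x, g, stats::median)
    if (nlevels(g) == 2L) {
      ht <- suppressWarnings(stats::wilcox.test(x ~ g, exact = FALSE,
                                                correct = TRUE))
    } else {
      ht <- stats::kruskal.test(x ~ g)
    }
    out <- data.frame(set = s, statistic = unname(ht$statistic),
                      p = ht$p.value)
    med_df <- as.data.frame(as.list(med))
    names(med_df) <- paste0("median_", levels(g))
    cbind(out[, "set", drop = FALSE], med_df,
          out[, c("statistic", "p"), drop = FALSE])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$adj_p <- bh_adjust(out$p)
  out$stars <- p_stars(out$p)
  out
}
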