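# Resampling-based consensus clustering with CDF/delta-area diagnostics,
# used both for the regulator-based molecular subtypes and for the gene
# clusters derived from prognostic phenotype genes.

# Base clusterers operate on a genes x samples matrix subset and return
# integer labels 1..k per sample.
.base_cluster <- function(v, k, base) {
  switch(base,
    hierarchical_pearson = {
      d <- stats::as.dist(1 - stats::cor(v, method = "pearson"))
      stats::cutree(stats::hclust(d, method = "average"), k = k)
    },
    kmeans = stats::kmeans(t(v), centers = k, nstart = 5L)$cluster,
    pam = {
      if (!requireNamespace("cluster", quietly = TRUE)) {
        stop("base = 'pam' requires the cluster package", call. = FALSE)
      }
      cluster::pam(t(v), k = k, cluster.only = TRUE)
    },
    stop(sprintf("unknown base clusterer '%s'", base), call. = FALSE))
}

#' Consensus clustering of samples
#'
#' For each of `reps` resampling iterations, a fraction `p_item` of the
#' samples is drawn without replacement and clustered at every K in
#' `k_range` with the base clusterer (default: hierarchical clustering on
#' 1 - Pearson correlation with average linkage). The consensus matrix
#' entry for a sample pair is the fraction of co-sampled iterations in
#' which the pair landed in the same cluster (0/0 counts as 0). Final
#' per-K labels come from hierarchical clustering of 1 - consensus.
#'
#' @param expr Expression matrix subset (genes x samples, LOG2 scale).
#' @param k_range Integer vector of candidate cluster numbers (>= 2).
#' @param reps Number of resampling iterations.
#' @param p_item Subsampling fraction.
#' @param base `"hierarchical_pearson"`, `"kmeans"` or `"pam"`.
#' @param seed Integer seed; runs are bit-stable given the seed.
#' @return A `consensus_result` with per-K consensus matrices, labels,
#'   CDF/delta-area diagnostics and `selected_k` (see [select_k()]).
#' @export
consensus_cluster <- function(expr, k_range = 2:6, reps = 1000L,
                              p_item = 0.8,
                              base = c("hierarchical_pearson", "kmeans", "pam"),
                              seed = 1L) {
  base <- match.arg(base)
  v <- .expr_values(expr)
  n <- ncol(v)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > floor(n / 3)) {
    stop("k_range must lie within [2, n_samples / 3]", call. = FALSE)
  }
  if (n < 3L * max(k_range)) {
    stop("need at least 3 * max(k_range) samples", call. = FALSE)
  }
  if (all(apply(v, 1L, stats::var) == 0)) {
    stop("constant expression matrix", call. = FALSE)
  }
  n_sub <- ceiling(p_item * n)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(derive_seed(seed, 0L)))

  co_count <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_count) <- as.character(k_range)
  sample_count <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, n_sub))
    ind <- matrix(0, n, n)
    ind[idx, idx] <- 1
    sample_count <- sample_count + ind
    sub <- v[, idx, drop = FALSE]
    for (k in k_range) {
      lab <- .base_cluster(sub, k, base)
      same <- outer(lab, lab, "==") * 1
      m <- matrix(0, n, n)
      m[idx, idx] <- same
      kk <- as.character(k)
      co_count[[kk]] <- co_count[[kk]] + m
    }
  }
  ids <- colnames(v)
  consensus <- lapply(co_count, function(cc) {
    M <- ifelse(sample_count > 0, cc / sample_count, 0)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    M
  })
  labels <- lapply(k_range, function(k) {
    M <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    stats::setNames(stats::cutree(hc, k = k), ids)
  })
  names(labels) <- as.character(k_range)

  # empirical CDF of off-diagonal consensus values and area under it
  grid <- seq(0, 1, by = 0.01)
  cdf <- lapply(consensus, function(M) {
    off <- M[upper.tri(M)]
    stats::setNames(vapply(grid, function(q) mean(off <= q), numeric(1)),
                    sprintf("%.2f", grid))
  })
  auc <- vapply(cdf, function(f) sum(diff(grid) * f[-1L]), numeric(1))

  # relative AUC increment; defined for the 3rd candidate K onwards, the
  # first candidate serving as baseline
  delta <- rep(NA_real_, length(k_range))
  names(delta) <- as.character(k_range)
  delta[1L] <- auc[1L]
  if (length(k_range) > 1L) {
    for (i in 2:length(k_range)) {
      delta[i] <- (auc[i] - auc[i - 1L]) / auc[i - 1L]
    }
  }

  res <- structure(list(consensus = consensus, labels = labels,
                        k_range = k_range, cdf = cdf, auc = auc,
                        delta_area = delta, reps = reps, p_item = p_item,
                        base = base, seed = seed, sample_ids = ids,
                        selected_k = NA_integer_, no_structure = FALSE),
                   class = "consensus_result")
  if (length(k_range) >= 3L) {
    sel <- select_k(res)
    res$selected_k <- sel$k
    res$no_structure <- sel$no_structure
  }
  res
}

#' Select the number of clusters from consensus diagnostics
#'
#' Scans the relative delta-area series (relative increment of the area
#' under the consensus CDF) and returns the largest K whose increment is
#' still at least `threshold` — i.e. the smallest K after which adding
#' clusters stops improving consensus. When no K beyond the smallest
#' candidate clears the threshold and the consensus matrix at that K is
#' ambiguous (a large share of entries far from both 0 and 1), a
#' "no structure" warning is raised.
#'
#' @param res A `consensus_result`.
#' @param threshold Relative delta-area threshold (default 0.1).
#' @return List with `k` (selected K), `delta_area` (full series) and
#'   `no_structure` flag.
#' @export
select_k <- function(res, threshold = 0.1) {
  stopifnot(inherits(res, "consensus_result"))
  kr <- res$k_range
  if (length(kr) < 3L) stop("need at least 3 candidate K", call. = FALSE)
  delta <- res$delta_area
  gains <- delta[-1L]                      # increments beyond the baseline K
  cleared <- which(gains >= threshold)
  k <- if (length(cleared)) kr[max(cleared) + 1L] else kr[1L]
  # ambiguity: share of off-diagonal consensus mass away from 0 and 1.
  # When the consensus at the candidate K is mostly ambiguous, the
  # delta-area gains reflect fragmentation of noise, not structure; fall
  # back to the baseline K and flag the run.
  M <- res$consensus[[as.character(k)]]
  off <- M[upper.tri(M)]
  pac <- mean(off > 0.1 & off < 0.9)
  no_structure <- FALSE
  if (pac > 0.4) {
    no_structure <- TRUE
    warning(sprintf(
      "no clear cluster structure (ambiguous consensus fraction %.2f at K = %d)",
      pac, k), call. = FALSE)
    k <- kr[1L]
  }
  list(k = k, delta_area = delta, no_structure = no_structure)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> n = %d samples, K in {%s}, reps = %d (%s)\n",
              length(x$sample_ids), paste(x$k_range, collapse = ","),
              x$reps, x$base))
  cat(sprintf("  selected K = %d%s\n", x$selected_k,
              if (x$no_structure) " [no clear structure]" else ""))
  cat("  delta-area:",
      paste(sprintf("K%d=%.3f", x$k_range, x$delta_area), collapse = " "), "\n")
  invisible(x)
}

#' Cluster labels at a given K
#' @param res A `consensus_result`.
#' @param k K (defaults to the selected K).
#' @return Named integer vector of labels.
#' @export
consensus_labels <- function(res, k = res$selected_k) {
  lab <- res$labels[[as.character(k)]]
  if (is.null(lab)) stop(sprintf("K = %s was not evaluated", k), call. = FALSE)
  lab
}

#' Two-component PCA embedding of samples
#'
#' Centers genes, takes the SVD, and returns the first two sample-score
#' columns with explained-variance fractions. Each component is oriented
#' so that its largest-magnitude gene loading is positive, removing the
#' SVD sign ambiguity.
#'
#' @param expr Expression matrix subset (genes x samples).
#' @return A `pca_embedding`: list with `scores` (n x 2), `explained`
#'   (variance fractions for all components), `loadings` (genes x 2).
#' @export
pca_embed <- function(expr) {
  v <- .expr_values(expr)
  if (ncol(v) < 3L || nrow(v) < 2L) {
    stop("need at least 3 samples and 2 genes", call. = FALSE)
  }
  x <- t(v - rowMeans(v))              # samples x genes, genes centered
  s <- svd(x)
  # rank-1 data (samples on an exact line) is allowed: the second
  # component then carries ~0 variance; a fully constant matrix is not
  if (s$d[1L] <= 0) {
    stop("expression matrix is constant (rank 0)", call. = FALSE)
  }
  flip <- vapply(1:2, function(j) {
    l <- s$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(s$u[, 1:2, drop = FALSE] %*% diag(s$d[1:2]), 2L, flip, "*")
  loadings <- sweep(s$v[, 1:2, drop = FALSE], 2L, flip, "*")
  dimnames(scores) <- list(colnames(v), c("PC1", "PC2"))
  dimnames(loadings) <- list(rownames(v), c("PC1", "PC2"))
  structure(list(scores = scores, explained = s$d^2 / sum(s$d^2),
                 loadings = loadings),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("<pca_embedding> %d samples; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$explained[1L], 100 * x$explained[2L]))
  invisible(x)
}
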