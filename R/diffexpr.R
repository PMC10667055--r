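# Moderated differential expression between modification-pattern clusters
# and derivation of the phenotype gene set. The empirical-Bayes moderated
# t-statistic (per-gene variances shrunk toward a common prior estimated
# by method of moments on the log variances) is provided by limma through
# a single multi-group fit shared by all pairwise contrasts.

.de_fit <- function(v, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  design <- stats::model.matrix(~ 0 + g)
  colnames(design) <- levels(g)
  limma::lmFit(v, design)
}

.contrast_table <- function(fit, g1, g2, shrink = TRUE) {
  cm <- matrix(0, ncol(fit$coefficients), 1,
               dimnames = list(colnames(fit$coefficients), "c"))
  cm[g1, 1] <- 1; cm[g2, 1] <- -1
  cf <- limma::contrasts.fit(fit, cm)
  if (shrink) {
    eb <- limma::eBayes(cf)
    t_stat <- eb$t[, 1L]
    p <- eb$p.value[, 1L]
    d0 <- eb$df.prior
    s02 <- eb$s2.prior
  } else {
    # ordinary (unmoderated) t from the same linear fit: the d0 = 0 limit
    t_stat <- cf$coefficients[, 1L] / (cf$stdev.unscaled[, 1L] * cf$sigma)
    p <- 2 * stats::pt(-abs(t_stat), df = cf$df.residual)
    d0 <- 0
    s02 <- NA_real_
  }
  logfc <- cf$coefficients[, 1L]
  flat <- cf$sigma == 0 & logfc == 0     # all-constant genes carry no signal
  p[flat] <- 1
  data.frame(gene = rownames(fit$coefficients), logFC = logfc, t = t_stat,
             p = p, adj_p = bh_adjust(p), d0 = d0, s02 = s02,
             flat = flat, row.names = NULL)
}

#' Moderated t differential expression for one contrast
#'
#' Fits per-gene group means, shrinks the residual variances toward a
#' common prior (prior df `d0` and prior variance `s0^2` estimated by
#' method of moments on the log residual variances), and tests the
#' `g1 - g2` mean difference with the moderated t on `d0 + d_g` degrees
#' of freedom. `shrink = FALSE` gives the ordinary pooled t (the d0 = 0
#' limit).
#'
#' @param expr Expression matrix (genes x samples, LOG2 scale).
#' @param labels Group label per sample.
#' @param contrast Character vector `c(g1, g2)`.
#' @param shrink Apply empirical-Bayes variance shrinkage (default TRUE).
#' @return Data frame: `gene`, `logFC`, `t`, `p`, `adj_p`, and the shared
#'   hyperparameters `d0`, `s02`.
#' @export
moderated_t <- function(expr, labels, contrast, shrink = TRUE) {
  v <- .expr_values(expr)
  stopifnot(length(labels) == ncol(v), length(contrast) == 2L)
  fit <- .de_fit(v, labels)
  if (!all(contrast %in% colnames(fit$coefficients))) {
    stop("contrast groups not found in labels", call. = FALSE)
  }
  .contrast_table(fit, contrast[1L], contrast[2L], shrink = shrink)
}

#' All pairwise moderated-t contrasts from one shared variance fit
#'
#' @inheritParams moderated_t
#' @return Named list of contrast tables (`"A_vs_B"`, ...), all sharing
#'   one variance-shrinkage fit.
#' @export
pairwise_moderated_t <- function(expr, labels, shrink = TRUE) {
  v <- .expr_values(expr)
  fit <- .de_fit(v, labels)
  lev <- colnames(fit$coefficients)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  out <- lapply(pairs, function(p)
    .contrast_table(fit, p[1L], p[2L], shrink = shrink))
  names(out) <- vapply(pairs, function(p) paste(p, collapse = "_vs_"),
                       character(1))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pvals Numeric p-values in `[0, 1]`; NAs are rejected.
#' @return Adjusted p-values (q-values).
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("NA p-values are not allowed", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Phenotype gene set from pairwise contrasts
#'
#' Genes whose adjusted p-value is below `alpha` in the required
#' combination of pairwise contrasts: the default `"intersection"` keeps
#' genes significant in every contrast (a Venn-diagram core);
#' `"union"` keeps genes significant in any contrast.
#'
#' @param de_results List of contrast tables from [pairwise_moderated_t()].
#' @param alpha Adjusted-p threshold.
#' @param rule `"intersection"` or `"union"`.
#' @return Character vector of gene ids.
#' @export
phenotype_degs <- function(de_results, alpha = 0.05,
                           rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  stopifnot(is.list(de_results), length(de_results) >= 2L)
  universes <- lapply(de_results, function(d) sort(d$gene))
  if (!all(vapply(universes[-1L], identical, logical(1), universes[[1L]]))) {
    stop("contrasts cover different gene universes", call. = FALSE)
  }
  # alpha = 1 disables the filter (adjusted p-values can equal 1 exactly)
  sig <- lapply(de_results, function(d)
    d$gene[if (alpha >= 1) rep(TRUE, nrow(d)) else d$adj_p < alpha])
  combine <- if (rule == "intersection") intersect else union
  sort(Reduce(combine, sig))
}
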