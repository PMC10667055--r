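# Regulator landscape: tumor-vs-normal differential expression, CNV
# gain/loss frequencies, somatic mutation frequency, and the prognostic
# coexpression network over the regulator genes.

#' Tumor-versus-normal differential expression of selected genes
#'
#' Two-sided Wilcoxon rank-sum per gene (exact when both groups have at
#' most 25 samples and no ties; normal approximation with continuity
#' correction otherwise), BH-adjusted, with star coding. Genes absent
#' from the matrix are reported as NA rows with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param group_labels Per-sample labels, `"tumor"` or `"normal"`.
#' @param genes Genes to test.
#' @return Data frame: `gene`, `median_tumor`, `median_normal`, `p`,
#'   `adj_p`, `stars`.
#' @export
tumor_vs_normal_de <- function(expr, group_labels, genes) {
  v <- .expr_values(expr)
  stopifnot(length(group_labels) == ncol(v))
  if (!all(group_labels %in% c("tumor", "normal"))) {
    stop("group_labels must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (!any(group_labels == "tumor") || !any(group_labels == "normal")) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  missing_genes <- setdiff(genes, rownames(v))
  if (length(missing_genes)) {
    warning(sprintf("gene(s) absent from expression: %s",
                    paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  present <- intersect(genes, rownames(v))
  is_t <- group_labels == "tumor"
  rows <- lapply(present, function(g) {
    xt <- v[g, is_t]; xn <- v[g, !is_t]
    use_exact <- length(xt) <= 25L && length(xn) <= 25L &&
      !anyDuplicated(c(xt, xn))
    ht <- suppressWarnings(stats::wilcox.test(xt, xn, exact = use_exact,
                                              correct = TRUE))
    data.frame(gene = g, median_tumor = stats::median(xt),
               median_normal = stats::median(xn), p = ht$p.value)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$adj_p <- bh_adjust(out$p)
  out$stars <- p_stars(out$p)
  if (length(missing_genes)) {
    out <- rbind(out, data.frame(gene = missing_genes, median_tumor = NA_real_,
                                 median_normal = NA_real_, p = NA_real_,
                                 adj_p = NA_real_, stars = NA_character_))
  }
  out
}

#' Read a long-format CNV call table
#'
#' Columns `sample_id`, `gene_id`, `call`; calls must be `gain`, `loss`
#' or `neutral`, or numeric segment means which are discretized at
#' `+/- threshold`.
#'
#' @param path File path (TSV).
#' @param threshold Discretization threshold for numeric calls.
#' @return Data frame with factor-free character columns.
#' @export
read_cnv <- function(path, threshold = 0.2) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "call")
  if (!all(need %in% names(df))) {
    stop("CNV table needs columns sample_id, gene_id, call", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(df$call))
  if (!anyNA(num)) {
    df$call <- ifelse(num > threshold, "gain",
               ifelse(num < -threshold, "loss", "neutral"))
  }
  bad <- setdiff(unique(df$call), c("gain", "loss", "neutral"))
  if (length(bad)) {
    stop(sprintf("unknown CNV call value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("sample_id", "gene_id")])) {
    stop("multiple CNV calls for the same (sample, gene)", call. = FALSE)
  }
  df
}

#' Per-gene CNV gain/loss frequencies
#'
#' @param cnv CNV call table (see [read_cnv()]).
#' @param genes Genes to tabulate.
#' @return Data frame: `gene`, `gain_freq`, `loss_freq` (denominator:
#'   number of distinct samples in the table).
#' @export
cnv_frequency <- function(cnv, genes) {
  n <- length(unique(cnv$sample_id))
  if (n < 1L) stop("CNV table has no samples", call. = FALSE)
  bad <- setdiff(unique(cnv$call), c("gain", "loss", "neutral"))
  if (length(bad)) {
    stop(sprintf("unknown CNV call value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    sub <- cnv[cnv$gene_id == g, , drop = FALSE]
    data.frame(gene = g,
               gain_freq = sum(sub$call == "gain") / n,
               loss_freq = sum(sub$call == "loss") / n)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Mutation frequency over a gene panel
#'
#' @param mutations Mutation table (see [read_mutations()]).
#' @param genes Gene panel.
#' @param n_samples Cohort size (denominator; must be >= number of
#'   distinct mutated samples).
#' @return List: `overall_freq` (fraction of samples with at least one
#'   mutation in the panel) and `per_gene` (mutated-sample count and
#'   frequency per gene).
#' @export
mutation_frequency <- function(mutations, genes, n_samples) {
  if (n_samples <= 0) stop("n_samples must be positive", call. = FALSE)
  sub <- mutations[mutations$gene_id %in% genes, , drop = FALSE]
  mutated <- unique(sub$sample_id)
  if (length(mutated) > n_samples) {
    stop("more mutated samples than n_samples", call. = FALSE)
  }
  per_gene <- do.call(rbind, c(lapply(genes, function(g) {
    cnt <- length(unique(sub$sample_id[sub$gene_id == g]))
    data.frame(gene = g, n_mutated = cnt, freq = cnt / n_samples)
  }), list(make.row.names = FALSE)))
  list(overall_freq = length(mutated) / n_samples, per_gene = per_gene)
}

#' Prognostic coexpression network of regulator genes
#'
#' Edges connect gene pairs whose Spearman correlation clears
#' `|r| >= r_threshold` at `p <= p_threshold`; nodes carry a functional
#' role tag and a prognosis class from univariate Cox results (`risk`
#' when HR > 1 with p < 0.05, `protective` when HR < 1 with p < 0.05,
#' `ns` otherwise). Constant genes are excluded from edges with a
#' warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Regulator genes.
#' @param cox_results Data frame with columns `gene`, `HR`, `p_value`
#'   (e.g. from [prognostic_filter()]).
#' @param r_threshold,p_threshold Edge inclusion thresholds.
#' @param roles Optional data frame `gene`, `role`; defaults to
#'   [m6a_regulator_roles()].
#' @return A `regulator_network`: list with `nodes` and `edges` data
#'   frames.
#' @export
build_regulator_network <- function(expr, genes, cox_results,
                                    r_threshold = 0.3, p_threshold = 0.05,
                                    roles = NULL) {
  v <- .expr_values(expr)
  genes <- intersect(genes, rownames(v))
  if (length(genes) < 2L) stop("need at least two genes present",
                               call. = FALSE)
  if (is.null(roles)) roles <- m6a_regulator_roles()
  sub <- v[genes, , drop = FALSE]
  flat <- apply(sub, 1L, stats::var) == 0
  if (any(flat)) {
    warning(sprintf("constant gene(s) excluded from edges: %s",
                    paste(genes[flat], collapse = ", ")), call. = FALSE)
  }
  usable <- genes[!flat]
  edges <- list()
  if (length(usable) >= 2L) {
    combs <- utils::combn(usable, 2L, simplify = FALSE)
    edges <- lapply(combs, function(pr) {
      ct <- suppressWarnings(stats::cor.test(sub[pr[1L], ], sub[pr[2L], ],
                                             method = "spearman"))
      data.frame(gene_i = pr[1L], gene_j = pr[2L],
                 r = unname(ct$estimate), p = ct$p.value)
    })
    edges <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
    edges <- edges[abs(edges$r) >= r_threshold & edges$p <= p_threshold, ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_i = character(), gene_j = character(),
                        r = numeric(), p = numeric())
  }
  cox_idx <- match(genes, cox_results$gene)
  hr <- cox_results$HR[cox_idx]
  cp <- cox_results$p_value[cox_idx]
  prognosis <- ifelse(is.na(hr) | is.na(cp) | cp >= 0.05, "ns",
               ifelse(hr > 1, "risk", "protective"))
  nodes <- data.frame(gene = genes,
                      role = roles$role[match(genes, roles$gene)],
                      prognosis = prognosis)
  structure(list(nodes = nodes, edges = edges,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "regulator_network")
}

#' @export
print.regulator_network <- function(x, ...) {
  cat(sprintf("<regulator_network> %d nodes, %d edges (|r| >= %.2f, p <= %.2g)\n",
              nrow(x$nodes), nrow(x$edges), x$r_threshold, x$p_threshold))
  invisible(x)
}
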