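# Mutation burden, clinical-subgroup survival, immune-checkpoint gene
# differences and immunotherapy response-rate analysis.

# MAF-style variant classes counted as nonsynonymous by default.
NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Translation_Start_Site", "Nonstop_Mutation")

MAF_CLASSES <- c(NONSYNONYMOUS_CLASSES, "Silent", "Intron", "3'UTR", "5'UTR",
                 "3'Flank", "5'Flank", "IGR", "RNA", "Targeted_Region")

#' Read a mutation table
#'
#' Accepts a MAF file or a minimal 3-column TSV. Column aliases
#' `Tumor_Sample_Barcode`/`Hugo_Symbol`/`Variant_Classification` are
#' mapped to `sample_id`/`gene_id`/`variant_classification`. Rows are
#' deduplicated on (sample, gene, classification, position) when a
#' position column is present.
#'
#' @param path File path (TSV).
#' @return Data frame with at least `sample_id`, `gene_id`,
#'   `variant_classification`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  ren <- c(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene_id",
           Variant_Classification = "variant_classification")
  for (old in names(ren)) {
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  }
  need <- c("sample_id", "gene_id", "variant_classification")
  if (!all(need %in% names(df))) {
    stop("mutation table needs sample_id, gene_id, variant_classification",
         call. = FALSE)
  }
  key_cols <- intersect(c(need, "Start_Position", "position"), names(df))
  df <- df[!duplicated(df[, key_cols, drop = FALSE]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-sample tumor mutational burden
#'
#' Counts qualifying variants per sample (0 for samples without any);
#' `mode = "per_mb"` divides by the captured exome size in megabases.
#' Rows with a classification outside `classes` are excluded with a
#' warning when the classification is not a known MAF class.
#'
#' @param mutations Mutation table.
#' @param sample_ids All cohort samples (unmutated ones get TMB 0).
#' @param mode `"count"` or `"per_mb"`.
#' @param exome_mb Capture size for per-Mb mode.
#' @param classes Qualifying variant classes (default: nonsynonymous).
#' @return Named numeric vector of TMB values.
#' @export
compute_tmb <- function(mutations, sample_ids, mode = c("count", "per_mb"),
                        exome_mb = 38, classes = NONSYNONYMOUS_CLASSES) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(mutations$variant_classification), MAF_CLASSES)
  if (length(unknown)) {
    warning(sprintf("excluded rows with unknown classification(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  qual <- mutations[mutations$variant_classification %in% classes, ,
                    drop = FALSE]
  counts <- table(factor(qual$sample_id, levels = sample_ids))
  tmb <- stats::setNames(as.numeric(counts), sample_ids)
  if (mode == "per_mb") tmb <- tmb / exome_mb
  tmb
}

#' Top mutated genes per group
#'
#' Genes ranked by mutated-sample count within each group; ties at the
#' cut rank are all kept (alphabetical order stabilizes the listing).
#' Also reports each group's overall mutation rate (fraction of samples
#' with at least one qualifying mutation).
#'
#' @param mutations Mutation table.
#' @param groups Named group label per sample (names = sample ids; all
#'   cohort samples, mutated or not).
#' @param n Number of top genes per group.
#' @param classes Qualifying variant classes.
#' @return List: `per_gene` (data frame `group`, `gene`, `n_mutated`,
#'   `pct`), `overall_rate` (named vector of per-group rates).
#' @export
top_mutated_genes <- function(mutations, groups, n = 20L,
                              classes = NONSYNONYMOUS_CLASSES) {
  stopifnot(!is.null(names(groups)))
  qual <- mutations[mutations$variant_classification %in% classes &
                    mutations$sample_id %in% names(groups), , drop = FALSE]
  glev <- sort(unique(as.character(groups)))
  per_gene <- list()
  overall <- stats::setNames(numeric(length(glev)), glev)
  for (g in glev) {
    ids <- names(groups)[groups == g]
    sub <- qual[qual$sample_id %in% ids, , drop = FALSE]
    overall[g] <- length(unique(sub$sample_id)) / length(ids)
    if (!nrow(sub)) next
    cnt <- vapply(split(sub$sample_id, sub$gene_id),
                  function(s) length(unique(s)), integer(1))
    tab <- data.frame(group = g, gene = names(cnt), n_mutated = as.integer(cnt),
                      pct = 100 * as.integer(cnt) / length(ids))
    tab <- tab[order(-tab$n_mutated, tab$gene), , drop = FALSE]
    if (nrow(tab) > n) {
      cut_count <- tab$n_mutated[n]
      tab <- tab[tab$n_mutated >= cut_count, , drop = FALSE]
    }
    per_gene[[g]] <- tab
  }
  per_gene <- if (length(per_gene)) {
    do.call(rbind, c(per_gene, list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(), gene = character(),
               n_mutated = integer(), pct = numeric())
  }
  list(per_gene = per_gene, overall_rate = overall)
}

#' TMB survival stratification
#'
#' Dichotomizes TMB at the maximally-selected cutpoint, tests high vs
#' low TMB survival, and — when score groups are supplied — forms the
#' four TMB x score strata and runs the overall log-rank across them.
#' Empty strata are dropped from the test with a warning.
#'
#' @param tmb Named TMB vector.
#' @param clinical Clinical table.
#' @param score_group Optional named `"high"`/`"low"` score labels.
#' @param minprop Cutpoint search constraint.
#' @return List: `cutpoint`, `tmb_group`, `km` (per TMB group),
#'   `logrank_p`, and when score groups are given `strata`, `strata_km`,
#'   `strata_logrank_p`.
#' @export
tmb_survival <- function(tmb, clinical, score_group = NULL, minprop = 0.1) {
  clinical <- validate_clinical(clinical)
  ids <- intersect(names(tmb), clinical$sample_id)
  if (!length(ids)) stop("no samples shared between TMB and clinical",
                         call. = FALSE)
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  tv <- tmb[ids]
  cp <- optimal_cutpoint(cl$os_time, cl$os_event, unname(tv),
                         minprop = minprop)
  tmb_group <- stats::setNames(ifelse(tv > cp$cutpoint, "H-TMB", "L-TMB"), ids)
  km <- lapply(split(seq_along(ids), tmb_group), function(i)
    km_estimate(cl$os_time[i], cl$os_event[i]))
  lr <- logrank_test(cl$os_time, cl$os_event, tmb_group)
  out <- list(cutpoint = cp$cutpoint, tmb_group = tmb_group, km = km,
              logrank_p = lr$p)
  if (!is.null(score_group)) {
    sg <- score_group[ids]
    strata <- stats::setNames(
      paste(tmb_group, ifelse(sg == "high", "H-score", "L-score"), sep = "+"),
      ids)
    tab <- table(strata)
    usable <- names(tab)[tab > 0]
    expected4 <- as.vector(outer(c("H-TMB", "L-TMB"),
                                 c("H-score", "L-score"), paste, sep = "+"))
    if (length(setdiff(expected4, usable))) {
      warning(sprintf("empty stratum(s): %s; tested on %d strata",
                      paste(setdiff(expected4, usable), collapse = ", "),
                      length(usable)), call. = FALSE)
    }
    keep <- strata %in% usable
    out$strata <- strata
    out$strata_km <- lapply(split(which(keep), strata[keep]), function(i)
      km_estimate(cl$os_time[i], cl$os_event[i]))
    out$strata_logrank_p <-
      logrank_test(cl$os_time[keep], cl$os_event[keep], strata[keep])$p
  }
  out
}

#' Survival of score groups within clinical subgroups
#'
#' Within each level of a clinical column (e.g. age dichotomized at 65,
#' or sex), compares high vs low score survival by Kaplan-Meier +
#' log-rank. Levels with fewer than 2 samples per score group are
#' skipped with a message.
#'
#' @param clinical Clinical table.
#' @param score_group Named `"high"`/`"low"` labels.
#' @param subgroup_col Clinical column name to stratify on.
#' @return Named list per subgroup level: `km` (per score group),
#'   `logrank_p`, `n`.
#' @export
subgroup_survival <- function(clinical, score_group, subgroup_col) {
  clinical <- validate_clinical(clinical)
  if (!subgroup_col %in% names(clinical)) {
    stop(sprintf("clinical table has no column '%s'", subgroup_col),
         call. = FALSE)
  }
  ids <- intersect(names(score_group), clinical$sample_id)
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  sg <- score_group[ids]
  out <- list()
  for (lev in sort(unique(as.character(cl[[subgroup_col]])))) {
    i <- which(cl[[subgroup_col]] == lev)
    tab <- table(sg[i])
    if (length(tab) < 2L || any(tab < 2L)) {
      message(sprintf("subgroup '%s' skipped (needs >= 2 samples per group)",
                      lev))
      next
    }
    km <- lapply(split(i, sg[i]), function(ii)
      km_estimate(cl$os_time[ii], cl$os_event[ii]))
    lr <- logrank_test(cl$os_time[i], cl$os_event[i], sg[i])
    out[[lev]] <- list(km = km, logrank_p = lr$p, n = length(i))
  }
  out
}

#' Immune-checkpoint gene expression differences between score groups
#'
#' Two-sided Wilcoxon rank-sum per gene between the high and low score
#' groups. Absent genes are reported as NA rows with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param score_group Named `"high"`/`"low"` labels.
#' @param icb_genes Genes to test (default the checkpoint trio
#'   PDCD1 / CD274 / CTLA4).
#' @return Data frame: `gene`, `median_high`, `median_low`, `p`, `stars`.
#' @export
icb_gene_diff <- function(expr, score_group,
                          icb_genes = c("PDCD1", "CD274", "CTLA4")) {
  v <- .expr_values(expr)
  ids <- intersect(names(score_group), colnames(v))
  sg <- score_group[ids]
  missing_genes <- setdiff(icb_genes, rownames(v))
  if (length(missing_genes)) {
    warning(sprintf("ICB gene(s) absent from expression: %s",
                    paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(icb_genes, function(g) {
    if (!g %in% rownames(v)) {
      return(data.frame(gene = g, median_high = NA_real_,
                        median_low = NA_real_, p = NA_real_,
                        stars = NA_character_))
    }
    xh <- v[g, ids[sg == "high"]]; xl <- v[g, ids[sg == "low"]]
    ht <- suppressWarnings(stats::wilcox.test(xh, xl, exact = FALSE,
                                              correct = TRUE))
    data.frame(gene = g, median_high = stats::median(xh),
               median_low = stats::median(xl), p = ht$p.value,
               stars = p_stars(ht$p.value))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Immunotherapy response-rate analysis of score groups
#'
#' Responders are CR or PR. Builds the 2x2 responder-by-group table,
#' reports per-group responder percentages and the CR/PR/SD/PD
#' composition, the sample odds ratio `(a*d)/(b*c)` (Haldane-Anscombe
#' 0.5 correction when a cell is zero, flagged), and the two-sided
#' Fisher exact p-value.
#'
#' @param responses Data frame `sample_id`, `response` (CR/PR/SD/PD).
#' @param score_group Named `"high"`/`"low"` labels.
#' @return List: `table` (2x2), `odds_ratio`, `or_corrected` flag,
#'   `fisher_p`, `responder_pct` (per group), `composition` (per-group
#'   4-level percentages).
#' @export
response_rate_analysis <- function(responses, score_group) {
  stopifnot(all(c("sample_id", "response") %in% names(responses)))
  if (anyDuplicated(responses$sample_id)) {
    stop("response table has duplicated sample ids", call. = FALSE)
  }
  if (!all(responses$response %in% c("CR", "PR", "SD", "PD"))) {
    stop("responses must be CR, PR, SD or PD", call. = FALSE)
  }
  ids <- intersect(responses$sample_id, names(score_group))
  resp <- responses[match(ids, responses$sample_id), , drop = FALSE]
  sg <- factor(score_group[ids], levels = c("high", "low"))
  if (any(table(sg) == 0)) stop("need at least 1 sample per score group",
                                call. = FALSE)
  responder <- factor(resp$response %in% c("CR", "PR"),
                      levels = c(TRUE, FALSE),
                      labels = c("responder", "non_responder"))
  tab <- table(sg, responder)
  a <- tab["high", "responder"]; b <- tab["high", "non_responder"]
  c_ <- tab["low", "responder"]; d <- tab["low", "non_responder"]
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  fp <- stats::fisher.test(tab)$p.value
  responder_pct <- 100 * c(high = a / (a + b), low = c_ / (c_ + d))
  comp <- t(vapply(levels(sg), function(g) {
    r <- resp$response[sg == g]
    100 * vapply(c("CR", "PR", "SD", "PD"), function(l) mean(r == l),
                 numeric(1))
  }, numeric(4)))
  list(table = tab, odds_ratio = unname(or), or_corrected = corrected,
       fisher_p = fp, responder_pct = responder_pct, composition = comp)
}
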