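# End-to-end orchestration: preprocess -> regulator landscape ->
# consensus subtypes -> enrichment/deconvolution by subtype -> phenotype
# DEGs -> prognostic filter -> gene clusters -> m6A score ->
# dichotomization -> immune correlation -> mutation/subgroup/checkpoint
# analyses. Every stage writes plain TSV tables into the output
# directory and the run ends with a JSON manifest of file checksums.

.default_config <- list(
  seed = 1L,
  k_range = 2:6,
  reps = 1000L,
  p_item = 0.8,
  base = "hierarchical_pearson",
  alpha_deg = 0.05,
  deg_rule = "intersection",
  alpha_prognostic = 0.05,
  prognostic_rule = "or",
  prognostic_split = "median",
  score_genes = "prognostic",     # or "deg": run PCA on the full DEG set
  minprop = 0.1,
  nu_grid = c(0.25, 0.5, 0.75),
  n_perm = 100L,
  icb_genes = c("PDCD1", "CD274", "CTLA4"),
  subgroups = c("age_group", "sex"),
  immune_gene_sets = NULL,        # path to a GMT; NULL = packaged synthetic
  pathway_gene_sets = NULL,       # path to a GMT; NULL = skip GSVA
  signature_matrix = NULL,        # path to a TSV; NULL = skip deconvolution
  synthetic = NULL                # list of generate_cohort() overrides
)

#' Default pipeline configuration
#'
#' @return Named list of all configuration keys with their defaults.
#' @export
default_config <- function() .default_config

#' Run the full subtyping-and-scoring pipeline
#'
#' @param config Named list overriding entries of [default_config()], or
#'   a path to a YAML file with such entries. Unknown keys are rejected.
#' @param cohort A [cohort_bundle()] to analyze; when `NULL`, a synthetic
#'   cohort is generated from `config$synthetic` (or the generator
#'   defaults) with the pipeline seed.
#' @param out_dir Output directory (created if needed).
#' @param icb Optional list with elements `cohort` (a bundle) and
#'   `responses` for the checkpoint-therapy validation stage; when
#'   `NULL` and the main cohort is synthetic, a synthetic checkpoint
#'   cohort is generated.
#' @return Invisibly, a list of all stage results plus `manifest` (output
#'   file checksums) and `out_dir`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL,
                         out_dir = tempfile("m6atme_run_"), icb = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(.default_config))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(.default_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[m6aTME] ", msg)
  }

  synthetic_run <- is.null(cohort)
  if (synthetic_run) {
    say("generating synthetic cohort (seed %d)", cfg$seed)
    gen_args <- c(cfg$synthetic, list(seed = cfg$seed))
    gen_args <- gen_args[!duplicated(names(gen_args))]
    gen <- do.call(generate_cohort, gen_args)
    cohort <- gen$cohort
  }
  expr <- cohort$expression
  clinical <- cohort$clinical
  results <- list(config = cfg)

  regs <- intersect(m6a_regulators(resolve_aliases = TRUE), rownames(expr))
  if (length(regs) < 5L) {
    stop("fewer than 5 regulator genes present in the expression matrix",
         call. = FALSE)
  }

  # --- regulator landscape -------------------------------------------------
  reg_cox <- prognostic_filter(expr, clinical, genes = regs,
                               alpha = cfg$alpha_prognostic,
                               rule = cfg$prognostic_rule,
                               split = cfg$prognostic_split)
  utils::write.table(reg_cox, file.path(out_dir, "regulator_prognostic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  network <- build_regulator_network(expr, regs, reg_cox)
  utils::write.table(network$edges, file.path(out_dir, "regulator_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$nodes, file.path(out_dir, "regulator_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$landscape <- list(cox = reg_cox, network = network)
  if (!is.null(cohort$cnv)) {
    cf <- cnv_frequency(cohort$cnv, regs)
    utils::write.table(cf, file.path(out_dir, "regulator_cnv_freq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$landscape$cnv_freq <- cf
  }
  if (!is.null(cohort$mutations)) {
    mf <- mutation_frequency(cohort$mutations, regs, ncol(expr))
    utils::write.table(mf$per_gene,
                       file.path(out_dir, "regulator_mutation_freq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$landscape$mutation_freq <- mf
    say("regulator mutation frequency: %.2f%%", 100 * mf$overall_freq)
  }

  # --- consensus subtypes on the regulators --------------------------------
  say("consensus clustering %d samples on %d regulators (reps = %d)",
      ncol(expr), length(regs), cfg$reps)
  cc <- consensus_cluster(expr[regs, , drop = FALSE], k_range = cfg$k_range,
                          reps = cfg$reps, p_item = cfg$p_item,
                          base = cfg$base,
                          seed = derive_seed(cfg$seed, 10L))
  m6a_cluster <- stats::setNames(
    LETTERS[consensus_labels(cc)], cc$sample_ids)
  say("selected K = %d for the regulator clusters", cc$selected_k)
  utils::write.table(
    data.frame(sample_id = cc$sample_ids, k = cc$selected_k,
               cluster = unname(m6a_cluster)),
    file.path(out_dir, "m6a_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(k = cc$k_range, auc = unname(cc$auc),
               delta_area = unname(cc$delta_area)),
    file.path(out_dir, "m6a_cluster_delta_area.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  pca <- pca_embed(expr[regs, , drop = FALSE])
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), pca$scores,
               cluster = unname(m6a_cluster)),
    file.path(out_dir, "m6a_cluster_pca.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  results$m6a_clusters <- cc
  results$m6a_cluster_labels <- m6a_cluster

  # --- enrichment and deconvolution by subtype -----------------------------
  immune_sets <- if (is.null(cfg$immune_gene_sets)) {
    immune_signatures_synthetic()
  } else read_gmt(cfg$immune_gene_sets)
  immune_sets <- suppressMessages(
    tryCatch(.match_sets(immune_sets, rownames(expr)), error = function(e) NULL))
  if (!is.null(immune_sets)) {
    ssg <- ssgsea_score(expr, immune_sets)
    utils::write.table(cbind(set = rownames(ssg), as.data.frame(unclass(ssg))),
                       file.path(out_dir, "ssgsea_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp <- compare_scores_by_group(ssg, m6a_cluster[colnames(ssg)])
    utils::write.table(cmp, file.path(out_dir, "ssgsea_by_cluster.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$ssgsea <- ssg
    results$ssgsea_by_cluster <- cmp
  } else {
    say("skipping ssGSEA: no immune gene set overlaps the matrix")
  }
  if (!is.null(cfg$pathway_gene_sets)) {
    paths <- read_gmt(cfg$pathway_gene_sets)
    gsva <- gsva_score(expr, paths)
    utils::write.table(cbind(set = rownames(gsva),
                             as.data.frame(unclass(gsva))),
                       file.path(out_dir, "gsva_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$gsva <- gsva
  } else {
    say("skipping GSVA: no pathway gene sets configured")
  }
  if (!is.null(cfg$signature_matrix)) {
    sig <- as.matrix(utils::read.table(cfg$signature_matrix, header = TRUE,
                                       sep = "\t", row.names = 1L,
                                       check.names = FALSE))
    dec <- svr_deconvolve(expr, sig, nu_grid = cfg$nu_grid,
                          n_perm = cfg$n_perm,
                          seed = derive_seed(cfg$seed, 11L))
    utils::write.table(
      data.frame(sample_id = rownames(dec$fractions), dec$fractions,
                 p = dec$p, rmse = dec$rmse, r = dec$r, check.names = FALSE),
      file.path(out_dir, "cibersort_fractions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$deconvolution <- dec
  } else {
    say("skipping deconvolution: no signature matrix configured")
  }

  # --- phenotype DEGs ------------------------------------------------------
  de <- pairwise_moderated_t(expr, m6a_cluster[colnames(expr)])
  for (nm in names(de)) {
    utils::write.table(de[[nm]],
                       file.path(out_dir, sprintf("de_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  degs <- phenotype_degs(de, alpha = cfg$alpha_deg, rule = cfg$deg_rule)
  degs <- setdiff(degs, regs)    # phenotype genes, not the regulators
  writeLines(degs, file.path(out_dir, "phenotype_degs.txt"))
  say("%d phenotype DEGs at adj. p < %g (%s rule)",
      length(degs), cfg$alpha_deg, cfg$deg_rule)
  results$de <- de
  results$degs <- degs
  if (length(degs) < 2L) stop("fewer than 2 phenotype DEGs; cannot score",
                              call. = FALSE)

  # --- prognostic filter and gene clusters ---------------------------------
  prog <- prognostic_filter(expr, clinical, genes = degs,
                            alpha = cfg$alpha_prognostic,
                            rule = cfg$prognostic_rule,
                            split = cfg$prognostic_split)
  utils::write.table(prog, file.path(out_dir, "prognostic_degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prog_genes <- prog$gene[prog$keep]
  say("%d prognostic phenotype genes", length(prog_genes))
  results$prognostic <- prog

  gene_cc <- consensus_cluster(expr[degs, , drop = FALSE],
                               k_range = cfg$k_range, reps = cfg$reps,
                               p_item = cfg$p_item, base = cfg$base,
                               seed = derive_seed(cfg$seed, 12L))
  gene_cluster <- stats::setNames(
    paste0("geneCluster", LETTERS[consensus_labels(gene_cc)]),
    gene_cc$sample_ids)
  utils::write.table(
    data.frame(sample_id = gene_cc$sample_ids, k = gene_cc$selected_k,
               cluster = unname(gene_cluster)),
    file.path(out_dir, "gene_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  results$gene_clusters <- gene_cc
  results$gene_cluster_labels <- gene_cluster

  # --- m6A score -----------------------------------------------------------
  score_genes <- if (cfg$score_genes == "deg" || length(prog_genes) < 2L) {
    if (length(prog_genes) < 2L) {
      say("fewer than 2 prognostic genes; scoring on the full DEG set")
    }
    degs
  } else prog_genes
  sc <- compute_score(expr, score_genes)
  sc <- dichotomize_score(sc, clinical, minprop = cfg$minprop)
  say("m6A score cutpoint %.4g: %d high / %d low", sc$cutpoint,
      sum(sc$group == "high"), sum(sc$group == "low"))
  utils::write.table(as.data.frame(sc),
                     file.path(out_dir, "m6a_score.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(sc$loadings), sc$loadings,
               set = ifelse(rownames(sc$loadings) %in% sc$partition$A,
                            "A", "B")),
    file.path(out_dir, "m6a_score_loadings.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  score_group <- stats::setNames(sc$group, sc$sample_id)
  lr_os <- logrank_test(clinical$os_time, clinical$os_event,
                        score_group[clinical$sample_id])
  say("OS log-rank high vs low score: p = %.3g", lr_os$p)
  results$score <- sc
  results$score_logrank_os_p <- lr_os$p
  if (all(c("pfs_time", "pfs_event") %in% names(clinical))) {
    results$score_logrank_pfs_p <-
      logrank_test(clinical$pfs_time, clinical$pfs_event,
                   score_group[clinical$sample_id])$p
  }

  st <- sankey_table(sc, m6a_cluster, gene_cluster, clinical)
  utils::write.table(st, file.path(out_dir, "sankey_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$sankey <- st

  if (!is.null(results$ssgsea)) {
    ic <- correlate_immune(sc, results$ssgsea)
    utils::write.table(ic, file.path(out_dir, "score_immune_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$immune_correlation <- ic
  }

  # --- mutation burden and clinical subgroups ------------------------------
  if (!is.null(cohort$mutations)) {
    tmb <- compute_tmb(cohort$mutations, clinical$sample_id)
    utils::write.table(data.frame(sample_id = names(tmb), tmb = unname(tmb)),
                       file.path(out_dir, "tmb.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- top_mutated_genes(cohort$mutations, score_group)
    utils::write.table(top$per_gene,
                       file.path(out_dir, "top_mutated_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("overall mutation rate: high %.2f%%, low %.2f%%",
        100 * top$overall_rate["high"], 100 * top$overall_rate["low"])
    ts <- tmb_survival(tmb, clinical, score_group, minprop = cfg$minprop)
    say("TMB x score 4-group log-rank: p = %.3g", ts$strata_logrank_p)
    utils::write.table(
      data.frame(sample_id = names(ts$strata), stratum = unname(ts$strata)),
      file.path(out_dir, "tmb_score_strata.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$tmb <- tmb
    results$top_mutated <- top
    results$tmb_survival <- ts
  } else {
    say("skipping mutation analyses: no mutation table")
  }
  sub_results <- list()
  for (col in intersect(cfg$subgroups, names(clinical))) {
    sub_results[[col]] <- subgroup_survival(clinical, score_group, col)
  }
  if (length(sub_results)) {
    sub_tab <- do.call(rbind, c(unlist(lapply(names(sub_results), function(col)
      lapply(names(sub_results[[col]]), function(lev)
        data.frame(subgroup = col, level = lev,
                   n = sub_results[[col]][[lev]]$n,
                   logrank_p = sub_results[[col]][[lev]]$logrank_p))),
      recursive = FALSE), list(make.row.names = FALSE)))
    utils::write.table(sub_tab, file.path(out_dir, "subgroup_survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$subgroup_survival <- sub_results
  }
  icb_tab <- icb_gene_diff(expr, score_group, cfg$icb_genes)
  utils::write.table(icb_tab, file.path(out_dir, "icb_gene_diff.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$icb_gene_diff <- icb_tab

  # --- checkpoint-therapy validation cohort --------------------------------
  if (is.null(icb) && synthetic_run) {
    icb_gen <- generate_icb_cohort(seed = derive_seed(cfg$seed, 13L))
    icb <- list(cohort = icb_gen$cohort, responses = icb_gen$responses)
  }
  if (!is.null(icb)) {
    icb_expr <- icb$cohort$expression
    icb_sc <- compute_score(icb_expr, intersect(score_genes,
                                                rownames(icb_expr)))
    icb_sc <- tryCatch(
      dichotomize_score(icb_sc, icb$cohort$clinical, minprop = cfg$minprop),
      error = function(e) {
        med <- stats::median(icb_sc$score)
        icb_sc$cutpoint <- med
        icb_sc$group <- ifelse(icb_sc$score > med, "high", "low")
        icb_sc
      })
    rra <- response_rate_analysis(icb$responses,
                                  stats::setNames(icb_sc$group,
                                                  icb_sc$sample_id))
    say("checkpoint response rate: high %.0f%%, low %.0f%% (OR %.2f, p %.3g)",
        rra$responder_pct["high"], rra$responder_pct["low"],
        rra$odds_ratio, rra$fisher_p)
    utils::write.table(
      data.frame(group = rownames(rra$composition), rra$composition,
                 responder_pct = rra$responder_pct[rownames(rra$composition)]),
      file.path(out_dir, "icb_response_rates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$icb_response <- rra
  } else {
    say("skipping checkpoint-response stage: no ICB cohort")
  }

  # --- manifest ------------------------------------------------------------
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  yaml::write_yaml(
    lapply(cfg, function(x) if (is.null(x)) NA else x),
    file.path(out_dir, "resolved_config.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
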