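test_that("TMB counts qualifying variants with sensible defaults", {
  ids <- sprintf("s%d", 1:4)
  mut <- data.frame(
    sample_id = c(rep("s1", 9), "s2", "s2", "s3"),
    gene_id = sprintf("g%d", 1:12),
    variant_classification = c(rep("Missense_Mutation", 5),
                               rep("Nonsense_Mutation", 2), "Silent",
                               "Silent", "Missense_Mutation", "Splice_Site",
                               "Intron"))
  tmb <- compute_tmb(mut, ids)
  expect_equal(unname(tmb), c(7, 2, 0, 0))     # silent/intron excluded
  expect_equal(unname(compute_tmb(mut, ids, mode = "per_mb")[1]), 7 / 38)
  expect_equal(unname(compute_tmb(mut[0, ], ids)), rep(0, 4))

  expect_warning(compute_tmb(transform(mut, variant_classification = "Odd"),
                             ids), "unknown")

  # additivity over disjoint partitions of the table
  half1 <- mut[1:6, ]; half2 <- mut[7:12, ]
  expect_equal(compute_tmb(half1, ids) + compute_tmb(half2, ids), tmb)
})

test_that("top mutated genes rank within groups with a stable tie rule", {
  groups <- stats::setNames(rep(c("high", "low"), each = 4),
                            sprintf("s%d", 1:8))
  mut <- data.frame(
    sample_id = c("s1", "s2", "s3", "s1", "s2", "s1", "s5", "s6"),
    gene_id = c("ga", "ga", "ga", "gb", "gb", "gc", "gz", "gz"),
    variant_classification = "Missense_Mutation")
  top <- top_mutated_genes(mut, groups, n = 2)
  hi <- top$per_gene[top$per_gene$group == "high", ]
  expect_identical(hi$gene, c("ga", "gb"))
  expect_equal(top$overall_rate[["high"]], 3 / 4)
  expect_equal(top$overall_rate[["low"]], 2 / 4)

  # tie at the cut rank keeps both, alphabetically ordered
  mut_tie <- rbind(mut, data.frame(sample_id = "s2", gene_id = "gc",
                                   variant_classification =
                                     "Missense_Mutation"))
  top2 <- top_mutated_genes(mut_tie, groups, n = 2)
  hi2 <- top2$per_gene[top2$per_gene$group == "high", ]
  expect_identical(hi2$gene, c("ga", "gb", "gc"))   # gb/gc tied at rank 2

  # n larger than the distinct gene count returns everything
  top3 <- top_mutated_genes(mut, groups, n = 50)
  expect_identical(sort(unique(top3$per_gene$gene)),
                   c("ga", "gb", "gc", "gz"))

  # against an independent group-by count on random data
  set.seed(31)
  big <- data.frame(sample_id = sample(names(groups), 60, replace = TRUE),
                    gene_id = sample(sprintf("g%d", 1:6), 60, replace = TRUE),
                    variant_classification = "Missense_Mutation")
  top4 <- top_mutated_genes(big, groups, n = 100)
  for (i in seq_len(nrow(top4$per_gene))) {
    row <- top4$per_gene[i, ]
    ids_g <- names(groups)[groups == row$group]
    expect_equal(row$n_mutated,
                 length(unique(big$sample_id[big$gene_id == row$gene &
                                             big$sample_id %in% ids_g])))
  }
})

test_that("TMB survival stratification orders planted strata", {
  g <- generate_cohort(n_samples = 200, n_genes = 200, n_deg = 40, seed = 55)
  cl <- g$cohort$clinical
  tmb <- compute_tmb(g$cohort$mutations, cl$sample_id)
  score_group <- stats::setNames(
    ifelse(g$truth$score > stats::median(g$truth$score), "high", "low"),
    names(g$truth$score))
  ts <- tmb_survival(tmb, cl, score_group)
  expect_true(all(c("H-TMB+H-score", "L-TMB+L-score") %in%
                  names(ts$strata_km)))
  tmid <- stats::median(cl$os_time)
  s_at <- vapply(ts$strata_km, km_surv_at, numeric(1), t = tmid)
  # hazard decreases in both TMB and score: HH best, LL worst
  expect_gt(s_at[["H-TMB+H-score"]], s_at[["L-TMB+L-score"]])
  expect_identical(names(which.max(s_at)), "H-TMB+H-score")

  # an empty stratum drops to a 3-group test with a warning
  sg2 <- score_group
  sg2[ts$tmb_group == "H-TMB"] <- "high"     # no H-TMB+L-score stratum
  expect_warning(ts2 <- tmb_survival(tmb, cl, sg2), "empty stratum")
  expect_identical(length(ts2$strata_km), 3L)
})

test_that("TMB independent of survival gives calibrated log-rank p", {
  set.seed(808)
  ps <- vapply(1:30, function(i) {
    s <- sim_surv(80)
    cl <- data.frame(sample_id = sprintf("s%02d", 1:80),
                     os_time = s$time, os_event = s$event)
    tmb <- stats::setNames(stats::rnbinom(80, size = 5, mu = 30),
                           cl$sample_id)
    tmb_survival(tmb, cl)$logrank_p
  }, numeric(1))
  # maximally selected statistics are anti-conservative by construction
  # when referred to the chi-square; here we only require that the split
  # is not always "significant" under the null
  expect_lt(mean(ps < 0.05), 0.8)
  expect_gt(stats::median(ps), 0.001)
})

test_that("subgroup survival isolates a stratum-specific effect", {
  set.seed(99)
  power_young <- 0; reject_old <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    n <- 200
    age_group <- rep(c("<=65", ">65"), each = n / 2)
    score_group <- stats::setNames(
      sample(rep(c("high", "low"), n / 2)), sprintf("s%03d", 1:n))
    young_high <- age_group == "<=65" &
      score_group[sprintf("s%03d", 1:n)] == "high"
    rate <- ifelse(young_high, 0.025, 0.06)
    t_ev <- stats::rexp(n, rate)
    cl <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     os_time = pmax(t_ev, 1e-3), os_event = rep(1, n),
                     age_group = age_group)
    res <- subgroup_survival(cl, score_group, "age_group")
    power_young <- power_young + (res[["<=65"]]$logrank_p < 0.05)
    reject_old <- reject_old + (res[[">65"]]$logrank_p < 0.05)
  }
  expect_gte(power_young / n_rep, 0.8)
  expect_lte(reject_old / n_rep, 0.25)

  # identical survival in both groups within a subgroup: p near 1
  t <- rep(c(3, 6, 9, 12), 2)
  cl2 <- data.frame(sample_id = sprintf("s%d", 1:8),
                    os_time = t, os_event = rep(1, 8),
                    sex = rep("f", 8))
  sg <- stats::setNames(rep(c("high", "low"), each = 4), cl2$sample_id)
  res2 <- subgroup_survival(cl2, sg, "sex")
  expect_gt(res2$f$logrank_p, 0.9)

  expect_error(subgroup_survival(cl2, sg, "nope"), "no column")
})

test_that("checkpoint gene differences are detected with planted shifts", {
  # identical groups: p = 1
  v <- matrix(rep(1:10, 2), 1, 20,
              dimnames = list("PDCD1", sprintf("s%02d", 1:20)))
  sg <- stats::setNames(rep(c("high", "low"), each = 10), colnames(v))
  tab <- icb_gene_diff(expr_matrix(v + 0, unit = "LOG2"), sg, "PDCD1")
  expect_gt(tab$p, 0.9)

  # planted 1.5 SD upshift in the high group, n = 60 per group
  set.seed(12)
  hits <- vapply(1:20, function(i) {
    x <- c(stats::rnorm(60, 1.5), stats::rnorm(60))
    vv <- matrix(x, 1, 120,
                 dimnames = list("PDCD1", sprintf("s%03d", 1:120)))
    sg2 <- stats::setNames(rep(c("high", "low"), each = 60), colnames(vv))
    icb_gene_diff(expr_matrix(vv, unit = "LOG2"), sg2, "PDCD1")$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_warning(tab2 <- icb_gene_diff(expr_matrix(v + 0, unit = "LOG2"),
                                       sg, c("PDCD1", "CTLA4")),
                 "absent")
  expect_true(is.na(tab2$p[tab2$gene == "CTLA4"]))
})

test_that("response-rate analysis reproduces the hand odds ratio and Fisher p", {
  mk <- function(a, b, c_, d) {
    n <- a + b + c_ + d
    data.frame(
      sample_id = sprintf("s%03d", 1:n),
      response = c(rep("CR", a), rep("PD", b), rep("PR", c_), rep("SD", d)))
  }
  resp <- mk(12, 8, 4, 16)
  sg <- stats::setNames(rep(c("high", "low"), c(20, 20)), resp$sample_id)
  rra <- response_rate_analysis(resp, sg)
  expect_equal(rra$odds_ratio, 6.0)
  expect_false(rra$or_corrected)
  expect_equal(rra$fisher_p, oracle_fisher_p(12, 8, 4, 16), tolerance = 1e-12)
  expect_equal(unname(rra$responder_pct), c(60, 20))
  expect_equal(unname(rowSums(rra$composition)), c(100, 100),
               tolerance = 0.1)

  # identical composition in both groups: OR = 1, p = 1
  resp2 <- data.frame(sample_id = sprintf("t%02d", 1:20),
                      response = rep(c("CR", "PD", "SD", "PR", "PD"), 4))
  sg2 <- stats::setNames(rep(c("high", "low"), each = 10), resp2$sample_id)
  rra2 <- response_rate_analysis(resp2, sg2)
  expect_equal(rra2$odds_ratio, 1)
  expect_equal(rra2$fisher_p, 1)

  # zero cell: Haldane-Anscombe correction flagged
  resp3 <- data.frame(sample_id = sprintf("u%02d", 1:10),
                      response = c(rep("CR", 5), rep("PD", 5)))
  sg3 <- stats::setNames(rep(c("high", "low"), each = 5), resp3$sample_id)
  rra3 <- response_rate_analysis(resp3, sg3)
  expect_true(rra3$or_corrected)
  expect_true(is.finite(rra3$odds_ratio))

  # Fisher p equals the enumeration oracle across many margins (n <= 40)
  set.seed(17)
  for (i in 1:25) {
    tot <- sample(8:40, 1)
    a <- sample(0:tot, 1); rest <- tot - a
    b <- sample(0:rest, 1); rest <- rest - b
    c_ <- sample(0:rest, 1); d <- rest - c_
    if (a + b == 0 || c_ + d == 0) next
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    expect_equal(ft$p.value, oracle_fisher_p(a, b, c_, d), tolerance = 1e-9)
  }
})
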