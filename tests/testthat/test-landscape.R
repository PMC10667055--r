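test_that("tumor-vs-normal testing handles nulls, exact p and missing genes", {
  # identical values under both labels: p = 1
  v <- matrix(rep(1:6, 2), 1, 12, dimnames = list("g1", sprintf("s%02d", 1:12)))
  tab <- tumor_vs_normal_de(expr_matrix(v + 0, unit = "LOG2"),
                            rep(c("tumor", "normal"), each = 6), "g1")
  expect_equal(tab$p, 1)

  # {1,2,3} vs {10,11,12}: exact two-sided rank-sum p = 0.1
  v2 <- matrix(c(10, 11, 12, 1, 2, 3), 1, 6,
               dimnames = list("g1", sprintf("s%d", 1:6)))
  tab2 <- tumor_vs_normal_de(expr_matrix(v2, unit = "LOG2"),
                             rep(c("tumor", "normal"), each = 3), "g1")
  expect_equal(tab2$p, 0.1)

  # absent gene: NA row with warning
  expect_warning(
    tab3 <- tumor_vs_normal_de(expr_matrix(v2, unit = "LOG2"),
                               rep(c("tumor", "normal"), each = 3),
                               c("g1", "ghost")),
    "absent")
  expect_true(is.na(tab3$p[tab3$gene == "ghost"]))

  # simulated null over 1000 genes: rejection near nominal
  set.seed(70)
  vn <- matrix(stats::rnorm(1000 * 40), 1000, 40,
               dimnames = list(sprintf("g%04d", 1:1000),
                               sprintf("s%02d", 1:40)))
  tabn <- tumor_vs_normal_de(expr_matrix(vn, unit = "LOG2"),
                             rep(c("tumor", "normal"), each = 20),
                             rownames(vn))
  expect_gte(mean(tabn$p < 0.05), 0.03)
  expect_lte(mean(tabn$p < 0.05), 0.07)
})

test_that("CNV frequencies count gains and losses per sample", {
  cnv <- data.frame(
    sample_id = rep(sprintf("s%02d", 1:10), each = 1),
    gene_id = "g1",
    call = c(rep("gain", 3), rep("loss", 2), rep("neutral", 5)))
  tab <- cnv_frequency(cnv, "g1")
  expect_equal(tab$gain_freq, 0.3)
  expect_equal(tab$loss_freq, 0.2)

  # all-neutral: zeros; frequencies bounded
  cnv0 <- transform(cnv, call = "neutral")
  tab0 <- cnv_frequency(cnv0, "g1")
  expect_equal(tab0$gain_freq + tab0$loss_freq, 0)

  # random table against an independent group-by count
  set.seed(12)
  genes <- sprintf("g%d", 1:5)
  big <- expand.grid(sample_id = sprintf("s%02d", 1:30), gene_id = genes,
                     stringsAsFactors = FALSE)
  big$call <- sample(c("gain", "loss", "neutral"), nrow(big), replace = TRUE)
  tabr <- cnv_frequency(big, genes)
  for (g in genes) {
    expect_equal(tabr$gain_freq[tabr$gene == g],
                 sum(big$call == "gain" & big$gene_id == g) / 30)
  }
  expect_true(all(tabr$gain_freq + tabr$loss_freq <= 1))

  expect_error(cnv_frequency(transform(cnv, call = "weird"), "g1"), "unknown")
})

test_that("mutation frequency matches hand counts", {
  mut <- data.frame(
    sample_id = c("a", "a", "b", "c", "c", "c", "d", "a", "b", "e", "e", "f"),
    gene_id = c("g1", "g2", "g1", "g1", "g3", "g3", "g9", "g1", "g9", "g9",
                "g1", "g9"),
    variant_classification = "Missense_Mutation")
  # panel {g1, g2, g3}: distinct mutated samples a, b, c, e = 4 of 50
  mf <- mutation_frequency(mut, c("g1", "g2", "g3"), 50)
  expect_equal(mf$overall_freq, 0.08)
  expect_equal(mf$per_gene$n_mutated[mf$per_gene$gene == "g1"], 4L)

  # the arithmetic behind a 10-of-237 cohort
  mut10 <- data.frame(sample_id = sprintf("m%02d", 1:10), gene_id = "g1",
                      variant_classification = "Missense_Mutation")
  expect_equal(round(100 * mutation_frequency(mut10, "g1", 237)$overall_freq,
                     2), 4.22)

  empty <- mut[0, ]
  expect_equal(mutation_frequency(empty, "g1", 20)$overall_freq, 0)
  expect_error(mutation_frequency(mut, "g1", 0), "positive")
})

test_that("regulator network edges reflect correlation structure", {
  cox_null <- data.frame(gene = sprintf("g%d", 1:10), HR = 1,
                         p_value = 0.5)
  # duplicated gene as two nodes: edge with r = 1
  s <- stats::rnorm(50)
  v <- rbind(g1 = s, g2 = s, g3 = stats::rnorm(50))
  colnames(v) <- sprintf("s%02d", 1:50)
  net <- build_regulator_network(expr_matrix(v, unit = "LOG2"),
                                 c("g1", "g2", "g3"), cox_null,
                                 roles = data.frame(gene = c("g1", "g2", "g3"),
                                                    role = "reader"))
  e12 <- net$edges[net$edges$gene_i == "g1" & net$edges$gene_j == "g2", ]
  expect_equal(e12$r, 1)

  # independent Gaussian genes at r >= 0.5: essentially no edges
  set.seed(18)
  vn <- matrix(stats::rnorm(10 * 200), 10, 200,
               dimnames = list(sprintf("g%d", 1:10), sprintf("s%03d", 1:200)))
  net0 <- build_regulator_network(expr_matrix(vn, unit = "LOG2"),
                                  rownames(vn), cox_null, r_threshold = 0.5,
                                  roles = data.frame(gene = rownames(vn),
                                                     role = "reader"))
  expect_lte(nrow(net0$edges), 1L)

  # planted correlated block: all within-block edges recovered
  set.seed(25)
  u <- stats::rnorm(200)
  block <- outer(rep(1, 4), u) * sqrt(0.8) +
    matrix(stats::rnorm(800, sd = sqrt(0.2)), 4, 200)
  vb <- rbind(block, matrix(stats::rnorm(6 * 200), 6, 200))
  dimnames(vb) <- list(sprintf("g%d", 1:10), sprintf("s%03d", 1:200))
  netb <- build_regulator_network(expr_matrix(vb, unit = "LOG2"),
                                  rownames(vb), cox_null, r_threshold = 0.4,
                                  roles = data.frame(gene = rownames(vb),
                                                     role = "reader"))
  within <- netb$edges$gene_i %in% sprintf("g%d", 1:4) &
    netb$edges$gene_j %in% sprintf("g%d", 1:4)
  expect_identical(sum(within), 6L)

  # node prognosis classes from Cox results
  cox2 <- data.frame(gene = rownames(vb),
                     HR = c(2, 0.5, rep(1, 8)),
                     p_value = c(0.01, 0.01, rep(0.5, 8)))
  net2 <- build_regulator_network(expr_matrix(vb, unit = "LOG2"),
                                  rownames(vb), cox2,
                                  roles = data.frame(gene = rownames(vb),
                                                     role = "writer"))
  expect_identical(net2$nodes$prognosis[1:3], c("risk", "protective", "ns"))

  # constant gene excluded from edges with warning; r bounded
  vc <- vb; vc[5, ] <- 3
  expect_warning(
    netc <- build_regulator_network(expr_matrix(vc, unit = "LOG2"),
                                    rownames(vc), cox_null,
                                    roles = data.frame(gene = rownames(vc),
                                                       role = "eraser")),
    "constant")
  expect_false(any(netc$edges$gene_i == "g5" | netc$edges$gene_j == "g5"))
  expect_true(all(abs(netc$edges$r) <= 1))
})
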