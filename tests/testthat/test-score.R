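test_that("signature partition splits by correlation sign", {
  # two perfectly anticorrelated genes: one in A, one in B
  s <- seq(-1, 1, length.out = 20)
  v <- rbind(gpos = s, gneg = -s) +
    matrix(stats::rnorm(40, sd = 1e-6), 2, 20)
  colnames(v) <- sprintf("s%02d", 1:20)
  p <- partition_signature(expr_matrix(v, unit = "LOG2"), c("gpos", "gneg"))
  expect_length(p$A, 1L)
  expect_length(p$B, 1L)
  expect_false(p$A == p$B)

  # all mutually positive: B empty with warning
  set.seed(2)
  f <- stats::rnorm(30)
  vp <- outer(rep(1, 4), f) + matrix(stats::rnorm(120, sd = 0.2), 4, 30)
  dimnames(vp) <- list(sprintf("g%d", 1:4), sprintf("s%02d", 1:30))
  expect_warning(pp <- partition_signature(expr_matrix(vp, unit = "LOG2"),
                                           rownames(vp)),
                 "set B empty")
  expect_length(pp$B, 0L)

  # planted two-block structure is recovered
  set.seed(5)
  u <- stats::rnorm(100)
  blockA <- outer(rep(1, 5), u) + matrix(stats::rnorm(500, sd = 0.6), 5, 100)
  blockB <- outer(rep(-1, 5), u) + matrix(stats::rnorm(500, sd = 0.6), 5, 100)
  vb <- rbind(blockA, blockB)
  dimnames(vb) <- list(c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)),
                       sprintf("s%03d", 1:100))
  pb <- partition_signature(expr_matrix(vb, unit = "LOG2"), rownames(vb))
  sideA <- grepl("^a", pb$A)
  expect_true(all(sideA) || all(!sideA))
  expect_length(pb$A, 5L)
  expect_length(pb$B, 5L)
})

test_that("compute_score equals the eigendecomposition oracle", {
  set.seed(19)
  r <- random_expr(12, 50, seed = 19)
  sc <- compute_score(r, rownames(r))
  v <- unclass(r)
  z <- t(scale(t(v)))
  ev <- eigen(stats::cov(t(z)), symmetric = TRUE)
  for (j in 1:2) {
    ref <- drop(t(z) %*% ev$vectors[, j])
    mine <- if (j == 1) sc$pc1 else sc$pc2
    agree <- min(max(abs(mine - ref)), max(abs(mine + ref)))
    expect_lt(agree, 1e-8)
  }
  # the score is exactly pc1 + pc2 and a linear functional of z
  expect_identical(sc$score, sc$pc1 + sc$pc2)
  w <- sc$loadings[, 1] + sc$loadings[, 2]
  expect_equal(sc$score, drop(t(z) %*% w), tolerance = 1e-10)

  # duplicated samples get identical scores
  v2 <- cbind(v, dup = v[, 1])
  colnames(v2) <- c(colnames(v), "dup")
  sc2 <- compute_score(expr_matrix(v2, unit = "LOG2"), rownames(v))
  expect_equal(unname(sc2$score[ncol(v2)]), unname(sc2$score[1]),
               tolerance = 1e-10)

  # invariant to per-gene affine rescaling and sample order
  v3 <- v * 3 + 7
  sc3 <- compute_score(expr_matrix(v3, unit = "LOG2"), rownames(v))
  expect_equal(sc3$score, sc$score, tolerance = 1e-8)
  set.seed(3)
  perm <- sample(ncol(v))
  sc4 <- compute_score(expr_matrix(v[, perm], unit = "LOG2"), rownames(v))
  expect_equal(sc4$score, sc$score[perm], tolerance = 1e-8)

  expect_error(compute_score(r, "g01"), "at least 2")
})

test_that("a single latent factor is recovered from loaded genes", {
  g <- generate_cohort(n_samples = 200, n_genes = 400, n_deg = 121, seed = 31)
  sc <- suppressWarnings(
    compute_score(g$cohort$expression, g$truth$deg_genes))
  rho <- stats::cor(sc$score, g$truth$score[sc$sample_id],
                    method = "spearman")
  expect_gte(abs(rho), 0.9)
  # orientation convention: positive association with set A's mean profile
  expect_gte(stats::cor(
    sc$pc1,
    colMeans(unclass(g$cohort$expression)[sc$partition$A, sc$sample_id])), 0)
})

test_that("dichotomization finds a survival-relevant split", {
  g <- generate_cohort(n_samples = 150, n_genes = 300, n_deg = 60,
                       tmb_log_hr = 0, seed = 77)
  sc <- suppressWarnings(
    compute_score(g$cohort$expression, g$truth$deg_genes))
  sc <- dichotomize_score(sc, g$cohort$clinical)
  expect_true(all(table(sc$group) >= ceiling(0.1 * 150)))
  cl <- g$cohort$clinical
  lr <- logrank_test(cl$os_time, cl$os_event, sc$group)
  expect_lt(lr$p, 0.01)
  # the protective planted effect: high scores live longer
  km_hi <- km_estimate(cl$os_time[sc$group == "high"],
                       cl$os_event[sc$group == "high"])
  km_lo <- km_estimate(cl$os_time[sc$group == "low"],
                       cl$os_event[sc$group == "low"])
  tmid <- stats::median(cl$os_time)
  expect_gt(km_surv_at(km_hi, tmid), km_surv_at(km_lo, tmid))

  # the cutpoint equals the shared brute-force maximizer
  cp <- optimal_cutpoint(cl$os_time, cl$os_event, sc$score)
  expect_equal(sc$cutpoint, cp$cutpoint)

  # constant scores cannot be dichotomized
  const <- stats::setNames(rep(1, 150), cl$sample_id)
  expect_error(dichotomize_score(const, cl), "constant")
})

test_that("immune correlation finds planted dependence and stays calibrated", {
  set.seed(44)
  n <- 100
  score <- stats::setNames(stats::rnorm(n), sprintf("s%03d", 1:n))
  planted <- 0.8 * score + stats::rnorm(n, sd = 0.6)
  em <- rbind(planted = planted,
              matrix(stats::rnorm(27 * n), 27, n,
                     dimnames = list(sprintf("null%02d", 1:27), NULL)))
  colnames(em) <- names(score)
  tab <- correlate_immune(score, em)
  expect_gte(tab$rho[tab$feature == "planted"], 0.6)
  expect_lt(tab$adj_p[tab$feature == "planted"], 0.05)
  null_rej <- mean(tab$p[tab$feature != "planted"] < 0.05)
  expect_lte(null_rej, 0.2)

  # a feature equal to the score itself has rho = 1
  em2 <- rbind(self = unname(score), em)
  colnames(em2) <- names(score)
  tab2 <- correlate_immune(score, em2)
  expect_equal(tab2$rho[tab2$feature == "self"], 1)

  # constant rows give NA with a warning
  em3 <- rbind(flat = rep(2, n), em)
  colnames(em3) <- names(score)
  expect_warning(tab3 <- correlate_immune(score, em3), "constant")
  expect_true(is.na(tab3$rho[tab3$feature == "flat"]))
})

test_that("the joined stratification table is single-valued per sample", {
  g <- generate_cohort(n_samples = 60, n_genes = 150, n_deg = 30, seed = 15)
  sc <- dichotomize_score(
    suppressWarnings(compute_score(g$cohort$expression, g$truth$deg_genes)),
    g$cohort$clinical)
  m6a <- stats::setNames(LETTERS[g$truth$cluster], names(g$truth$cluster))
  genec <- stats::setNames(paste0("geneCluster", LETTERS[g$truth$cluster]),
                           names(g$truth$cluster))
  st <- sankey_table(sc, m6a, genec, g$cohort$clinical)
  expect_identical(nrow(st), 60L)
  expect_false(anyNA(st))
  expect_identical(anyDuplicated(st$sample_id), 0L)
  expect_true(all(st$score_group %in% c("high", "low")))
  expect_true(all(st$status %in% c("alive", "dead")))
})
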