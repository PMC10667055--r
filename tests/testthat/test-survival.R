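test_that("Kaplan-Meier matches the hand product-limit on the small fixture", {
  fx <- fixture_survival_small()$km
  km <- km_estimate(fx$os_time, fx$os_event)
  expect_equal(km_surv_at(km, c(5, 8, 16)), c(0.75, 0.50, 0))
  expect_equal(km_surv_at(km, 4.9), 1)       # S(0) = 1 before first event

  # all censored: flat at 1
  km_c <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))

  # no censoring: S = 1 - empirical CDF (right-continuous)
  set.seed(8)
  t <- stats::rexp(40) + 0.1
  km_n <- km_estimate(t, rep(1, 40))
  expect_equal(km_n$surv, 1 - stats::ecdf(t)(km_n$time))

  # against the hand oracle on random censored data
  s <- sim_surv(60)
  km_r <- km_estimate(s$time, s$event)
  orc <- oracle_km(s$time, s$event)
  expect_equal(km_r$surv, orc$surv, tolerance = 1e-12)

  # Greenwood variance is 0 at S = 1 and S = 0
  expect_true(all(km_c$greenwood_var == 0))
  expect_equal(km$greenwood_var[km$surv == 0], 0)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("log-rank test matches hand accumulation and survdiff", {
  # symmetric case: identical vectors in both groups
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # fully ordered 6-subject example: hand hypergeometric accumulation
  fx <- fixture_survival_small()$logrank
  lr <- logrank_test(fx$os_time, fx$os_event, fx$group)
  o_minus_e <- 0; v_acc <- 0
  times <- fx$os_time; grp <- fx$group
  for (tt in sort(times)) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "g1")
    d <- 1
    o1 <- as.numeric(grp[times == tt] == "g1")
    o_minus_e <- o_minus_e + o1 - d * n1 / n
    if (n > 1) v_acc <- v_acc + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  expect_equal(lr$chisq, o_minus_e^2 / v_acc, tolerance = 1e-12)

  # cross-check against the survival package on censored 3-group data
  set.seed(12)
  s <- sim_surv(90)
  g3 <- sample(c("x", "y", "z"), 90, replace = TRUE)
  lr3 <- logrank_test(s$time, s$event, g3)
  sd3 <- survival::survdiff(survival::Surv(s$time, s$event) ~ g3)
  expect_equal(lr3$chisq, sd3$chisq, tolerance = 1e-10)
  expect_equal(lr3$df, 2L)

  # invariance to group relabeling
  lr3b <- logrank_test(s$time, s$event,
                       c(x = "u", y = "v", z = "w")[g3])
  expect_equal(lr3b$chisq, lr3$chisq, tolerance = 1e-12)
})

test_that("univariate Cox matches coxph and recovers a planted HR", {
  set.seed(31)
  # Breslow ties: compare against coxph on tied data
  s <- sim_surv(120, hr = 1.8, x = stats::rbinom(120, 1, 0.5))
  s$time <- round(s$time) + 1
  fit <- cox_univariate(s$time, s$event, s$x)
  ref <- survival::coxph(survival::Surv(s$time, s$event) ~ s$x,
                         ties = "breslow")
  expect_equal(fit$beta, unname(stats::coef(ref)), tolerance = 1e-7)
  expect_equal(fit$se, sqrt(unname(stats::vcov(ref)[1, 1])), tolerance = 1e-7)

  fit_e <- cox_univariate(s$time, s$event, s$x, ties = "efron")
  ref_e <- survival::coxph(survival::Surv(s$time, s$event) ~ s$x,
                           ties = "efron")
  expect_equal(fit_e$beta, unname(stats::coef(ref_e)), tolerance = 1e-7)

  # consistency: exponential hazards lambda vs 2*lambda, n = 1000
  set.seed(77)
  x <- stats::rbinom(1000, 1, 0.5)
  t_ev <- stats::rexp(1000, 0.05 * 2^x)
  hr_fit <- cox_univariate(t_ev, rep(1, 1000), x)
  expect_gte(hr_fit$hr, 1.8)
  expect_lte(hr_fit$hr, 2.2)

  # affine rescaling of x scales beta by 1/a
  fit_scaled <- cox_univariate(t_ev, rep(1, 1000), 10 * x + 3)
  expect_equal(fit_scaled$beta, hr_fit$beta / 10, tolerance = 1e-6)
  expect_equal(fit_scaled$hr_std, hr_fit$hr_std, tolerance = 1e-6)

  expect_error(cox_univariate(c(1, 2, 3), c(1, 1, 0), rep(2, 3)),
               "degenerate")
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square", {
  set.seed(55)
  t <- stats::rexp(80) + stats::runif(80, 0, 1e-4)   # break ties
  e <- stats::rbinom(80, 1, 0.8)
  e[1] <- 1
  x <- stats::rbinom(80, 1, 0.5)
  fit <- cox_univariate(t, e, x)
  lr <- logrank_test(t, e, x)
  expect_equal(fit$score_chisq, lr$chisq, tolerance = 1e-8)
})

test_that("monotone likelihood is flagged instead of diverging", {
  # perfect separation: all events in the high-x half, ordered times
  t <- c(1:10, 21:30)
  e <- c(rep(1, 10), rep(0, 10))
  x <- c(rep(1, 10), rep(0, 10))
  expect_warning(fit <- cox_univariate(t, e, x), "separation|capped")
  expect_false(fit$converged)
  expect_lte(abs(fit$beta), 15)
})

test_that("optimal_cutpoint equals brute-force enumeration", {
  brute <- function(time, event, score, minprop) {
    n <- length(score)
    svals <- sort(unique(score))
    cands <- (svals[-length(svals)] + svals[-1]) / 2
    best <- NULL
    for (cut in cands) {
      hi <- score > cut
      if (sum(hi) < ceiling(minprop * n) ||
          sum(!hi) < ceiling(minprop * n)) next
      chi <- survival::survdiff(survival::Surv(time, event) ~ hi)$chisq
      z <- sqrt(chi)
      if (is.null(best) || z > best$z + 1e-12) best <- list(cut = cut, z = z)
    }
    best
  }
  for (seed in c(3, 14, 59)) {
    set.seed(seed)
    s <- sim_surv(60)
    score <- stats::rnorm(60)
    cp <- optimal_cutpoint(s$time, s$event, score, minprop = 0.1)
    bf <- brute(s$time, s$event, score, 0.1)
    expect_equal(abs(cp$statistic), bf$z, tolerance = 1e-8)
    expect_equal(cp$cutpoint, bf$cut, tolerance = 1e-12)
  }

  # perfectly informative score: the chosen split puts every short
  # survivor below every long survivor
  t <- c(1:5, 51:55) + 0.5
  cp2 <- optimal_cutpoint(t, rep(1, 10), t, minprop = 0.2)
  expect_lt(max(t[t <= cp2$cutpoint]), min(t[t > cp2$cutpoint]))
  # the split is maximally informative: a large standardized statistic,
  # negative under this sign convention (high scores are protective here)
  expect_gt(abs(cp2$statistic), 2)
  expect_lt(cp2$statistic, 0)

  # minprop = 0.5 with even n: only the median split is admissible
  set.seed(9)
  s3 <- sim_surv(20)
  sc3 <- stats::rnorm(20)
  cp3 <- optimal_cutpoint(s3$time, s3$event, sc3, minprop = 0.5)
  expect_equal(cp3$n_low, 10L)
  expect_equal(cp3$n_high, 10L)

  expect_error(optimal_cutpoint(c(1, 2), c(1, 1), c(3, 3)), "constant")
})

test_that("prognostic filter keeps planted genes and respects alpha", {
  # planted prognostic gene, beta = 0.8: kept in >= 90% of seeds
  kept <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- stats::rnorm(200)
    t_ev <- stats::rexp(200, 0.05 * exp(0.8 * x))
    cl <- data.frame(sample_id = sprintf("s%03d", 1:200),
                     os_time = pmax(t_ev, 1e-3), os_event = rep(1, 200))
    ex <- make_expr(matrix(x, 1, 200, dimnames = list("gene1", cl$sample_id)))
    prognostic_filter(ex, cl, "gene1")$keep
  }, logical(1))
  expect_gte(mean(kept), 0.9)

  # pure noise gene: kept at roughly the alpha level (OR of two 5% tests)
  set.seed(404)
  kept_null <- vapply(1:100, function(i) {
    x <- stats::rnorm(100)
    s <- sim_surv(100)
    cl <- data.frame(sample_id = sprintf("s%03d", 1:100),
                     os_time = s$time, os_event = s$event)
    ex <- make_expr(matrix(x, 1, 100, dimnames = list("g", cl$sample_id)))
    prognostic_filter(ex, cl, "g")$keep
  }, logical(1))
  expect_lte(mean(kept_null), 0.2)

  # alpha = 0 keeps nothing; missing genes come back as NA rows
  set.seed(5)
  s <- sim_surv(50)
  cl <- data.frame(sample_id = sprintf("s%02d", 1:50),
                   os_time = s$time, os_event = s$event)
  ex <- make_expr(matrix(stats::rnorm(100), 2, 50,
                         dimnames = list(c("a", "b"), cl$sample_id)))
  tab <- prognostic_filter(ex, cl, c("a", "b"), alpha = 0)
  expect_false(any(tab$keep))
  expect_warning(tab2 <- prognostic_filter(ex, cl, c("a", "ghost")),
                 "absent")
  expect_true(is.na(tab2$HR[tab2$gene == "ghost"]))
})
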