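# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are written as literal, loop-based transcriptions so they
# stay independent of the vectorized package code paths.

make_expr <- function(values, unit = "LOG2", genes = NULL, samples = NULL) {
  if (is.null(genes)) {
    genes <- if (!is.null(rownames(values))) rownames(values)
             else sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(samples)) {
    samples <- if (!is.null(colnames(values))) colnames(values)
               else sprintf("s%02d", seq_len(ncol(values)))
  }
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, unit = unit)
}

random_expr <- function(n_genes, n_samples, unit = "LOG2", seed = 1,
                        gen = function(n) stats::rnorm(n)) {
  set.seed(seed)
  make_expr(matrix(gen(n_genes * n_samples), n_genes, n_samples), unit = unit)
}

# Literal ssGSEA running-sum: per sample, per set, explicit loops.
oracle_ssgsea <- function(v, sets, alpha = 0.25) {
  out <- matrix(NA_real_, length(sets), ncol(v),
                dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(ncol(v))) {
    r <- rank(v[, j], ties.method = "average")
    ord <- order(v[, j], decreasing = TRUE)
    for (si in seq_along(sets)) {
      inset <- rownames(v) %in% sets[[si]]
      denom_in <- sum(r[inset]^alpha)
      n_out <- sum(!inset)
      p_in <- 0; p_out <- 0; es <- 0
      for (pos in ord) {
        if (inset[pos]) p_in <- p_in + r[pos]^alpha / denom_in
        else p_out <- p_out + 1 / n_out
        es <- es + (p_in - p_out)
      }
      out[si, j] <- es
    }
  }
  out
}

# Literal GSVA recipe: Gaussian kernel CDF, symmetric rank statistic,
# weighted Kolmogorov walk, signed difference of extremes.
oracle_gsva <- function(v, sets) {
  n <- ncol(v); ng <- nrow(v)
  z <- matrix(0.5, ng, n)
  for (i in seq_len(ng)) {
    s <- stats::sd(v[i, ])
    if (s == 0) next
    h <- s / 4
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + stats::pnorm((v[i, j] - v[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(n)) {
    rk <- rank(z[, j], ties.method = "average")
    rs <- abs(ng / 2 - rk)
    ord <- order(z[, j], decreasing = TRUE)
    for (si in seq_along(sets)) {
      inset <- rownames(v) %in% sets[[si]]
      denom_in <- sum(rs[inset])
      n_out <- sum(!inset)
      p_in <- 0; p_out <- 0; mx <- 0; mn <- 0
      for (pos in ord) {
        if (inset[pos]) p_in <- p_in + rs[pos] / denom_in
        else p_out <- p_out + 1 / n_out
        dev <- p_in - p_out
        if (dev > mx) mx <- dev
        if (dev < mn) mn <- dev
      }
      out[si, j] <- mx + mn
    }
  }
  out
}

# Literal transcription of the empirical-Bayes moderated t recipe for a
# two-group comparison with equal residual df across genes.
oracle_moderated_t <- function(v, lab, g1, g2) {
  xa <- v[, lab == g1, drop = FALSE]; xb <- v[, lab == g2, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb); dg <- na + nb - 2
  s2 <- ((na - 1) * apply(xa, 1, stats::var) +
         (nb - 1) * apply(xb, 1, stats::var)) / dg
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  trig_inv <- function(y)
    stats::uniroot(function(x) trigamma(x) - y, c(1e-8, 1e10),
                   tol = 1e-14)$root
  if (evar > 0) {
    d0 <- 2 * trig_inv(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_t <- d0 + dg
  } else {
    s02 <- exp(mean(e))
    s2post <- rep(s02, length(s2))
    d0 <- Inf
    df_t <- Inf
  }
  delta <- rowMeans(xa) - rowMeans(xb)
  t_stat <- delta / sqrt(s2post * (1 / na + 1 / nb))
  list(logFC = delta, t = t_stat,
       p = 2 * stats::pt(-abs(t_stat), df = df_t), d0 = d0, s02 = s02)
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand product-limit estimator over distinct times.
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1; out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    nr <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / nr)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Simple survival data generator for calibration runs.
sim_surv <- function(n, hr = 1, x = NULL, censor = 0.3) {
  if (is.null(x)) x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, 0.05 * hr^x)
  c_ev <- if (censor > 0) stats::rexp(n, 0.05 * censor / (1 - censor))
          else rep(Inf, n)
  list(time = pmax(pmin(t_ev, c_ev), 1e-4), event = as.numeric(t_ev <= c_ev),
       x = x)
}
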