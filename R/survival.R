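# Survival machinery: Kaplan-Meier product-limit estimation, the log-rank
# test, univariate Cox regression (Breslow/Efron ties) and the
# maximally-selected-rank-statistic cutpoint search. These primitives are
# implemented here directly because the cutpoint search needs the
# standardized log-rank statistic at every candidate split; the survival
# package is used as an independent cross-check in the test suite.

#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive event/censoring times.
#' @param events 0 = censored, 1 = event.
#' @return A `km_curve`: data frame of distinct times with at-risk counts,
#'   event counts, survival estimates and Greenwood variance.
#' @export
km_estimate <- function(times, events) {
  .assert_pos_times(times)
  .assert_binary(events, "events")
  stopifnot(length(times) == length(events), length(times) >= 1L)
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- unique(times)
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)));  0/0 at S = 0 -> 0
  gw_term <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  gvar <- surv^2 * cumsum(gw_term)
  gvar[surv == 0] <- 0
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    surv = surv, greenwood_var = gvar)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, final S = %.3f\n",
              nrow(x), x$surv[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Survival probability at given times
#'
#' Step-function evaluation of a Kaplan-Meier curve; S(t) = 1 before the
#' first event time.
#'
#' @param km A `km_curve`.
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

# Observed/expected/variance accumulation over pooled event times.
# Returns per-group O and E plus the full hypergeometric covariance matrix.
.logrank_oev <- function(times, events, groups) {
  g <- as.factor(groups)
  lev <- levels(g)
  k <- length(lev)
  ut <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(k), lev)
  V <- matrix(0, k, k, dimnames = list(lev, lev))
  for (t in ut) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    d_j <- sum(times == t & events == 1)
    n_gj <- vapply(lev, function(l) sum(at_risk & g == l), numeric(1))
    d_gj <- vapply(lev, function(l)
      sum(times == t & events == 1 & g == l), numeric(1))
    O <- O + d_gj
    E <- E + d_j * n_gj / n_j
    if (n_j > 1) {
      p <- n_gj / n_j
      hyper <- d_j * (n_j - d_j) / (n_j - 1)
      V <- V + hyper * (diag(p, nrow = k) - tcrossprod(p))
    }
  }
  list(O = O, E = E, V = V, levels = lev)
}

#' Log-rank test
#'
#' Standard O-E/V log-rank across the pooled event times of two or more
#' groups; degrees of freedom are the number of groups minus one.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List with `chisq`, `df`, `p`, and per-group `observed`,
#'   `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  .assert_pos_times(times)
  .assert_binary(events, "events")
  g <- as.factor(as.character(groups))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  acc <- .logrank_oev(times, events, g)
  k <- length(acc$levels)
  d <- (acc$O - acc$E)[-k]
  Vsub <- acc$V[-k, -k, drop = FALSE]
  Vinv <- tryCatch(solve(Vsub), error = function(e) MASS_ginv(Vsub))
  chisq <- drop(t(d) %*% Vinv %*% d)
  df <- k - 1L
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = acc$O, expected = acc$E)
}

# Moore-Penrose pseudoinverse via SVD (degenerate variance matrices arise
# when a group leaves the risk set early).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Two-group standardized log-rank statistic (O - E)/sqrt(V) for the
# indicator `high`; positive when the high group has MORE events than
# expected.
.logrank_z <- function(times, events, high) {
  acc <- .logrank_oev(times, events, factor(high, levels = c(FALSE, TRUE)))
  v <- acc$V[2L, 2L]
  if (v <= 0) return(0)
  (acc$O[2L] - acc$E[2L]) / sqrt(v)
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with Breslow
#' (default) or Efron handling of tied event times. Reports the hazard
#' ratio with a 95% Wald confidence interval and the Wald p-value, plus
#' the score test at beta = 0 (which equals the log-rank chi-square for a
#' binary covariate without ties).
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param x Numeric covariate with positive variance.
#' @param ties `"breslow"` or `"efron"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A `cox_fit` list: `beta`, `se`, `hr`, `hr_lo`, `hr_hi`, `p`,
#'   `score_chisq`, `hr_std` (HR per SD of x), `converged`, `iterations`.
#' @export
cox_univariate <- function(times, events, x, ties = c("breslow", "efron"),
                           max_iter = 25L, tol = 1e-9) {
  ties <- match.arg(ties)
  .assert_pos_times(times)
  .assert_binary(events, "events")
  stopifnot(length(x) == length(times))
  if (stats::var(x) == 0) stop("degenerate covariate (zero variance)",
                               call. = FALSE)
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)

  ord <- order(times)
  tt <- times[ord]; ee <- events[ord]; xx <- x[ord]
  ut <- unique(tt[ee == 1])

  deriv <- function(beta) {
    w <- exp(beta * xx)
    ll <- 0; U <- 0; I <- 0
    for (t in ut) {
      risk <- tt >= t
      dead <- tt == t & ee == 1
      d <- sum(dead)
      s0 <- sum(w[risk]); s1 <- sum(w[risk] * xx[risk])
      s2 <- sum(w[risk] * xx[risk]^2)
      xsum <- sum(xx[dead])
      if (ties == "breslow" || d == 1L) {
        ll <- ll + beta * xsum - d * log(s0)
        U <- U + xsum - d * s1 / s0
        I <- I + d * (s2 / s0 - (s1 / s0)^2)
      } else {  # Efron
        sd0 <- sum(w[dead]); sd1 <- sum(w[dead] * xx[dead])
        sd2 <- sum(w[dead] * xx[dead]^2)
        for (r in seq_len(d) - 1L) {
          f <- r / d
          a0 <- s0 - f * sd0; a1 <- s1 - f * sd1; a2 <- s2 - f * sd2
          ll <- ll - log(a0)
          U <- U - a1 / a0
          I <- I + a2 / a0 - (a1 / a0)^2
        }
        ll <- ll + beta * xsum
        U <- U + xsum
      }
    }
    list(ll = ll, U = U, I = I)
  }

  d0 <- deriv(0)
  score_chisq <- if (d0$I > 0) d0$U^2 / d0$I else 0

  beta <- 0; converged <- FALSE; iter <- 0L
  ll_old <- d0$ll; dv <- d0
  while (iter < max_iter) {
    iter <- iter + 1L
    if (dv$I <= 0) break
    step <- dv$U / dv$I
    beta_new <- beta + step
    dv_new <- deriv(beta_new)
    halvings <- 0L
    while (dv_new$ll < ll_old - 1e-12 && halvings < 10L) {
      halvings <- halvings + 1L
      beta_new <- (beta + beta_new) / 2
      dv_new <- deriv(beta_new)
    }
    beta <- beta_new; dv <- dv_new; ll_old <- dv$ll
    if (abs(dv$U) < tol * max(1, abs(d0$U))) { converged <- TRUE; break }
    if (abs(beta) > 15) break  # monotone likelihood / separation
  }
  if (!converged && abs(beta) > 15) {
    warning("monotone partial likelihood (possible separation); |beta| capped",
            call. = FALSE)
    beta <- sign(beta) * 15
    dv <- deriv(beta)
  }
  se <- if (dv$I > 0) 1 / sqrt(dv$I) else NA_real_
  hr <- exp(beta)
  z <- beta / se
  out <- list(beta = beta, se = se, hr = hr,
              hr_lo = exp(beta - 1.96 * se), hr_hi = exp(beta + 1.96 * se),
              p = 2 * stats::pnorm(-abs(z)),
              score_chisq = score_chisq,
              hr_std = exp(beta * stats::sd(x)),
              loglik = dv$ll, converged = converged, iterations = iter,
              ties = ties, n = length(times), n_event = sum(events))
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> HR = %.4f (95%% CI %.4f-%.4f), p = %.3g, n = %d (%d events)%s\n",
    x$hr, x$hr_lo, x$hr_hi, x$p, x$n, x$n_event,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Prognostic gene filter by Cox and Kaplan-Meier analyses
#'
#' For each gene: a univariate Cox regression on its expression, and a
#' log-rank test after a median split (configurable to the
#' maximally-selected cutpoint). A gene is kept when the Cox p OR the KM p
#' is below `alpha` (rule configurable to AND).
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical table aligned to the expression columns.
#' @param genes Genes to test (default: all rows).
#' @param alpha Significance level.
#' @param rule `"or"` or `"and"` combination of the two tests.
#' @param split `"median"` or `"cutpoint"` for the KM dichotomization.
#' @return Data frame with columns `gene`, `HR`, `HR.95L`, `HR.95H`,
#'   `p_value`, `km`, `keep`.
#' @export
prognostic_filter <- function(expr, clinical, genes = NULL, alpha = 0.05,
                              rule = c("or", "and"),
                              split = c("median", "cutpoint")) {
  rule <- match.arg(rule)
  split <- match.arg(split)
  v <- .expr_values(expr)
  clinical <- validate_clinical(clinical)
  stopifnot(ncol(v) == nrow(clinical))
  if (is.null(genes)) genes <- rownames(v)
  missing_genes <- setdiff(genes, rownames(v))
  if (length(missing_genes)) {
    warning(sprintf("gene(s) absent from expression: %s",
                    paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  genes <- intersect(genes, rownames(v))
  if (!length(genes)) {
    stop("none of the requested genes are present in the expression matrix",
         call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    xg <- v[g, ]
    if (stats::var(xg) == 0) {
      return(data.frame(gene = g, HR = NA_real_, HR.95L = NA_real_,
                        HR.95H = NA_real_, p_value = NA_real_, km = NA_real_,
                        keep = FALSE))
    }
    fit <- cox_univariate(clinical$os_time, clinical$os_event, xg)
    km_p <- NA_real_
    grp <- xg > stats::median(xg)
    if (split == "cutpoint") {
      cp <- try(optimal_cutpoint(clinical$os_time, clinical$os_event, xg),
                silent = TRUE)
      if (!inherits(cp, "try-error")) grp <- xg > cp$cutpoint
    }
    if (length(unique(grp)) == 2L) {
      km_p <- logrank_test(clinical$os_time, clinical$os_event, grp)$p
    }
    keep <- if (rule == "or") {
      isTRUE(fit$p < alpha) || isTRUE(km_p < alpha)
    } else {
      isTRUE(fit$p < alpha) && isTRUE(km_p < alpha)
    }
    data.frame(gene = g, HR = fit$hr, HR.95L = fit$hr_lo, HR.95H = fit$hr_hi,
               p_value = fit$p, km = km_p, keep = keep)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(missing_genes)) {
    out <- rbind(out, data.frame(gene = missing_genes, HR = NA_real_,
                                 HR.95L = NA_real_, HR.95H = NA_real_,
                                 p_value = NA_real_, km = NA_real_,
                                 keep = FALSE))
  }
  out
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic at every split
#' of the score that leaves at least `ceiling(minprop * n)` samples on
#' each side, and returns the split maximizing its absolute value. Ties
#' are broken toward the median score; the cutpoint is reported as the
#' midpoint between the adjacent order statistics so that group assignment
#' is stable under floating-point noise.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param score Numeric score with at least two distinct values.
#' @param minprop Minimum fraction of samples per group.
#' @return A `cutpoint_result`: `cutpoint`, `statistic` (standardized
#'   log-rank z at the cutpoint, sign: positive when the high group has
#'   more events than expected), `n_low`, `n_high`, `minprop`.
#' @export
optimal_cutpoint <- function(times, events, score, minprop = 0.1) {
  .assert_pos_times(times)
  .assert_binary(events, "events")
  n <- length(score)
  stopifnot(length(times) == n, length(events) == n)
  if (length(unique(score)) < 2L) {
    stop("score is constant: no admissible split", call. = FALSE)
  }
  min_n <- ceiling(minprop * n)
  svals <- sort(unique(score))
  # candidate cuts: midpoints between adjacent distinct values
  cand <- (svals[-length(svals)] + svals[-1L]) / 2
  sizes_low <- vapply(cand, function(c) sum(score <= c), numeric(1))
  ok <- sizes_low >= min_n & (n - sizes_low) >= min_n
  if (!any(ok)) stop("no admissible split under minprop", call. = FALSE)
  cand <- cand[ok]
  zs <- vapply(cand, function(c) .logrank_z(times, events, score > c),
               numeric(1))
  best <- which(abs(zs) == max(abs(zs)))
  if (length(best) > 1L) {  # tie: toward the median score
    med <- stats::median(score)
    best <- best[which.min(abs(cand[best] - med))]
  }
  out <- list(cutpoint = cand[best], statistic = zs[best],
              n_low = sum(score <= cand[best]),
              n_high = sum(score > cand[best]), minprop = minprop)
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> cut = %.4g, |z| = %.3f (n_low = %d, n_high = %d)\n",
              x$cutpoint, abs(x$statistic), x$n_low, x$n_high))
  invisible(x)
}

#' Write a Kaplan-Meier curve as TSV
#' @param km A `km_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km <- function(km, path) {
  utils::write.table(as.data.frame(km), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
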