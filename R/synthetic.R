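# Synthetic cohorts with known ground truth. The generators plant the
# exact statistical structure the analysis stages assume — regulator
# expression clusters, a latent phenotype score driving survival, immune
# mixtures, mutation counts and checkpoint-therapy response — so that
# every pipeline stage can be validated by parameter recovery.

#' Generate a synthetic tumor cohort
#'
#' Expression (LOG2 scale) consists of a regulator block drawn from
#' cluster-specific Gaussian means (separation `cluster_shift_sd` times
#' the within-cluster SD), `n_deg` phenotype genes loaded positively on
#' a latent score correlated with cluster identity, and pure-noise
#' genes. The first three phenotype genes are named after the immune
#' checkpoint trio so checkpoint analyses have targets. Overall survival
#' is Weibull (shape 1.2, median about 30 months at baseline) with
#' log-hazard `score_log_hr` per SD of the latent score and
#' `tmb_log_hr` per SD of log mutation burden; censoring is independent
#' exponential with its rate tuned to the requested fraction.
#' Progression-free survival uses half the score effect and half the
#' time scale. Mutation counts are negative binomial; age and sex are
#' independent of the score.
#'
#' @param n_samples,n_regulators,n_genes,n_clusters Cohort dimensions.
#' @param cluster_shift_sd Between-cluster shift of regulator means, in
#'   within-cluster SD units.
#' @param n_deg Number of phenotype genes loaded on the latent score.
#' @param deg_effect_sd Loading of phenotype genes on the score, in
#'   residual SD units.
#' @param censor_rate Target censoring fraction (must be <= 0.95).
#' @param score_log_hr Log hazard ratio per SD of the latent score.
#' @param tmb_log_hr Log hazard ratio per SD of log1p mutation count.
#' @param tmb_score_link Correlation-inducing coefficient of the score
#'   on the log mutation mean (0 = independent).
#' @param seed Integer seed; generation is a pure function of
#'   (parameters, seed).
#' @return List: `cohort` (a [cohort_bundle()]) and `truth` (cluster
#'   labels, DEG names, latent score, planted log-HRs, seed).
#' @export
generate_cohort <- function(n_samples = 180L, n_regulators = 23L,
                            n_genes = 2000L, n_clusters = 3L,
                            cluster_shift_sd = 3.0, n_deg = 121L,
                            deg_effect_sd = 2.0, censor_rate = 0.4,
                            score_log_hr = -1.0, tmb_log_hr = -0.5,
                            tmb_score_link = 0, seed = 1L) {
  stopifnot(n_clusters >= 2L, n_deg <= n_genes)
  if (censor_rate > 0.95) stop("censor_rate > 0.95 is infeasible",
                               call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(derive_seed(seed, 2L)))

  ids <- sprintf("S%04d", seq_len(n_samples))
  cluster <- sample(rep_len(seq_len(n_clusters), n_samples))

  reg_names <- if (n_regulators == 23L) {
    m6a_regulators(resolve_aliases = TRUE)
  } else {
    sprintf("REG%03d", seq_len(n_regulators))
  }
  mu <- matrix(stats::rnorm(n_clusters * n_regulators, sd = cluster_shift_sd),
               n_clusters, n_regulators)
  reg <- t(mu[cluster, , drop = FALSE]) +
    matrix(stats::rnorm(n_regulators * n_samples), n_regulators, n_samples)
  rownames(reg) <- reg_names

  # latent phenotype score: cluster-linked factor plus individual noise
  centers <- seq(-1, 1, length.out = n_clusters)
  score_raw <- centers[cluster] + stats::rnorm(n_samples, sd = 0.5)
  score <- as.numeric(scale(score_raw))

  deg_names <- c(c("PDCD1", "CD274", "CTLA4")[seq_len(min(3L, n_deg))],
                 if (n_deg > 3L) sprintf("DEG%04d", seq_len(n_deg - 3L)))
  loadings <- deg_effect_sd * stats::runif(n_deg, 0.75, 1.25)
  deg <- outer(loadings, score) +
    matrix(stats::rnorm(n_deg * n_samples), n_deg, n_samples)
  rownames(deg) <- deg_names

  n_noise <- n_genes - n_deg
  noise <- matrix(stats::rnorm(n_noise * n_samples), n_noise, n_samples)
  rownames(noise) <- sprintf("GENE%05d", seq_len(n_noise))

  # genes of the packaged synthetic immune signatures, so enrichment and
  # immune-correlation stages have targets; odd-numbered cell types are
  # positively linked to the latent score, the rest are pure noise
  imm_sets <- immune_signatures_synthetic()
  linked <- seq_along(imm_sets) %% 2L == 1L
  imm_rows <- lapply(seq_along(imm_sets), function(si) {
    gs <- imm_sets[[si]]
    m <- matrix(stats::rnorm(length(gs) * n_samples), length(gs), n_samples)
    if (linked[si]) m <- m + outer(rep(0.6, length(gs)), score)
    rownames(m) <- gs
    m
  })
  imm <- do.call(rbind, imm_rows)

  expr <- rbind(reg, deg, noise, imm) + 8   # shift to a plausible log2 level
  colnames(expr) <- ids

  # mutation counts (negative binomial), optionally score-linked
  mut_mu <- 30 * exp(tmb_score_link * score)
  counts <- stats::rnbinom(n_samples, size = 5, mu = mut_mu)
  z_tmb <- as.numeric(scale(log1p(counts)))

  # Weibull OS with exponential censoring tuned to the target fraction
  shape <- 1.2
  b <- 30 / log(2)^(1 / shape)
  lp <- score_log_hr * score + tmb_log_hr * z_tmb
  draw_times <- function(scale_b, lp_vec) {
    u <- stats::runif(n_samples)
    scale_b * (-log(u) / exp(lp_vec))^(1 / shape)
  }
  tune_censor <- function(t_event) {
    if (censor_rate <= 0) return(rep(Inf, n_samples))
    f <- function(rate) mean(1 - exp(-rate * t_event)) - censor_rate
    rate <- stats::uniroot(f, c(1e-8, 100), tol = 1e-10)$root
    stats::rexp(n_samples, rate)
  }
  t_os <- draw_times(b, lp)
  c_os <- tune_censor(t_os)
  os_time <- pmax(pmin(t_os, c_os), 0.01)
  os_event <- as.numeric(t_os <= c_os)

  lp_pfs <- 0.5 * lp
  t_pfs <- draw_times(b / 2, lp_pfs)
  c_pfs <- tune_censor(t_pfs)
  pfs_time <- pmax(pmin(t_pfs, c_pfs), 0.01)
  pfs_event <- as.numeric(t_pfs <= c_pfs)

  age <- pmin(pmax(round(stats::rnorm(n_samples, 60, 12)), 20), 90)
  sex <- sample(c("male", "female"), n_samples, replace = TRUE)
  clinical <- data.frame(sample_id = ids, os_time = os_time,
                         os_event = os_event, pfs_time = pfs_time,
                         pfs_event = pfs_event, age = age, sex = sex,
                         age_group = ifelse(age > 65, ">65", "<=65"),
                         stringsAsFactors = FALSE)

  # long-format mutation table: genes from a synthetic pool, with a small
  # chance of hitting a regulator
  mut_pool <- sprintf("MUT%03d", 1:300)
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "Splice_Site", "Silent")
  class_p <- c(0.55, 0.1, 0.05, 0.05, 0.05, 0.2)
  mut_rows <- lapply(seq_len(n_samples), function(i) {
    if (counts[i] == 0L) return(NULL)
    hit_reg <- stats::runif(counts[i]) < 0.02
    genes <- ifelse(hit_reg,
                    sample(reg_names, counts[i], replace = TRUE),
                    sample(mut_pool, counts[i], replace = TRUE))
    data.frame(sample_id = ids[i], gene_id = genes,
               variant_classification = sample(classes, counts[i],
                                               replace = TRUE, prob = class_p),
               stringsAsFactors = FALSE)
  })
  mutations <- do.call(rbind, c(mut_rows, list(make.row.names = FALSE)))

  cnv_calls <- sample(c("gain", "loss", "neutral"),
                      n_samples * n_regulators, replace = TRUE,
                      prob = c(0.05, 0.08, 0.87))
  cnv <- data.frame(sample_id = rep(ids, each = n_regulators),
                    gene_id = rep(reg_names, n_samples),
                    call = cnv_calls, stringsAsFactors = FALSE)

  bundle <- cohort_bundle(expr_matrix(expr, unit = "LOG2"), clinical,
                          mutations = mutations, cnv = cnv)
  truth <- list(cluster = stats::setNames(cluster, ids),
                deg_genes = deg_names,
                noise_genes = rownames(noise),
                immune_linked_sets = names(imm_sets)[linked],
                score = stats::setNames(score, ids),
                score_log_hr = score_log_hr, tmb_log_hr = tmb_log_hr,
                mutation_counts = stats::setNames(counts, ids),
                loadings = stats::setNames(loadings, deg_names),
                seed = seed)
  list(cohort = bundle, truth = truth)
}

#' Generate a synthetic deconvolution test bed
#'
#' Log-normal signature matrix with cell-type-specific marker blocks,
#' Dirichlet(1) mixing fractions, and mixtures `S f` plus Gaussian noise
#' scaled to `noise_frac` of the signal SD (negative values are clipped
#' to zero when noise is added).
#'
#' @param n_cell_types,n_sig_genes,n_samples Dimensions
#'   (`n_sig_genes >= 10 * n_cell_types`).
#' @param noise_frac Noise SD as a fraction of signal SD.
#' @param seed Integer seed.
#' @return List: `signature` (genes x cell types), `mixture`
#'   ([expr_matrix()], FPKM unit), `fractions` (samples x cell types,
#'   rows sum to 1).
#' @export
generate_mixtures <- function(n_cell_types = 6L, n_sig_genes = 200L,
                              n_samples = 50L, noise_frac = 0.1, seed = 1L) {
  stopifnot(n_sig_genes >= 10L * n_cell_types)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(derive_seed(seed, 3L)))

  genes <- sprintf("SIG%04d", seq_len(n_sig_genes))
  cells <- sprintf("CellType%02d", seq_len(n_cell_types))
  S <- matrix(stats::rlnorm(n_sig_genes * n_cell_types, meanlog = 1,
                            sdlog = 0.6),
              n_sig_genes, n_cell_types, dimnames = list(genes, cells))
  block <- floor(n_sig_genes / n_cell_types)
  for (k in seq_len(n_cell_types)) {
    rows <- ((k - 1L) * block + 1L):(k * block)
    # marker genes: strictly maximal in their own cell type
    S[rows, k] <- apply(S[rows, , drop = FALSE], 1L, max) * 4
  }
  F <- matrix(stats::rgamma(n_samples * n_cell_types, shape = 1),
              n_samples, n_cell_types)
  F <- F / rowSums(F)
  dimnames(F) <- list(sprintf("MIX%03d", seq_len(n_samples)), cells)
  M <- S %*% t(F)
  if (noise_frac > 0) {
    M <- M + matrix(stats::rnorm(length(M), sd = noise_frac * stats::sd(M)),
                    nrow(M), ncol(M))
    M <- pmax(M, 0)
  }
  list(signature = S,
       mixture = expr_matrix(M, unit = "FPKM"),
       fractions = F)
}

#' Generate a synthetic checkpoint-therapy cohort
#'
#' A latent score drives responder probability through a logistic model
#' (`plogis(intercept + slope * score)`); CR/PR/SD/PD grades come from
#' thresholding a latent response variable, and responders have half the
#' overall-survival hazard. Expression carries the score on checkpoint
#' and signature genes so the scoring stage can recover it.
#'
#' @param n Cohort size (>= 10).
#' @param response_slope Logistic slope on the score.
#' @param response_intercept Logistic intercept (default -1, about a 27%
#'   baseline response rate).
#' @param seed Integer seed.
#' @return List: `cohort` (a [cohort_bundle()]), `responses`
#'   (`sample_id`, `response`), `truth` (score, model parameters,
#'   responder flags).
#' @export
generate_icb_cohort <- function(n = 30L, response_slope = 1.5,
                                response_intercept = -1, seed = 1L) {
  stopifnot(n >= 10L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(derive_seed(seed, 4L)))

  ids <- sprintf("ICB%03d", seq_len(n))
  score <- stats::rnorm(n)
  p_resp <- stats::plogis(response_intercept + response_slope * score)
  responder <- stats::runif(n) < p_resp
  grade_u <- stats::runif(n)
  response <- ifelse(responder,
                     ifelse(grade_u < 0.3, "CR", "PR"),
                     ifelse(grade_u < 0.4, "SD", "PD"))

  n_loaded <- 40L; n_noise <- 20L
  loaded_names <- c("PDCD1", "CD274", "CTLA4",
                    sprintf("ICBSIG%03d", seq_len(n_loaded - 3L)))
  expr <- rbind(
    outer(stats::runif(n_loaded, 1, 1.5), score) +
      matrix(stats::rnorm(n_loaded * n), n_loaded, n),
    matrix(stats::rnorm(n_noise * n), n_noise, n)) + 6
  rownames(expr) <- c(loaded_names, sprintf("ICBNOISE%03d", seq_len(n_noise)))
  colnames(expr) <- ids

  rate <- 0.03 * ifelse(responder, 0.5, 1)
  t_os <- stats::rexp(n, rate)
  c_os <- stats::rexp(n, 0.015)
  clinical <- data.frame(sample_id = ids,
                         os_time = pmax(pmin(t_os, c_os), 0.01),
                         os_event = as.numeric(t_os <= c_os),
                         age = pmin(pmax(round(stats::rnorm(n, 62, 10)), 25), 90),
                         sex = sample(c("male", "female"), n, replace = TRUE),
                         stringsAsFactors = FALSE)
  list(cohort = cohort_bundle(expr_matrix(expr, unit = "LOG2"), clinical),
       responses = data.frame(sample_id = ids, response = response,
                              stringsAsFactors = FALSE),
       truth = list(score = stats::setNames(score, ids),
                    responder = stats::setNames(responder, ids),
                    intercept = response_intercept, slope = response_slope,
                    seed = seed))
}

#' Tiny hand-checkable survival fixtures
#'
#' Returns the four-subject product-limit example (times 5, 8, 12, 16
#' with events 1, 1, 0, 1, so S(5) = 0.75, S(8) = 0.50, S(16) = 0) and a
#' six-subject two-group log-rank example with fully ordered survival.
#'
#' @return List of two clinical data frames, `km` and `logrank` (the
#'   latter with a `group` column).
#' @export
fixture_survival_small <- function() {
  list(
    km = data.frame(sample_id = sprintf("P%d", 1:4),
                    os_time = c(5, 8, 12, 16),
                    os_event = c(1, 1, 0, 1),
                    stringsAsFactors = FALSE),
    logrank = data.frame(sample_id = sprintf("Q%d", 1:6),
                         os_time = c(1, 2, 3, 4, 5, 6),
                         os_event = rep(1, 6),
                         group = rep(c("g1", "g2"), each = 3),
                         stringsAsFactors = FALSE))
}
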