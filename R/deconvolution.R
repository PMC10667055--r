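# Immune-cell fraction estimation by linear nu-support-vector regression
# against a signature matrix, with permutation significance — the
# deconvolution strategy popularized for bulk immune profiling. The SVR
# solver is e1071's nu-regression; the surrounding algorithm (joint
# z-scoring, nu grid selection by RMSE, negative-coefficient clipping,
# simplex renormalization, gene-permutation null) lives here.

.svr_weights <- function(X, y, nu) {
  fit <- e1071::svm(x = X, y = y, type = "nu-regression", kernel = "linear",
                    nu = nu, scale = FALSE)
  drop(t(fit$coefs) %*% fit$SV)
}

# Fit one mixture profile: returns clipped/renormalized fractions plus
# fit QC (RMSE and Pearson r of the reconstruction, on the z-scored scale).
.fit_sample <- function(X, y, nu_grid) {
  best <- NULL
  for (nu in nu_grid) {
    w <- .svr_weights(X, y, nu)
    w_pos <- pmax(w, 0)
    if (sum(w_pos) == 0) next
    f <- w_pos / sum(w_pos)
    u <- drop(X %*% f)
    rmse <- sqrt(mean((u - y)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(fractions = f, rmse = rmse,
                   r = suppressWarnings(stats::cor(u, y)), nu = nu)
    }
  }
  if (is.null(best)) {
    k <- ncol(X)
    best <- list(fractions = rep(1 / k, k), rmse = sqrt(mean(y^2)),
                 r = 0, nu = NA_real_)
  }
  best
}

#' SVR deconvolution of immune-cell fractions
#'
#' Estimates the cell-type composition of each mixture sample by linear
#' nu-support-vector regression of the (jointly z-scored) mixture profile
#' on the signature-matrix columns. For each sample the nu in `nu_grid`
#' minimizing reconstruction RMSE is kept; negative coefficients are
#' clipped to zero and the remainder renormalized to sum to one. A
#' permutation p-value per sample comes from refitting against profiles
#' assembled from randomly drawn mixture values and comparing Pearson r.
#'
#' @param mixture Expression matrix (genes x samples, linear scale).
#' @param sig Signature matrix: signature genes x cell types (>= 50% of
#'   its genes must be present in the mixture).
#' @param nu_grid Candidate nu values.
#' @param n_perm Permutations for the significance null (0 disables).
#' @param seed Integer seed for the permutation draws.
#' @return A `deconvolution_result`: `fractions` (samples x cell types),
#'   `rmse`, `r`, `p` per sample, `nu` chosen per sample.
#' @export
svr_deconvolve <- function(mixture, sig, nu_grid = c(0.25, 0.5, 0.75),
                           n_perm = 100L, seed = 1L) {
  v <- .expr_values(mixture)
  S <- as.matrix(sig)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("signature matrix needs gene row names and cell-type column names",
         call. = FALSE)
  }
  if (any(colSums(S != 0) == 0)) stop("signature has all-zero column(s)",
                                      call. = FALSE)
  dup_cor <- stats::cor(S)
  if (any(dup_cor[upper.tri(dup_cor)] > 0.9999)) {
    warning("signature columns are collinear (near-duplicate cell types)",
            call. = FALSE)
  }
  shared <- intersect(rownames(S), rownames(v))
  if (length(shared) < 0.5 * nrow(S)) {
    stop(sprintf("only %d/%d signature genes present in mixture (< 50%%)",
                 length(shared), nrow(S)), call. = FALSE)
  }
  S <- S[shared, , drop = FALSE]
  M <- v[shared, , drop = FALSE]
  # joint z-scoring over the signature genes (global moments per matrix)
  Xz <- (S - mean(S)) / stats::sd(S)
  n <- ncol(M)
  k <- ncol(S)
  fractions <- matrix(NA_real_, n, k, dimnames = list(colnames(M),
                                                      colnames(S)))
  rmse <- r <- pval <- nu_sel <- rep(NA_real_, n)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(derive_seed(seed, 1L)))

  null_r <- NULL
  if (n_perm > 0L) {
    pool <- as.vector(M)
    null_r <- vapply(seq_len(n_perm), function(p) {
      yp <- sample(pool, length(shared), replace = length(pool) < length(shared))
      yp <- (yp - mean(yp)) / stats::sd(yp)
      .fit_sample(Xz, yp, nu_grid)$r
    }, numeric(1))
  }
  for (j in seq_len(n)) {
    y <- M[, j]
    sy <- stats::sd(y)
    if (sy == 0) {
      warning(sprintf("mixture sample '%s' is constant; skipped",
                      colnames(M)[j]), call. = FALSE)
      next
    }
    yz <- (y - mean(y)) / sy
    fit <- .fit_sample(Xz, yz, nu_grid)
    fractions[j, ] <- fit$fractions
    rmse[j] <- fit$rmse
    r[j] <- fit$r
    nu_sel[j] <- fit$nu
    if (!is.null(null_r)) pval[j] <- mean(null_r >= fit$r)
  }
  structure(list(fractions = fractions, rmse = rmse, r = r, p = pval,
                 nu = nu_sel, n_perm = n_perm, solver = "nu-SVR (e1071)"),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d samples x %d cell types (%s)\n",
              nrow(x$fractions), ncol(x$fractions), x$solver))
  cat(sprintf("  median RMSE %.3f, median r %.3f\n",
              stats::median(x$rmse, na.rm = TRUE),
              stats::median(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Compare deconvolved cell fractions across groups
#'
#' Same contract as [compare_scores_by_group()], applied to the fraction
#' columns of a deconvolution result.
#'
#' @param result A `deconvolution_result` (or samples x cell types matrix).
#' @param labels Group label per sample.
#' @return Comparison data frame (set = cell type).
#' @export
compare_fractions_by_group <- function(result, labels) {
  m <- if (inherits(result, "deconvolution_result")) result$fractions
       else as.matrix(result)
  compare_scores_by_group(t(m), labels)
}
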