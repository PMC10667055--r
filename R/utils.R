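# Shared helpers: significance stars, seed fan-out, input checks.

#' Significance stars for p-values
#'
#' Conventional star coding: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, empty otherwise. `NA` maps to `NA`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
p_stars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
  out
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic fan-out of one user seed into per-stage / per-replicate
#' sub-seeds (linear congruential step on the 31-bit integer lattice), so
#' a single master seed reproduces every stage of a run. Every derived
#' seed is a valid positive R integer.
#'
#' @param seed Master seed (single finite number).
#' @param index Stage/replicate index.
#' @return A numeric scalar in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647                      # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  ((s * 48271 + 104729 * as.numeric(index)) %% m) + 1
}

.assert_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0/1 values", what), call. = FALSE)
  }
  invisible(TRUE)
}

.assert_pos_times <- function(times) {
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("survival times must be finite and strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two clusterings of the same items, corrected
#' for chance; 1 means identical partitions, 0 is the expectation under
#' independent random labels.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
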