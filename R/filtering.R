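#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, exposed so the two
#' filtering stages and external callers share one adjustment entry point.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, order-aligned with the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Step-one filter: t-test of factor loadings
#'
#' The factor loading of gene h on component c is the Pearson correlation
#' between the gene's (processed) expression column and the X-score `t_c`.
#' Each loading is tested with the usual t statistic
#' `rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided); p-values are BH-adjusted across all (gene, component) pairs.
#' A gene whose loading reaches `q < alpha1` on no component has no
#' model support at all: its coefficients are zeroed. Genes retained on at
#' least one component keep their full summed coefficients — zeroing single
#' retained components would subtract real rank-1 coefficient mass and
#' systematically distort the surviving coefficient vectors (the projection
#' weights can be large even when a loading is small), which fabricates
#' spurious structure downstream; the magnitude of every individual
#' (type, gene) coefficient is instead vetted by the step-two permutation
#' test.
#'
#' @param fit A [fit_pls()] object.
#' @param Y The response matrix the fit was computed on.
#' @param alpha1 FDR level of the first step (default 0.05).
#' @return List with `loadings` and `q` (H x C matrices), the logical
#'   `retained` mask, and `W_candidate` (L x H summed coefficients after
#'   masking).
#' @export
loading_significance_test <- function(fit, Y, alpha1 = 0.05) {
  stopifnot(inherits(fit, "pls_fit"))
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n <= 2) .stopf("loading test needs more than 2 cells")
  rho <- suppressWarnings(stats::cor(Y, fit$T))       # H x C
  rho[!is.finite(rho)] <- 0                           # constant columns
  r2 <- pmin(rho^2, 1)
  tstat <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  q <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  retained <- q < alpha1

  W_candidate <- fit$W_sum
  W_candidate[, rowSums(retained) == 0] <- 0
  list(loadings = rho, q = q, retained = retained, W_candidate = W_candidate)
}

#' Step-two filter: permutation test of summed coefficients
#'
#' Builds a permutation null by shuffling the rows of the predictor block —
#' breaking the cell-to-neighborhood linkage while preserving both marginal
#' structures — refitting the PLS model at the already-selected component
#' count, and recording the summed coefficients of each permuted fit. The
#' two-sided p-value of entry (f, h) is
#' `(1 + #\{|w_perm| >= |w_obs|\}) / (1 + n_perm)`, where `w_obs` is the
#' step-one-masked summed coefficient. P-values are BH-adjusted across the
#' full L x H coefficient matrix and entries failing `q < alpha2` are set to
#' exactly zero. Entries already zeroed by step one have `p = 1` by
#' construction and can never re-enter.
#'
#' @param W_candidate Step-one-masked summed coefficients (L x H).
#' @param X,Y The blocks the observed model was fitted on.
#' @param ncomp Component count of the observed fit (held fixed in refits).
#' @param n_perm Number of permutations (default 999; below 99 the
#'   resolution of the p-values is warned about).
#' @param seed Integer seed for the permutation stream.
#' @param alpha2 FDR level of the second step (default 0.05).
#' @param tol,max_iter Passed to [fit_pls()] for the refits.
#' @param return_null Keep the n_perm x L x H array of permuted coefficients
#'   (for diagnostics/tests; default `FALSE`).
#' @return List with `p` and `q` (L x H matrices), `W_filtered` (L x H, zeros
#'   where filtered out), and optionally `null_coefficients`.
#' @export
coefficient_significance_test <- function(W_candidate, X, Y, ncomp,
                                          n_perm = 999L, seed = 1L,
                                          alpha2 = 0.05, tol = 1e-10,
                                          max_iter = 500L,
                                          return_null = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  W_candidate <- as.matrix(W_candidate)
  n <- nrow(X)
  if (n_perm < 99) warning("n_perm < 99 limits the attainable p-value resolution")
  set.seed(seed)
  exceed <- matrix(0L, nrow(W_candidate), ncol(W_candidate))
  absobs <- abs(W_candidate)
  null_arr <- if (return_null) {
    array(NA_real_, dim = c(n_perm, nrow(W_candidate), ncol(W_candidate)))
  }
  for (r in seq_len(n_perm)) {
    Xp <- X[sample.int(n), , drop = FALSE]
    pf <- fit_pls(Xp, Y, ncomp = ncomp, tol = tol, max_iter = max_iter)
    exceed <- exceed + (abs(pf$W_sum) >= absobs)
    if (return_null) null_arr[r, , ] <- pf$W_sum
  }
  p <- (1 + exceed) / (1 + n_perm)
  dimnames(p) <- dimnames(W_candidate)
  q <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  W_filtered <- W_candidate
  W_filtered[q >= alpha2] <- 0
  out <- list(p = p, q = q, W_filtered = W_filtered)
  if (return_null) out$null_coefficients <- null_arr
  out
}

#' Two-step coefficient filtering
#'
#' Runs [loading_significance_test()] followed by
#' [coefficient_significance_test()] and assembles the filtered coefficient
#' matrix. A coefficient is nonzero in the result only if its gene passed
#' the loading test for at least one retained component and the (neighbor
#' type, gene) pair passed the permutation test. The filter is a projection:
#' applying it to already-filtered coefficients changes nothing.
#'
#' @param fit A [fit_pls()] object.
#' @param X,Y The fitted blocks.
#' @param alpha1,alpha2 FDR levels of the two steps.
#' @param n_perm,seed Permutation settings for step two.
#' @param tol,max_iter Passed through to the refits.
#' @return An object of class `filtered_coefficients`: list with
#'   `W_filtered` (L x H), `step1_q` (H x C), `step2_q` (L x H), `alpha1`,
#'   `alpha2`, and `n_perm`.
#' @export
filter_coefficients <- function(fit, X, Y, alpha1 = 0.05, alpha2 = 0.05,
                                n_perm = 999L, seed = 1L,
                                tol = 1e-10, max_iter = 500L) {
  s1 <- loading_significance_test(fit, Y, alpha1 = alpha1)
  s2 <- coefficient_significance_test(s1$W_candidate, X, Y, ncomp = fit$C,
                                      n_perm = n_perm, seed = seed,
                                      alpha2 = alpha2, tol = tol,
                                      max_iter = max_iter)
  structure(list(W_filtered = s2$W_filtered, step1_q = s1$q, step2_q = s2$q,
                 alpha1 = alpha1, alpha2 = alpha2, n_perm = n_perm),
            class = "filtered_coefficients")
}

#' @export
print.filtered_coefficients <- function(x, ...) {
  nz <- colSums(x$W_filtered != 0)
  cat(sprintf("filtered_coefficients: %d x %d, %d nonzero entries, %d genes retained\n",
              nrow(x$W_filtered), ncol(x$W_filtered),
              sum(x$W_filtered != 0), sum(nz > 0)))
  invisible(x)
}
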