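#' Partial least squares regression by NIPALS
#'
#' Fits a PLS2 regression of a multi-column response on a (small) predictor
#' block by sequential NIPALS extraction: for each component, the inner
#' iteration alternates `w = X'u/||X'u||`, `t = Xw`, `c = Y't/t't`,
#' `u = Yc/c'c` to convergence; X is then deflated by `t p'` with
#' `p = X't/t't` and Y by `t c'`. Scores in `T` are mutually orthogonal, the
#' inner relation `U = TD + H` has diagonal `D`, and the summed coefficient
#' matrix equals the closed form `W = X'U (T'X X'U)^{-1} T'Y` evaluated on the
#' undeflated data. Per-component coefficient increments are the rank-1
#' updates `r_c c_c'` (with `R = W_x (P'W_x)^{-1}`), so predictions after c
#' components equal `X %*% rowSums(W_comp[, , 1:c])` by construction and
#' `W_sum = sum_c W_comp[, , c]` holds exactly.
#'
#' Both blocks must be column-centered (guaranteed upstream by z-scoring);
#' zero-variance predictor columns must be excluded before calling.
#' Extraction stops early (with fewer than `ncomp` components) when the
#' response residual is numerically exhausted, as happens for noiseless
#' low-rank data.
#'
#' @param X Centered predictor matrix, n x L (neighbor scores).
#' @param Y Centered response matrix, n x H (processed expression).
#' @param ncomp Number of components to extract (`<= min(L, n - 1)`).
#' @param tol Convergence tolerance of the inner iteration.
#' @param max_iter Maximum inner iterations per component; exceeding it is an
#'   error naming the component.
#' @return An object of class `pls_fit`: list with `C` (components actually
#'   extracted), score matrices `T` and `U` (n x C), loadings `P_load`
#'   (L x C) and `Q` (H x C), Y-side regression weights `Cq` (H x C),
#'   diagonal inner-relation matrix `D` (C x C), coefficient array `W_comp`
#'   (L x H x C), summed coefficients `W_sum` (L x H), and residual norms
#'   `residue_norms` for the X-residue E, Y-residue F, inner residue H and
#'   regression residue G.
#' @export
fit_pls <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); L <- ncol(X); H <- ncol(Y)
  if (nrow(Y) != n) .stopf("X and Y must have the same number of rows")
  if (ncomp < 1) .stopf("ncomp must be >= 1")
  if (ncomp > min(L, n - 1)) {
    .stopf("ncomp = %d exceeds min(L = %d, n - 1 = %d)", ncomp, L, n - 1)
  }

  Tm <- matrix(0, n, ncomp); Um <- matrix(0, n, ncomp)
  Pm <- matrix(0, L, ncomp); Qm <- matrix(0, H, ncomp)
  Cm <- matrix(0, H, ncomp); Wx <- matrix(0, L, ncomp)
  Xc <- X; Yc <- Y
  y_scale <- sum(Y^2)
  actual <- 0L
  for (comp in seq_len(ncomp)) {
    if (sum(Yc^2) <= max(y_scale, 1) * 1e-24) break  # response exhausted
    S <- crossprod(Xc, Yc)                           # L x H cross-covariance
    if (sum(S^2) <= 1e-28 * max(1, sum(Xc^2)) * max(1, sum(Yc^2))) break
    # The classical inner loop (u -> w -> t -> c -> u) is a power iteration
    # on the L x L matrix S S'; its fixed point is the dominant left
    # singular vector of S. With L small we take that fixed point from a
    # direct symmetric eigen-solve — immune to the slow convergence the
    # plain iteration suffers when singular values are nearly degenerate —
    # and then run the documented iteration from there until the update is
    # below `tol` (one pass away from a fixed point; ties aside).
    ev <- eigen(tcrossprod(S), symmetric = TRUE)
    w <- ev$vectors[, 1]
    if (w[which.max(abs(w))] < 0) w <- -w   # deterministic sign convention
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- drop(S %*% crossprod(S, w))
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) { w_new <- w; converged <- TRUE; break }
      w_new <- w_new / nw
      if (w_new[which.max(abs(w_new))] < 0) w_new <- -w_new
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; converged <- TRUE; break }
      w <- w_new
    }
    if (!converged) {
      .stopf("NIPALS inner iteration did not converge for component %d (max_iter = %d)",
             comp, max_iter)
    }
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 <= 0) break
    cc <- drop(crossprod(Yc, tt)) / tt2
    u <- drop(Yc %*% cc) / sum(cc^2)
    p <- drop(crossprod(Xc, tt)) / tt2
    q <- drop(crossprod(Yc, u))
    qn <- sqrt(sum(q^2)); if (qn > 0) q <- q / qn

    actual <- comp
    Tm[, comp] <- tt; Um[, comp] <- u; Pm[, comp] <- p
    Cm[, comp] <- cc; Wx[, comp] <- w; Qm[, comp] <- q
    Xc <- Xc - tcrossprod(tt, p)
    Yc <- Yc - tcrossprod(tt, cc)
  }
  if (actual == 0L) .stopf("no PLS component could be extracted (X'Y is null)")

  idx <- seq_len(actual)
  Tm <- Tm[, idx, drop = FALSE]; Um <- Um[, idx, drop = FALSE]
  Pm <- Pm[, idx, drop = FALSE]; Qm <- Qm[, idx, drop = FALSE]
  Cm <- Cm[, idx, drop = FALSE]; Wx <- Wx[, idx, drop = FALSE]

  # rank-1 coefficient increments: R = Wx (P'Wx)^{-1}, B_c = r_c c_c'
  R <- Wx %*% solve(crossprod(Pm, Wx))
  W_comp <- array(0, dim = c(L, ncol(Y), actual),
                  dimnames = list(colnames(X), colnames(Y), NULL))
  for (comp in idx) W_comp[, , comp] <- tcrossprod(R[, comp], Cm[, comp])
  W_sum <- apply(W_comp, c(1, 2), sum)

  d <- colSums(Tm * Um) / colSums(Tm^2)
  fit <- list(
    C = actual, T = Tm, U = Um, P_load = Pm, Q = Qm, Cq = Cm, W_x = Wx,
    D = diag(d, nrow = actual), W_comp = W_comp, W_sum = W_sum,
    residue_norms = c(
      E = sqrt(sum(Xc^2)), F = sqrt(sum(Yc^2)),
      H = sqrt(sum((Um - Tm %*% diag(d, nrow = actual))^2)),
      G = sqrt(sum((Y - X %*% W_sum)^2))
    ),
    requested = as.integer(ncomp)
  )
  class(fit) <- "pls_fit"
  fit
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d component(s) (%d requested), %d predictors, %d responses\n",
              x$C, x$requested, nrow(x$W_sum), ncol(x$W_sum)))
  cat(sprintf("  |G| residual norm: %.4g\n", x$residue_norms[["G"]]))
  invisible(x)
}

#' Predict from a PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Predictor matrix on the same (centered) scale as the
#'   training block.
#' @param ncomp Number of leading components to use (default: all extracted).
#' @param ... Unused.
#' @return Fitted response matrix `newdata %*% sum_{c<=ncomp} W_comp[,,c]`.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$C, ...) {
  ncomp <- min(ncomp, object$C)
  B <- apply(object$W_comp[, , seq_len(ncomp), drop = FALSE], c(1, 2), sum)
  as.matrix(newdata) %*% B
}

#' Choose the number of PLS components by cross-validation
#'
#' Assigns cells to folds by a seeded shuffle, fits the model on each
#' training split (re-centered with the training means), and scores the mean
#' squared prediction error of the held-out cells for every candidate
#' component count. The count minimizing the mean CV-MSE is returned; ties
#' (within `1e-12`) go to the smaller count.
#'
#' @param X,Y Centered predictor and response blocks.
#' @param folds Number of CV folds (default 10). If `n < folds` the fold
#'   count is reduced to `n` with a warning (leave-one-out).
#' @param c_max Largest candidate component count; capped at
#'   `min(ncol(X), n - ceiling(n/folds) - 1)` so every training split can
#'   support the fit.
#' @param seed Integer seed for the fold shuffle.
#' @param tol,max_iter Passed to [fit_pls()].
#' @return An object of class `cv_selection`: list with `candidates`,
#'   `cv_mse` (mean CV-MSE per candidate), `C` (chosen count), `folds`,
#'   and `seed`.
#' @export
select_num_components <- function(X, Y, folds = 10L, c_max = NULL, seed = 1L,
                                  tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) .stopf("need at least 3 cells for cross-validation")
  if (n < folds) {
    warning(sprintf("n = %d < folds = %d; using leave-one-out (%d folds)",
                    n, folds, n))
    folds <- n
  }
  max_test <- ceiling(n / folds)
  cap <- min(ncol(X), n - max_test - 1)
  if (is.null(c_max)) c_max <- min(ncol(X), 10L)
  c_max <- max(1L, min(c_max, cap))
  candidates <- seq_len(c_max)

  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  sse <- matrix(NA_real_, folds, c_max)
  for (k in seq_len(folds)) {
    te <- fold_id == k
    Xtr <- X[!te, , drop = FALSE]; Ytr <- Y[!te, , drop = FALSE]
    xm <- colMeans(Xtr); ym <- colMeans(Ytr)
    Xtr <- sweep(Xtr, 2, xm); Ytr <- sweep(Ytr, 2, ym)
    fit <- fit_pls(Xtr, Ytr, ncomp = c_max, tol = tol, max_iter = max_iter)
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    Yte <- Y[te, , drop = FALSE]
    B <- matrix(0, ncol(X), ncol(Y))
    for (cc in candidates) {
      if (cc <= fit$C) B <- B + fit$W_comp[, , cc]
      pred <- sweep(Xte %*% B, 2, ym, "+")
      sse[k, cc] <- mean((Yte - pred)^2)
    }
  }
  cv_mse <- colMeans(sse)
  best <- min(cv_mse)
  chosen <- candidates[which(cv_mse <= best + 1e-12)[1]]
  structure(list(candidates = candidates, cv_mse = cv_mse, C = chosen,
                 folds = folds, seed = seed),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("cv_selection: C = %d chosen from 1..%d (%d-fold)\n",
              x$C, max(x$candidates), x$folds))
  cat("  mean CV-MSE:", paste(sprintf("%.4g", x$cv_mse), collapse = ", "), "\n")
  invisible(x)
}
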