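# Shared fixture builders. Everything is generated in code under fixed seeds.

# Small count-scale dataset with random geometry; used by IO/preprocess tests.
make_toy_dataset <- function(n = 30, g = 8, n_types = 2, seed = 1,
                             lambda = 4) {
  set.seed(seed)
  expr <- matrix(rpois(n * g, lambda), n, g,
                 dimnames = list(paste0("c", seq_len(n)),
                                 paste0("g", seq_len(g))))
  coords <- cbind(x = runif(n), y = runif(n))
  labels <- sample(LETTERS[seq_len(n_types)], n, replace = TRUE)
  # guarantee every type is present
  labels[seq_len(n_types)] <- LETTERS[seq_len(n_types)]
  spatial_dataset(expr, coords, labels)
}

# Centered random regression blocks for PLS tests.
make_pls_blocks <- function(n = 20, L = 3, H = 5, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * L), n, L), scale = FALSE)
  Y <- scale(matrix(rnorm(n * H), n, H), scale = FALSE)
  dimnames(X) <- list(NULL, paste0("f", seq_len(L)))
  dimnames(Y) <- list(NULL, paste0("h", seq_len(H)))
  list(X = X, Y = Y)
}

# Independent oracle: the printed PLS coefficient closed form evaluated with
# dense linear algebra from a fit's scores and the undeflated blocks.
closed_form_W <- function(fit, X, Y) {
  crossprod(X, fit$U) %*%
    solve(t(fit$T) %*% X %*% crossprod(X, fit$U)) %*%
    crossprod(fit$T, Y)
}

# Independent oracle: textbook step-up BH adjustment over sorted p * m / rank.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Independent oracle: ARI from the contingency-table closed form.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
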