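test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_stepup_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(6)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("loading test retains perfect correlates and matches a beta-tail oracle", {
  b <- make_pls_blocks(n = 30, L = 3, H = 6, seed = 41)
  Y <- b$Y + b$X %*% matrix(rnorm(18), 3, 6)
  fit <- fit_pls(b$X, Y, ncomp = 2)

  # a response column that IS a score has loading 1 and is always retained
  Y2 <- Y
  Y2[, 1] <- fit$T[, 1]
  s1 <- loading_significance_test(fit, Y2, alpha1 = 0.05)
  expect_equal(unname(s1$loadings[1, 1]), 1)
  expect_true(s1$retained[1, 1])

  # p-values agree with the incomplete-beta form of the correlation test:
  # two-sided p = pbeta(1 - r^2, (n - 2)/2, 1/2)
  n <- nrow(Y)
  rho <- cor(Y, fit$T)
  p_oracle <- pbeta(1 - rho^2, (n - 2) / 2, 0.5)
  tstat <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  p_impl <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  expect_equal(p_impl, p_oracle, tolerance = 1e-10)
})

test_that("an independent noise response is filtered out by the loading test", {
  set.seed(55)
  n <- 100
  X <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  Y <- scale(matrix(rnorm(n * 10), n, 10), scale = FALSE)
  signal <- X %*% matrix(c(rep(2, 3), rep(0, 27)), 3, 10)  # only column 1 real
  fit <- fit_pls(X, Y + signal, ncomp = 2)
  s1 <- loading_significance_test(fit, Y + signal)
  expect_true(any(s1$retained[1, ]))           # the real gene survives
  expect_lt(mean(s1$retained[-1, ]), 0.25)     # noise genes mostly filtered
})

test_that("permutation p-values equal an exhaustive hand count of the recorded draws", {
  set.seed(3)
  n <- 12
  x <- matrix(scale(rnorm(n), scale = FALSE), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- matrix(scale(2 * x + 0.3 * rnorm(n), scale = FALSE), ncol = 1,
              dimnames = list(NULL, "h1"))
  w_obs <- matrix(drop(crossprod(x, y)) / sum(x^2), 1, 1,
                  dimnames = list("f1", "h1"))
  res <- suppressWarnings(
    coefficient_significance_test(w_obs, x, y, ncomp = 1, n_perm = 4,
                                  seed = 99, return_null = TRUE))

  # oracle: replay the seeded permutation stream and compute the univariate
  # slope of each permuted predictor by hand
  set.seed(99)
  exceed <- 0
  for (r in 1:4) {
    xp <- x[sample.int(n), , drop = FALSE]
    slope <- drop(crossprod(xp, y)) / sum(xp^2)
    exceed <- exceed + (abs(slope) >= abs(w_obs[1, 1]))
    expect_equal(res$null_coefficients[r, 1, 1], slope, tolerance = 1e-10)
  }
  expect_equal(res$p[1, 1], (1 + exceed) / 5)
})

test_that("a planted strong effect attains the minimal permutation p-value", {
  set.seed(60)
  n <- 100
  X <- scale(matrix(rnorm(n * 2), n, 2), scale = FALSE)
  colnames(X) <- c("f1", "f2")
  Y <- X %*% rbind(c(1, 0), c(0, 0)) + 0.1 * matrix(rnorm(n * 2), n, 2)
  colnames(Y) <- c("h1", "h2")
  Y <- scale(Y, scale = FALSE)
  fit <- fit_pls(X, Y, ncomp = 2)
  res <- coefficient_significance_test(fit$W_sum, X, Y, ncomp = 2,
                                       n_perm = 199, seed = 5)
  expect_equal(res$p["f1", "h1"], 1 / 200)
  expect_lt(res$q["f1", "h1"], 0.05)
  expect_equal(res$W_filtered["f1", "h1"], fit$W_sum["f1", "h1"])
})

test_that("under a global null the filter reports (almost) nothing", {
  nonzero_frac <- vapply(1:20, function(rep) {
    set.seed(700 + rep)
    n <- 50
    X <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
    Y <- scale(matrix(rnorm(n * 15), n, 15), scale = FALSE)
    fit <- fit_pls(X, Y, ncomp = 2)
    filt <- suppressWarnings(filter_coefficients(fit, X, Y, n_perm = 60,
                                                 seed = rep))
    mean(filt$W_filtered != 0)
  }, 0)
  # expected nonzero fraction bounded by the step-2 FDR level
  expect_lte(mean(nonzero_frac), 0.05 * 1.5)
})

test_that("filtering is a projection: refiltering filtered coefficients is a no-op", {
  set.seed(91)
  n <- 60
  X <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  colnames(X) <- paste0("f", 1:3)
  B <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 0))
  Y <- X %*% B + 0.3 * matrix(rnorm(n * 4), n, 4)
  colnames(Y) <- paste0("h", 1:4)
  Y <- scale(Y, scale = FALSE)
  fit <- fit_pls(X, Y, ncomp = 3)
  s1 <- loading_significance_test(fit, Y)
  first <- coefficient_significance_test(s1$W_candidate, X, Y, ncomp = 3,
                                         n_perm = 99, seed = 8)
  second <- coefficient_significance_test(first$W_filtered, X, Y, ncomp = 3,
                                          n_perm = 99, seed = 8)
  expect_identical(second$W_filtered, first$W_filtered)
})

test_that("tiny permutation counts trigger the resolution warning", {
  x <- matrix(scale(rnorm(10), scale = FALSE), ncol = 1)
  y <- matrix(scale(rnorm(10), scale = FALSE), ncol = 1)
  w <- matrix(0.1, 1, 1)
  expect_warning(coefficient_significance_test(w, x, y, ncomp = 1,
                                               n_perm = 9, seed = 1),
                 "resolution")
})
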