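# Internal helpers shared across modules.

# Column z-score with sample sd. Constant columns (sd below `tol`) are set to
# zero and their names returned in the "degenerate" attribute so callers can
# drop or flag them.
.zscore_cols <- function(mat, tol = 1e-12) {
  mu <- colMeans(mat)
  sdev <- apply(mat, 2, stats::sd)
  degen <- sdev < tol | !is.finite(sdev)
  sdev[degen] <- 1
  out <- sweep(sweep(mat, 2, mu, "-"), 2, sdev, "/")
  out[, degen] <- 0
  attr(out, "degenerate") <- colnames(mat)[degen]
  out
}

# Deterministic substream seeds: one global seed in the config is split into
# per-(unit, step) seeds so CV folds, permutations and k-means restarts are
# reproducible independently of evaluation order. Kept below 2^31 - 1.
.derive_seed <- function(seed, unit, step) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (tok in c(unit, step)) {
    for (ch in utf8ToInt(as.character(tok))) {
      s <- (s * 48271 + ch) %% 2147483647
    }
  }
  as.integer(s)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
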