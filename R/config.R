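#' Pipeline configuration
#'
#' Builds the fully-resolved configuration for [run_nichepls()], merging
#' user-supplied values over the documented defaults. Unknown keys — at the
#' top level or inside the nested groups — are rejected, and every schema
#' violation is reported at once rather than first-error-only. Re-parsing a
#' resolved configuration returns it unchanged.
#'
#' Keys and defaults:
#' * `min_cells = 20`: smallest receiver type modeled (10-fold CV needs
#'   several cells per fold; smaller types are skipped with a reason).
#' * `normalize = "median_log1p"`: per-cell median-total scaling + log1p
#'   before z-scoring; `"none"` for data already on a processed scale.
#' * `hvg`: `method = "cv_residual"` (`"top_n"`, `"none"`),
#'   `quantile = 0.9`, `top_n = NULL`, `min_hvgs = 5`.
#' * `kernel = "exponential"`: distance-decay kernel of the neighbor score.
#' * `dist0 = "auto_min"`: decay length; `"auto_min"` or a positive number.
#' * `pls`: `folds = 10`, `c_max = NULL` (resolved per type to
#'   `min(L, 10)`), `tol = 1e-10`, `max_iter = 500`.
#' * `filter`: `alpha1 = 0.05`, `alpha2 = 0.05`, `n_perm = 999`.
#' * `cluster`: `kmin = 2`, `kmax = 15`, `nstart = 10`.
#' * `cell_types = NULL`: subset of receiver types to model (default all).
#' * `seed = 1`: single global seed, split deterministically into per-step
#'   substreams.
#'
#' @param ... Named overrides; nested groups given as named lists, e.g.
#'   `filter = list(n_perm = 199)`.
#' @return An object of class `nichepls_config` (a named list).
#' @export
nichepls_config <- function(...) {
  defaults <- list(
    min_cells = 20L,
    normalize = "median_log1p",
    hvg = list(method = "cv_residual", quantile = 0.9, top_n = NULL,
               min_hvgs = 5L),
    kernel = "exponential",
    dist0 = "auto_min",
    pls = list(folds = 10L, c_max = NULL, tol = 1e-10, max_iter = 500L),
    filter = list(alpha1 = 0.05, alpha2 = 0.05, n_perm = 999L),
    cluster = list(kmin = 2L, kmax = 15L, nstart = 10L),
    cell_types = NULL,
    seed = 1L
  )
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) &&
      inherits(user[[1]], "nichepls_config")) {
    user <- unclass(user[[1]])
  }
  problems <- character()
  if (length(user) && (is.null(names(user)) || any(names(user) == ""))) {
    .stopf("all configuration values must be named")
  }
  bad_top <- setdiff(names(user), names(defaults))
  if (length(bad_top)) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(bad_top, collapse = ", ")))
  }
  cfg <- defaults
  for (key in intersect(names(user), names(defaults))) {
    val <- user[[key]]
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(val)) {
        problems <- c(problems, sprintf("`%s` must be a named list", key))
        next
      }
      bad_sub <- setdiff(names(val), names(defaults[[key]]))
      if (length(bad_sub)) {
        problems <- c(problems, sprintf("unknown key(s) under `%s`: %s", key,
                                        paste(bad_sub, collapse = ", ")))
      }
      for (sub in intersect(names(val), names(defaults[[key]]))) {
        cfg[[key]][sub] <- list(val[[sub]])   # keeps NULL-valued fields
      }
    } else {
      cfg[key] <- list(val)
    }
  }

  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$min_cells) && cfg$min_cells >= 3,
      "`min_cells` must be a number >= 3")
  chk(cfg$normalize %in% c("median_log1p", "none"),
      "`normalize` must be \"median_log1p\" or \"none\"")
  chk(cfg$hvg$method %in% c("cv_residual", "top_n", "none"),
      "`hvg$method` must be \"cv_residual\", \"top_n\" or \"none\"")
  chk(is.numeric(cfg$hvg$quantile) && cfg$hvg$quantile > 0 && cfg$hvg$quantile < 1,
      "`hvg$quantile` must be in (0, 1)")
  chk(cfg$hvg$method != "top_n" ||
        (is.numeric(cfg$hvg$top_n) && cfg$hvg$top_n >= 1),
      "`hvg$top_n` must be >= 1 when `hvg$method` is \"top_n\"")
  chk(is.numeric(cfg$hvg$min_hvgs) && cfg$hvg$min_hvgs >= 1,
      "`hvg$min_hvgs` must be >= 1")
  chk(cfg$kernel %in% c("exponential", "gaussian"),
      "`kernel` must be \"exponential\" or \"gaussian\"")
  chk(identical(cfg$dist0, "auto_min") ||
        (is.numeric(cfg$dist0) && cfg$dist0 > 0),
      "`dist0` must be \"auto_min\" or a positive number")
  chk(is.numeric(cfg$pls$folds) && cfg$pls$folds >= 2,
      "`pls$folds` must be >= 2")
  chk(is.null(cfg$pls$c_max) || (is.numeric(cfg$pls$c_max) && cfg$pls$c_max >= 1),
      "`pls$c_max` must be NULL or >= 1")
  chk(is.numeric(cfg$pls$tol) && cfg$pls$tol > 0, "`pls$tol` must be > 0")
  chk(is.numeric(cfg$pls$max_iter) && cfg$pls$max_iter >= 1,
      "`pls$max_iter` must be >= 1")
  for (a in c("alpha1", "alpha2")) {
    chk(is.numeric(cfg$filter[[a]]) && cfg$filter[[a]] > 0 && cfg$filter[[a]] < 1,
        sprintf("`filter$%s` must be in (0, 1)", a))
  }
  chk(is.numeric(cfg$filter$n_perm) && cfg$filter$n_perm >= 1,
      "`filter$n_perm` must be >= 1")
  chk(is.numeric(cfg$cluster$kmin) && cfg$cluster$kmin >= 2,
      "`cluster$kmin` must be >= 2")
  chk(is.numeric(cfg$cluster$kmax) && cfg$cluster$kmax >= cfg$cluster$kmin,
      "`cluster$kmax` must be >= `cluster$kmin`")
  chk(is.numeric(cfg$cluster$nstart) && cfg$cluster$nstart >= 1,
      "`cluster$nstart` must be >= 1")
  chk(is.null(cfg$cell_types) || is.character(cfg$cell_types),
      "`cell_types` must be NULL or a character vector")
  chk(is.numeric(cfg$seed) && is.finite(cfg$seed),
      "`seed` must be a finite number")

  if (length(problems)) {
    .stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "nichepls_config")
}

#' @export
print.nichepls_config <- function(x, ...) {
  cat("nichepls_config:\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
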