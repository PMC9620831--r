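#' Split expression by cell type
#'
#' Partitions the expression matrix into one submatrix per cell type. The
#' union of rows over all submatrices is the full matrix; no cell appears
#' twice.
#'
#' @param ds A [spatial_dataset()].
#' @return Named list of expression submatrices, one per cell-type level.
#' @export
split_by_cell_type <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  lapply(stats::setNames(nm = levels(ds$labels)), function(m) {
    ds$expression[ds$labels == m, , drop = FALSE]
  })
}

#' Drop genes that are zero in every cell
#'
#' Removes columns whose entries are all zero within the given (per-cell-type)
#' submatrix, preserving column order.
#'
#' @param mat Non-negative expression submatrix (cells x genes).
#' @return The matrix restricted to genes with at least one positive entry,
#'   with attribute `"dropped"` listing removed gene ids. A zero-column matrix
#'   is returned (not an error) when every gene is all-zero; callers skip the
#'   cell type in that case.
#' @export
drop_all_zero_genes <- function(mat) {
  keep <- colSums(mat != 0) > 0
  out <- mat[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(mat)[!keep]
  out
}

#' Normalize and z-score an expression submatrix
#'
#' Standard per-cell-type preprocessing: (a) per-cell library-size scaling to
#' the median per-cell total, (b) `log(1 + x)`, (c) per-gene z-score. With
#' `normalize = "none"` the input is taken to be on a processed scale already
#' (e.g. simulated standardized data): scaling, log transform and per-gene
#' rescaling are all bypassed and columns are only mean-centered — idempotent
#' for already-standardized input and required by the downstream regression —
#' so that per-gene coefficient magnitudes are preserved. In both modes,
#' genes that are constant (no usable variation) are dropped and listed in
#' the `"dropped_constant"` attribute.
#'
#' @param mat Zero-filtered expression submatrix (cells x genes).
#' @param normalize `"median_log1p"` (default) or `"none"`.
#' @return Processed matrix (columns mean 0; additionally sd 1 under
#'   `"median_log1p"`) with attribute `"dropped_constant"`.
#' @export
normalize_log_zscore <- function(mat, normalize = c("median_log1p", "none")) {
  normalize <- match.arg(normalize)
  if (normalize == "median_log1p") {
    totals <- rowSums(mat)
    sf <- totals / stats::median(totals)
    sf[!is.finite(sf) | sf <= 0] <- 1  # all-zero cells left untouched
    out <- .zscore_cols(log1p(mat / sf))
  } else {
    sdev <- apply(mat, 2, stats::sd)
    degen_mask <- sdev < 1e-12 | !is.finite(sdev)
    out <- sweep(mat, 2, colMeans(mat), "-")
    out[, degen_mask] <- 0
    attr(out, "degenerate") <- colnames(mat)[degen_mask]
  }
  degen <- attr(out, "degenerate")
  keep <- setdiff(colnames(out), degen)
  res <- out[, keep, drop = FALSE]
  attr(res, "dropped_constant") <- degen
  res
}

#' Select highly variable genes within one cell type
#'
#' `method = "cv_residual"` regresses log CV-squared on log mean expression
#' across genes and selects genes whose residual exceeds the given quantile —
#' i.e. genes more dispersed than expected for their mean. `method = "top_n"`
#' simply takes the `n` genes of highest CV-squared. `method = "none"` returns
#' all genes (used for data simulated directly on the processed scale, where
#' every gene is treated as highly variable). All methods are deterministic.
#'
#' @param mat Zero-filtered raw expression submatrix (cells x genes).
#' @param method `"cv_residual"`, `"top_n"`, or `"none"`.
#' @param quantile Residual quantile above which a gene is selected
#'   (default 0.90).
#' @param top_n Number of genes for `method = "top_n"`.
#' @return Character vector of selected gene ids (in input column order).
#' @export
select_hvgs <- function(mat, method = c("cv_residual", "top_n", "none"),
                        quantile = 0.90, top_n = NULL) {
  method <- match.arg(method)
  genes <- colnames(mat)
  if (method == "none") return(genes)
  if (ncol(mat) < 2 || nrow(mat) < 3) {
    .stopf("HVG selection needs at least 2 genes and 3 cells (got %d x %d)",
           nrow(mat), ncol(mat))
  }
  mu <- colMeans(mat)
  v <- apply(mat, 2, stats::var)
  cv2 <- v / mu^2
  if (method == "top_n") {
    if (is.null(top_n)) .stopf("method = \"top_n\" requires top_n")
    top_n <- min(top_n, length(genes))
    ord <- order(cv2, decreasing = TRUE)
    return(genes[sort(ord[seq_len(top_n)])])
  }
  usable <- is.finite(log(cv2)) & mu > 0
  res <- rep(-Inf, length(genes))
  fit <- stats::lm(log(cv2[usable]) ~ log(mu[usable]))
  res[usable] <- stats::residuals(fit)
  thr <- stats::quantile(res[usable], quantile)
  genes[res > thr]
}

#' Pairwise overlap ratio of HVG sets
#'
#' For cell types a and b with HVG sets A and B the overlap ratio is
#' `|A intersect B| / min(|A|, |B|)`. Used to assess how cell-type-specific
#' the selected gene sets are.
#'
#' @param hvg_lists Named list of character vectors of gene ids.
#' @return Symmetric matrix of overlap ratios with unit diagonal.
#' @export
hvg_overlap_ratio <- function(hvg_lists) {
  m <- length(hvg_lists)
  out <- matrix(NA_real_, m, m, dimnames = list(names(hvg_lists), names(hvg_lists)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      a <- hvg_lists[[i]]; b <- hvg_lists[[j]]
      denom <- min(length(a), length(b))
      out[i, j] <- if (denom == 0) NA_real_ else length(intersect(a, b)) / denom
    }
  }
  out
}
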