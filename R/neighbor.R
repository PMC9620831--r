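#' Minimum positive pairwise distance
#'
#' The decay length scale of the neighbor-score kernel: the smallest positive
#' Euclidean distance between any two cells, computed once on the full
#' coordinate matrix (not per cell type). Zero-distance pairs (duplicated
#' coordinates, which occur in spot-based exports) are excluded from the
#' minimum so that the kernel stays well defined.
#'
#' @param coords Numeric N x 2 coordinate matrix, N >= 2.
#' @return A positive scalar.
#' @export
min_pairwise_distance <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) .stopf("need at least 2 cells to compute a distance")
  d <- stats::dist(coords)
  pos <- d[d > 0]
  if (!length(pos)) .stopf("all pairwise distances are zero: degenerate geometry")
  min(pos)
}

#' Raw neighboring cell-type scores
#'
#' For every cell i and cell type f, sums a distance-decay kernel over all
#' other cells j of type f: `sum_j exp(-d(i,j)/dist0)` (exponential decay,
#' the default) or `sum_j exp(-(d(i,j)/dist0)^2)` (squared-exponential).
#' The sum runs over all cells j != i regardless of the receiver's own type;
#' a cell's own type is a valid neighbor type (self-type signaling is
#' biologically meaningful). Coincident cells (d = 0) contribute exp(0) = 1.
#'
#' @param coords Numeric N x 2 coordinate matrix.
#' @param labels Cell-type factor (or character) of length N.
#' @param dist0 Positive decay length, typically [min_pairwise_distance()].
#' @param kernel `"exponential"` (default) or `"gaussian"`.
#' @return N x M non-negative matrix; rows named by cells, columns by the M
#'   cell-type levels.
#' @export
raw_neighbor_scores <- function(coords, labels, dist0,
                                kernel = c("exponential", "gaussian")) {
  kernel <- match.arg(kernel)
  coords <- as.matrix(coords)
  labels <- factor(labels)
  n <- nrow(coords)
  if (length(labels) != n) .stopf("labels length must match coordinate rows")
  if (!is.numeric(dist0) || dist0 <= 0) .stopf("dist0 must be a positive number")
  d <- as.matrix(stats::dist(coords))
  k <- if (kernel == "exponential") exp(-d / dist0) else exp(-(d / dist0)^2)
  diag(k) <- 0  # j != i: a cell is not its own neighbor
  memb <- stats::model.matrix(~ labels - 1)
  colnames(memb) <- levels(labels)
  out <- k %*% memb
  dimnames(out) <- list(rownames(coords), levels(labels))
  out
}

#' Z-score neighbor scores within a receiver cell type
#'
#' Column-wise z-score of the raw score rows belonging to one receiver cell
#' type. Neighbor types whose score is constant across the receiver's cells
#' carry no information for regression: their column is set to zero and the
#' type is listed in the `"degenerate"` attribute so the caller can exclude
#' it from the predictor set.
#'
#' @param raw Raw score rows for the receiver type's cells (N_m x M).
#' @return Z-scored matrix of the same shape with attribute `"degenerate"`.
#' @export
zscore_neighbor_scores <- function(raw) {
  if (nrow(raw) < 2) .stopf("need at least 2 receiver cells to z-score scores")
  .zscore_cols(raw)
}

#' Neighbor score matrix for one receiver cell type
#'
#' Convenience wrapper running the full scoring pipeline: kernel scores on
#' all cells, then within-type z-scoring for the requested receiver type.
#'
#' @param ds A [spatial_dataset()].
#' @param receiver Cell-type level to model.
#' @param dist0 `"auto_min"` (default) or a fixed positive number.
#' @param kernel Passed to [raw_neighbor_scores()].
#' @return List with `raw` (receiver rows of the raw scores), `scored`
#'   (z-scored predictors), `dist0`, `degenerate` (dropped neighbor types)
#'   and `receiver`.
#' @export
neighbor_score_matrix <- function(ds, receiver, dist0 = "auto_min",
                                  kernel = c("exponential", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!receiver %in% levels(ds$labels)) .stopf("unknown cell type: %s", receiver)
  d0 <- if (identical(dist0, "auto_min")) {
    min_pairwise_distance(ds$coordinates)
  } else {
    as.numeric(dist0)
  }
  raw_all <- raw_neighbor_scores(ds$coordinates, ds$labels, d0, kernel)
  raw <- raw_all[ds$labels == receiver, , drop = FALSE]
  scored <- zscore_neighbor_scores(raw)
  list(raw = raw, scored = scored, dist0 = d0,
       degenerate = attr(scored, "degenerate"), receiver = receiver)
}
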