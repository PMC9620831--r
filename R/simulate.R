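#' Default planted coefficient pattern
#'
#' The four-type, four-cluster design used throughout the simulation study:
#' cluster 1 is a multiple-input case (types A and C), clusters 2 and 3 are
#' single-input cases (B and C respectively), and cluster 4 receives no
#' neighbor effect. Entries are 0 or `w_max`.
#'
#' @param w_max Magnitude of the planted nonzero coefficients.
#' @return 4 x 4 matrix (neighbor types A-D x gene clusters 1-4).
#' @export
default_coefficient_table <- function(w_max = 1) {
  tab <- rbind(
    A = c(1, 0, 0, 0),
    B = c(0, 1, 0, 0),
    C = c(1, 0, 1, 0),
    D = c(0, 0, 0, 0)
  ) * w_max
  colnames(tab) <- paste0("cluster", 1:4)
  tab
}

#' Simulate cell coordinates and type labels
#'
#' Places cells uniformly on the unit square under a minimum-separation
#' rejection rule (no coincident cells) and assigns type labels i.i.d. with
#' the given frequencies. If any type ends up unrepresented the labels are
#' redrawn (the planted design needs every type present).
#'
#' @param n_cells Number of cells (>= 2 per type).
#' @param type_labels Character vector of type names (default A-D).
#' @param freqs Type frequencies (default equal).
#' @param min_sep Minimum allowed separation; default `0.4 / sqrt(n_cells)`,
#'   comfortably below the typical nearest-neighbor spacing at that density.
#' @param max_attempts Rejection-sampling budget per cell.
#' @param seed Integer seed.
#' @return List with `coordinates` (n x 2 matrix) and `labels` (factor).
#' @export
simulate_coordinates <- function(n_cells, type_labels = LETTERS[1:4],
                                 freqs = NULL, min_sep = NULL,
                                 max_attempts = 200L, seed = 1L) {
  n_types <- length(type_labels)
  if (n_cells < 2 * n_types) .stopf("n_cells must be at least 2 per type")
  if (is.null(freqs)) freqs <- rep(1 / n_types, n_types)
  if (is.null(min_sep)) min_sep <- 0.4 / sqrt(n_cells)
  set.seed(seed)
  pts <- matrix(NA_real_, n_cells, 2)
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- stats::runif(2)
      if (i == 1) { ok <- TRUE } else {
        prev <- pts[seq_len(i - 1), , drop = FALSE]
        dmin <- sqrt(min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2))
        ok <- dmin >= min_sep
      }
      if (ok) { pts[i, ] <- cand; break }
    }
    if (!ok) .stopf("could not place cell %d after %d attempts; lower the density or min_sep",
                    i, max_attempts)
  }
  for (a in seq_len(100L)) {
    labels <- factor(sample(type_labels, n_cells, replace = TRUE, prob = freqs),
                     levels = type_labels)
    if (all(table(labels) > 0)) break
  }
  if (any(table(labels) == 0)) .stopf("failed to draw labels covering every type")
  rownames(pts) <- paste0("cell", seq_len(n_cells))
  names(labels) <- rownames(pts)
  list(coordinates = pts, labels = labels)
}

#' Simulate a spatial dataset with planted neighbor effects
#'
#' Generates expression directly on the processed (log/z) scale as
#' `Y = XW + alpha * E`: `X` is the full neighbor-score pipeline (kernel
#' scores with `dist0` equal to the minimum pairwise distance, z-scored
#' within each receiver type), `W` replicates the planted coefficient table
#' across `genes_per_cluster` genes per cluster, and `E` is per-gene noise.
#'
#' Gaussian noise draws `e_ih ~ N(0, sigma_h)` where the per-gene scale
#' comes from a parametric mean-CV model: gene means are log-normal
#' (`mu_meanlog`, `mu_sdlog`), `CV^2 = cv2_a / mu + cv2_b`, and the noise SD
#' on the processed scale is `sigma_h = CV_h` (delta method for the SD of a
#' log-transformed quantity). The gamma variant draws `Gamma(shape, scale)`
#' per entry, log-transforms and z-scores per gene, giving unit-SD skewed
#' noise. No count sampling is performed — the data are simulated on the
#' scale the regression sees.
#'
#' @param n_cells Number of cells (default 523).
#' @param genes_per_cluster Genes per planted cluster (default 500).
#' @param w_max Planted coefficient magnitude (default 1).
#' @param alpha Noise multiplier (default 1).
#' @param noise `"gaussian"` or `"gamma"`.
#' @param coefficient_table Types x clusters matrix of planted coefficients;
#'   default [default_coefficient_table()] at `w_max`.
#' @param type_labels,freqs,min_sep Passed to [simulate_coordinates()] when
#'   `coords` is not supplied.
#' @param coords,labels Optional user-provided geometry (pass-through mode).
#' @param kernel Neighbor-score kernel (default `"exponential"`).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of the gene means.
#' @param cv2_a,cv2_b Mean-CV curve `CV^2 = a / mu + b` (defaults 1, 0.1).
#' @param gamma_shape,gamma_scale Gamma-noise parameters (defaults 2, 1).
#' @param seed Integer seed for geometry, noise, and gene means.
#' @return List with `dataset` (a [spatial_dataset()] on the processed
#'   scale) and `truth`, an object of class `simulated_truth`: list with
#'   `W_true` (types x genes), `cluster` (named integer vector, 1-4),
#'   `sigma` (per-gene noise SD), `noise` (realized noise matrix), `X_scored`
#'   (the within-type z-scored score matrix used), `alpha`, `w_max`, and
#'   `vp` (variance-proportion index, see [compute_vp()]).
#' @export
simulate_spatial_dataset <- function(n_cells = 523L, genes_per_cluster = 500L,
                                     w_max = 1, alpha = 1,
                                     noise = c("gaussian", "gamma"),
                                     coefficient_table = NULL,
                                     type_labels = LETTERS[1:4], freqs = NULL,
                                     min_sep = NULL, coords = NULL,
                                     labels = NULL,
                                     kernel = c("exponential", "gaussian"),
                                     mu_meanlog = log(2), mu_sdlog = 0.5,
                                     cv2_a = 1, cv2_b = 0.1,
                                     gamma_shape = 2, gamma_scale = 1,
                                     seed = 1L) {
  noise <- match.arg(noise)
  kernel <- match.arg(kernel)
  if (is.null(coefficient_table)) {
    coefficient_table <- default_coefficient_table(w_max)
  }
  if (alpha < 0) .stopf("alpha must be non-negative")
  if (genes_per_cluster < 1) .stopf("genes_per_cluster must be >= 1")

  if (is.null(coords)) {
    geo <- simulate_coordinates(n_cells, type_labels = rownames(coefficient_table),
                                freqs = freqs, min_sep = min_sep, seed = seed)
    coords <- geo$coordinates; labels <- geo$labels
  } else {
    coords <- as.matrix(coords)
    labels <- factor(labels)
    n_cells <- nrow(coords)
    if (is.null(rownames(coords))) rownames(coords) <- paste0("cell", seq_len(n_cells))
    names(labels) <- rownames(coords)
  }
  types <- rownames(coefficient_table)
  if (!all(levels(labels) %in% types)) {
    .stopf("labels contain types absent from the coefficient table")
  }

  # full neighbor-score pipeline: dist0 on all cells, kernel scores,
  # z-scored within each receiver type
  d0 <- min_pairwise_distance(coords)
  raw <- raw_neighbor_scores(coords, labels, d0, kernel)
  X <- raw
  for (m in levels(labels)) {
    idx <- labels == m
    X[idx, ] <- zscore_neighbor_scores(raw[idx, , drop = FALSE])
  }

  n_clusters <- ncol(coefficient_table)
  G <- genes_per_cluster * n_clusters
  gene_ids <- sprintf("gene%04d", seq_len(G))
  cluster <- stats::setNames(rep(seq_len(n_clusters), each = genes_per_cluster),
                             gene_ids)
  W_true <- coefficient_table[, cluster, drop = FALSE]
  colnames(W_true) <- gene_ids

  set.seed(.derive_seed(seed, "noise", noise))
  mu <- stats::rlnorm(G, meanlog = mu_meanlog, sdlog = mu_sdlog)
  sigma <- sqrt(cv2_a / mu + cv2_b)
  names(sigma) <- gene_ids
  if (noise == "gaussian") {
    E <- matrix(stats::rnorm(n_cells * G), n_cells, G)
    E <- sweep(E, 2, sigma, "*")
  } else {
    E <- matrix(stats::rgamma(n_cells * G, shape = gamma_shape,
                              scale = gamma_scale), n_cells, G)
    E <- .zscore_cols(log(E))
    attr(E, "degenerate") <- NULL
  }
  dimnames(E) <- list(rownames(coords), gene_ids)

  signal <- X %*% W_true
  Y <- signal + alpha * E
  ds <- spatial_dataset(Y, coords, labels, gene_ids = gene_ids,
                        cell_ids = rownames(coords), scale = "processed")
  truth <- structure(list(
    W_true = W_true, cluster = cluster, sigma = sigma, noise = E,
    X_scored = X, alpha = alpha, w_max = w_max,
    coefficient_table = coefficient_table, dist0 = d0, seed = seed),
    class = "simulated_truth")
  truth$vp <- compute_vp(truth, X, Y)
  list(dataset = ds, truth = truth)
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf("simulated_truth: %d genes in %d clusters, w_max = %g, alpha = %g, VP = %.3f\n",
              length(x$cluster), max(x$cluster), x$w_max, x$alpha, x$vp))
  invisible(x)
}

#' Variance-proportion index of a simulated dataset
#'
#' For each affected gene (true coefficients not all zero) the variance
#' across cells of the planted model term `X w_h` is divided by the variance
#' of the simulated expression; the index is the mean of these ratios over
#' affected genes. It measures how much of the expression variability is
#' attributable to the neighbor effect rather than noise, and is the
#' difficulty dial of the simulation: recovery degrades as it approaches
#' zero.
#'
#' @param truth A `simulated_truth` object.
#' @param X Score matrix the data were generated from (defaults to
#'   `truth$X_scored`).
#' @param Y Simulated expression matrix.
#' @return Scalar in \[0, 1\].
#' @export
compute_vp <- function(truth, X = truth$X_scored, Y) {
  stopifnot(inherits(truth, "simulated_truth"))
  affected <- colSums(truth$W_true != 0) > 0
  if (!any(affected)) .stopf("no affected genes: VP is undefined")
  signal <- X %*% truth$W_true[, affected, drop = FALSE]
  y <- if (missing(Y)) signal + truth$alpha * truth$noise[, affected, drop = FALSE] else {
    as.matrix(Y)[, affected, drop = FALSE]
  }
  vs <- apply(signal, 2, stats::var)
  vy <- apply(y, 2, stats::var)
  mean(vs / vy)
}

#' Default (w_max, alpha) condition grid
#'
#' The 3 x 3 grid of simulation conditions spanning effect size and noise
#' level, from easy (strong effect, low noise) to failing (weak effect,
#' high noise). A harness for sweeps, not a claim about any particular
#' dataset.
#'
#' @return Data frame with columns `condition`, `w_max`, `alpha`.
#' @export
simulation_grid <- function() {
  g <- expand.grid(alpha = c(1, 2, 4), w_max = c(1, 0.5, 0.1))
  data.frame(condition = seq_len(nrow(g)), w_max = g$w_max, alpha = g$alpha)
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Writes the three standard input files (via [write_spatial_dataset()])
#' plus `truth.tsv` (gene, cluster, per-type planted coefficients) and
#' `sim_meta.json` (noise model, per-gene sigma summary, VP, seed).
#'
#' @param sim Result of [simulate_spatial_dataset()].
#' @param dir Output directory (created if missing).
#' @param format Expression format, `"csv"` or `"mtx"`.
#' @return Invisibly, the output directory.
#' @export
save_simulation <- function(sim, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spatial_dataset(sim$dataset, dir, format = format)
  truth <- data.frame(gene = names(sim$truth$cluster),
                      cluster = unname(sim$truth$cluster),
                      t(sim$truth$W_true), check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(alpha = sim$truth$alpha, w_max = sim$truth$w_max,
               dist0 = sim$truth$dist0, vp = sim$truth$vp,
               seed = sim$truth$seed,
               sigma_summary = unname(stats::quantile(sim$truth$sigma)))
  jsonlite::write_json(meta, file.path(dir, "sim_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
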