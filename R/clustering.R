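#' Cluster genes on their filtered coefficient profiles
#'
#' Genes whose filtered coefficients are all zero are removed first — they
#' carry no detected neighbor effect and are never reported. The remaining
#' genes are clustered by k-means on their coefficient column-vectors for
#' every candidate cluster number k, and the k with the largest mean
#' silhouette width (Euclidean distance) is chosen; ties go to the smaller
#' k. Cluster labels are renumbered by descending cluster size. With fewer
#' than two clusterable genes (or a single distinct profile) a degenerate
#' single-cluster result is returned and flagged.
#'
#' @param Wf A `filtered_coefficients` object or a plain L x H filtered
#'   coefficient matrix.
#' @param kmin,kmax Candidate range for k (defaults 2 and 15). `kmax` is
#'   clipped to one less than the number of distinct profiles.
#' @param nstart k-means restarts (default 10).
#' @param seed Integer seed for the k-means initializations.
#' @return An object of class `hvg_clustering`: list with `gene_ids`,
#'   `labels` (named integer vector), `k`, `silhouette_by_k` (data frame),
#'   `cluster_means` (k x L matrix of mean coefficients), and `degenerate`.
#' @export
cluster_hvgs <- function(Wf, kmin = 2L, kmax = 15L, nstart = 10L, seed = 1L) {
  W <- if (inherits(Wf, "filtered_coefficients")) Wf$W_filtered else as.matrix(Wf)
  keep <- colSums(W != 0) > 0
  if (!any(keep)) .stopf("no gene has a nonzero filtered coefficient")
  genes <- colnames(W)[keep]
  mat <- t(W[, keep, drop = FALSE])       # genes x neighbor types

  n_distinct <- nrow(unique(mat))
  kmax_eff <- min(kmax, nrow(mat) - 1L, n_distinct)
  if (nrow(mat) < 2 || kmax_eff < kmin) {
    labels <- stats::setNames(rep(1L, nrow(mat)), genes)
    return(structure(list(
      gene_ids = genes, labels = labels, k = 1L,
      silhouette_by_k = data.frame(k = integer(), mean_silhouette = numeric()),
      cluster_means = matrix(colMeans(mat), 1, ncol(mat),
                             dimnames = list("1", colnames(mat))),
      degenerate = TRUE), class = "hvg_clustering"))
  }

  ks <- seq.int(kmin, kmax_eff)
  d <- stats::dist(mat)
  sil <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(.derive_seed(seed, "kmeans", ks[i]))
    km <- stats::kmeans(mat, centers = ks[i], nstart = nstart, iter.max = 100)
    fits[[i]] <- km
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  best <- which(sil >= max(sil) - 1e-12)[1]    # ties -> smallest k
  km <- fits[[best]]

  # renumber by descending cluster size (ties by original index)
  sizes <- table(km$cluster)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- stats::setNames(as.integer(remap[as.character(km$cluster)]), genes)

  cm <- do.call(rbind, lapply(seq_len(ks[best]), function(q) {
    colMeans(mat[labels == q, , drop = FALSE])
  }))
  dimnames(cm) <- list(seq_len(ks[best]), colnames(mat))

  structure(list(
    gene_ids = genes, labels = labels, k = ks[best],
    silhouette_by_k = data.frame(k = ks, mean_silhouette = sil),
    cluster_means = cm, degenerate = FALSE), class = "hvg_clustering")
}

#' @export
print.hvg_clustering <- function(x, ...) {
  cat(sprintf("hvg_clustering: %d genes in %d cluster(s)%s\n",
              length(x$gene_ids), x$k, if (x$degenerate) " [degenerate]" else ""))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Assign contributor cell types to gene clusters
#'
#' A neighbor cell type is a contributor to a cluster when at least
#' `support_threshold` of the cluster's genes carry a nonzero filtered
#' coefficient for that type and all those nonzero coefficients share one
#' sign; the shared sign gives the direction of regulation.
#'
#' @param clustering An [cluster_hvgs()] result.
#' @param Wf A `filtered_coefficients` object or filtered coefficient matrix.
#' @param support_threshold Minimum supporting fraction (default 0.9).
#' @return Data frame with columns `cluster`, `cell_type`, `direction`
#'   (`"up"` or `"down"`) and `support`.
#' @export
assign_contributors <- function(clustering, Wf, support_threshold = 0.9) {
  W <- if (inherits(Wf, "filtered_coefficients")) Wf$W_filtered else as.matrix(Wf)
  rows <- list()
  for (q in sort(unique(clustering$labels))) {
    genes_q <- names(clustering$labels)[clustering$labels == q]
    sub <- W[, genes_q, drop = FALSE]
    for (f in rownames(W)) {
      v <- sub[f, ]
      nz <- v[v != 0]
      support <- length(nz) / length(v)
      if (support >= support_threshold && length(nz) > 0 &&
          (all(nz > 0) || all(nz < 0))) {
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = q, cell_type = f,
          direction = if (all(nz > 0)) "up" else "down",
          support = support, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster = integer(), cell_type = character(),
                      direction = character(), support = numeric()))
  }
  do.call(rbind, rows)
}

#' Build the report tables: coefficient heat map and bipartite edges
#'
#' The heat-map table holds the filtered coefficients with neighbor cell
#' types as rows and reported genes as columns, ordered by cluster. The edge
#' table gives, for every (cluster, neighbor type) pair, the mean filtered
#' coefficient over the cluster's genes — the edge width of the bipartite
#' cluster-to-type graph; zero-mean edges are omitted.
#'
#' @param clustering An [cluster_hvgs()] result.
#' @param Wf A `filtered_coefficients` object or filtered coefficient matrix.
#' @return List with `heatmap` (L x n_reported matrix) and `edges`
#'   (data frame `cluster`, `neighbor_type`, `mean_coefficient`).
#' @export
build_report <- function(clustering, Wf) {
  W <- if (inherits(Wf, "filtered_coefficients")) Wf$W_filtered else as.matrix(Wf)
  ord <- names(clustering$labels)[order(clustering$labels,
                                        match(names(clustering$labels),
                                              colnames(W)))]
  heatmap <- W[, ord, drop = FALSE]
  rows <- list()
  for (q in sort(unique(clustering$labels))) {
    genes_q <- names(clustering$labels)[clustering$labels == q]
    mean_coef <- rowMeans(W[, genes_q, drop = FALSE])
    nz <- mean_coef != 0
    if (any(nz)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = q, neighbor_type = names(mean_coef)[nz],
        mean_coefficient = unname(mean_coef[nz]), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(cluster = integer(), neighbor_type = character(),
               mean_coefficient = numeric())
  }
  rownames(edges) <- NULL
  list(heatmap = heatmap, edges = edges)
}
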