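#' Match estimated gene clusters to planted clusters
#'
#' Finds the one-to-one assignment of estimated clusters to the planted
#' effect clusters (those whose true coefficients are nonzero) that
#' maximizes the total overlap of the contingency table — solved exactly by
#' enumeration over all injective partial assignments, which is cheap at
#' this scale. Estimated clusters left unmatched map to `"others"`, as do
#' genes the pipeline did not report.
#'
#' @param est_labels Named integer vector of estimated cluster labels over
#'   the reported genes.
#' @param true_labels Named vector of planted cluster labels over all genes;
#'   the value in `others_label` marks the no-effect cluster.
#' @param others_label Label of the planted no-effect class (default `4`).
#' @return An object of class `cluster_matching`: list with `mapping` (named
#'   character vector, estimated cluster -> planted cluster or `"others"`),
#'   `overlap` (total matched overlap), and `contingency`.
#' @export
match_clusters <- function(est_labels, true_labels, others_label = 4) {
  est_labels <- est_labels[names(est_labels) %in% names(true_labels)]
  targets <- setdiff(sort(unique(as.character(true_labels))),
                     as.character(others_label))
  est_ids <- sort(unique(as.integer(est_labels)))
  cont <- matrix(0L, length(est_ids), length(targets),
                 dimnames = list(est_ids, targets))
  for (g in names(est_labels)) {
    tl <- as.character(true_labels[[g]])
    if (tl %in% targets) {
      cont[as.character(est_labels[[g]]), tl] <- cont[as.character(est_labels[[g]]), tl] + 1L
    }
  }

  # exact search: for every target pick an estimated cluster or none, all
  # distinct; <= (n_est + 1)^n_targets cases with n_targets small
  n_t <- length(targets)
  choices <- c(0L, seq_along(est_ids))
  grid <- expand.grid(rep(list(choices), n_t))
  best_score <- -1L; best <- rep(0L, n_t)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    nz <- a[a > 0]
    if (anyDuplicated(nz)) next
    sc <- 0L
    for (j in seq_len(n_t)) if (a[j] > 0) sc <- sc + cont[a[j], j]
    if (sc > best_score) { best_score <- sc; best <- a }
  }
  mapping <- stats::setNames(rep("others", length(est_ids)), est_ids)
  for (j in seq_len(n_t)) if (best[j] > 0) mapping[best[j]] <- targets[j]
  structure(list(mapping = mapping, overlap = best_score, contingency = cont),
            class = "cluster_matching")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (delegates to
#' `mclust::adjustedRandIndex`).
#'
#' @param a,b Two label vectors over the same elements.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

#' Ten-index evaluation of recovery on simulated data
#'
#' Scores a pipeline result for one receiver cell type against the planted
#' truth. Estimated clusters are matched to the planted effect clusters by
#' [match_clusters()]; unreported genes and unmatched estimated clusters are
#' scored as `"others"` (the planted no-effect class is never reported, so
#' this is its natural estimate). The ten indexes are: the adjusted Rand
#' index between the mapped and planted partitions over all genes; the
#' Pearson correlation between estimated filtered coefficients and true
#' coefficients over the full (type x gene) vectorization, with unreported
#' genes contributing zeros; and per-class precision and recall for the
#' planted clusters and `"others"`. Precision of an empty estimated class is
#' reported as `NA` (undefined), not 0.
#'
#' @param result A [run_nichepls()] result, or a single cell-type entry from
#'   its `results` list.
#' @param truth A `simulated_truth` object.
#' @param cell_type Which receiver's result to score when `result` is a full
#'   run (default `"A"`).
#' @return An object of class `evaluation_report`: list with `mapping`,
#'   `ari`, `pearson_r`, `precision` and `recall` (named vectors over
#'   clusters and `"others"`), `vp`, and `indexes` (the ten values as one
#'   named vector).
#' @export
evaluate_recovery <- function(result, truth, cell_type = "A") {
  stopifnot(inherits(truth, "simulated_truth"))
  res <- if (inherits(result, "nichepls_result")) {
    if (!cell_type %in% names(result$results)) {
      .stopf("no result for cell type %s", cell_type)
    }
    result$results[[cell_type]]
  } else result
  genes <- names(truth$cluster)
  types <- rownames(truth$W_true)
  targets <- as.character(sort(unique(
    truth$cluster[colSums(truth$W_true != 0) > 0])))
  classes <- c(targets, "others")
  true_class <- ifelse(as.character(truth$cluster) %in% targets,
                       as.character(truth$cluster), "others")
  names(true_class) <- genes

  if (identical(res$status, "ok") && !is.null(res$clustering)) {
    est_raw <- res$clustering$labels
    W_hat <- res$filtered$W_filtered
  } else {
    est_raw <- stats::setNames(integer(0), character(0))
    W_hat <- matrix(0, 0, 0)
  }

  matching <- match_clusters(est_raw, truth$cluster,
                             others_label = setdiff(unique(truth$cluster),
                                                    as.integer(targets)))
  est_class <- stats::setNames(rep("others", length(genes)), genes)
  reported <- intersect(names(est_raw), genes)
  est_class[reported] <- matching$mapping[as.character(est_raw[reported])]

  ari <- adjusted_rand_index(est_class, true_class)

  # full coefficient matrices on the (type x gene) universe
  W_est <- matrix(0, length(types), length(genes),
                  dimnames = list(types, genes))
  if (length(W_hat) && nrow(W_hat) > 0) {
    W_est[rownames(W_hat), colnames(W_hat)] <- W_hat
  }
  pearson_r <- suppressWarnings(
    stats::cor(as.vector(W_est), as.vector(truth$W_true)))

  precision <- recall <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (q in classes) {
    est_q <- names(est_class)[est_class == q]
    true_q <- names(true_class)[true_class == q]
    hit <- length(intersect(est_q, true_q))
    precision[q] <- if (length(est_q)) hit / length(est_q) else NA_real_
    recall[q] <- if (length(true_q)) hit / length(true_q) else NA_real_
  }

  indexes <- c(ari = ari, pearson_r = pearson_r,
               stats::setNames(precision, paste0("precision_", classes)),
               stats::setNames(recall, paste0("recall_", classes)))
  structure(list(mapping = matching$mapping, ari = ari,
                 pearson_r = pearson_r, precision = precision,
                 recall = recall, vp = truth$vp, indexes = indexes),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (ten indexes):\n")
  print(round(x$indexes, 4))
  cat(sprintf("  VP of the evaluated dataset: %.3f\n", x$vp))
  invisible(x)
}
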