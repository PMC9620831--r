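#' Run the full neighbor-effect pipeline
#'
#' Executes, for each receiver cell type: (i) per-type gene filtering,
#' normalization and HVG selection; (ii) neighbor cell-type scoring with a
#' distance-decay kernel, z-scored within the receiver type; (iii) PLS
#' regression of HVG expression on the scores with the component count
#' chosen by cross-validation; (iv) two-step coefficient filtering under
#' BH-FDR control; (v) k-means clustering of the surviving genes with
#' silhouette-selected k; and (vi) report-table construction. Cell types
#' with too few cells or no usable genes are skipped with a recorded
#' reason — never a hard failure. The run is deterministic for a fixed
#' `config$seed`.
#'
#' @param ds A [spatial_dataset()].
#' @param config A [nichepls_config()] (default configuration if omitted).
#' @return An object of class `nichepls_result`: list with `results` (one
#'   entry per attempted cell type; each has `status` `"ok"` or
#'   `"skipped"` + `reason`, and for completed types `hvg_ids`, `X`
#'   (scored predictors), `cv`, `fit`, `filtered`, `clustering`,
#'   `contributors`, `report`), plus `dist0`, `config`, and `log` (per-step
#'   messages).
#' @export
run_nichepls <- function(ds, config = nichepls_config()) {
  stopifnot(inherits(ds, "spatial_dataset"))
  config <- nichepls_config(config)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  types <- levels(ds$labels)
  if (!is.null(config$cell_types)) {
    unknown <- setdiff(config$cell_types, types)
    if (length(unknown)) .stopf("unknown cell type(s) in config: %s",
                                paste(unknown, collapse = ", "))
    types <- config$cell_types
  }

  d0 <- if (identical(config$dist0, "auto_min")) {
    min_pairwise_distance(ds$coordinates)
  } else as.numeric(config$dist0)
  raw_scores <- raw_neighbor_scores(ds$coordinates, ds$labels, d0,
                                    kernel = config$kernel)
  note("dist0 = %.6g; raw neighbor scores computed for %d cells x %d types",
       d0, nrow(raw_scores), ncol(raw_scores))

  submats <- split_by_cell_type(ds)
  results <- list()
  for (m in types) {
    results[[m]] <- .run_one_type(
      m, submats[[m]], raw_scores[ds$labels == m, , drop = FALSE],
      config, note)
  }
  structure(list(results = results, dist0 = d0, config = config,
                 log = log_lines),
            class = "nichepls_result")
}

.skip <- function(cell_type, reason) {
  list(cell_type = cell_type, status = "skipped", reason = reason)
}

.run_one_type <- function(m, expr, raw_m, config, note) {
  n_m <- nrow(expr)
  if (n_m < config$min_cells) {
    note("[%s] skipped: %d cells < min_cells = %d", m, n_m, config$min_cells)
    return(.skip(m, sprintf("too few cells (%d < %d)", n_m, config$min_cells)))
  }

  # step (i): zero filter, HVG selection on the raw scale, normalize+z-score
  expr <- drop_all_zero_genes(expr)
  if (ncol(expr) == 0) {
    note("[%s] skipped: all genes zero", m)
    return(.skip(m, "all genes zero within the cell type"))
  }
  hvg_ids <- switch(config$hvg$method,
    none = colnames(expr),
    cv_residual = select_hvgs(expr, "cv_residual", quantile = config$hvg$quantile),
    top_n = select_hvgs(expr, "top_n", top_n = config$hvg$top_n))
  processed <- normalize_log_zscore(expr, normalize = config$normalize)
  hvg_ids <- intersect(hvg_ids, colnames(processed))
  if (length(hvg_ids) < config$hvg$min_hvgs) {
    note("[%s] skipped: %d HVGs < min_hvgs = %d", m, length(hvg_ids),
         config$hvg$min_hvgs)
    return(.skip(m, sprintf("too few HVGs (%d < %d)", length(hvg_ids),
                            config$hvg$min_hvgs)))
  }
  Y <- processed[, hvg_ids, drop = FALSE]

  # step (ii): z-score neighbor scores within the receiver type and drop
  # degenerate (constant) neighbor-type columns from the predictors
  X_all <- zscore_neighbor_scores(raw_m)
  degen <- attr(X_all, "degenerate")
  X <- X_all[, setdiff(colnames(X_all), degen), drop = FALSE]
  if (ncol(X) == 0) {
    note("[%s] skipped: all neighbor-score columns constant", m)
    return(.skip(m, "no usable neighbor-score predictors"))
  }
  if (length(degen)) note("[%s] degenerate neighbor types excluded: %s", m,
                          paste(degen, collapse = ", "))

  # step (iii): component count by CV, then the PLS fit
  c_max <- if (is.null(config$pls$c_max)) min(ncol(X), 10L) else config$pls$c_max
  cv <- select_num_components(X, Y, folds = config$pls$folds, c_max = c_max,
                              seed = .derive_seed(config$seed, m, "cv"),
                              tol = config$pls$tol,
                              max_iter = config$pls$max_iter)
  fit <- fit_pls(X, Y, ncomp = cv$C, tol = config$pls$tol,
                 max_iter = config$pls$max_iter)
  note("[%s] n = %d, H = %d HVGs, L = %d predictors, C = %d components",
       m, n_m, ncol(Y), ncol(X), fit$C)

  # step (iv): two-step filtering
  filtered <- filter_coefficients(fit, X, Y,
                                  alpha1 = config$filter$alpha1,
                                  alpha2 = config$filter$alpha2,
                                  n_perm = config$filter$n_perm,
                                  seed = .derive_seed(config$seed, m, "perm"),
                                  tol = config$pls$tol,
                                  max_iter = config$pls$max_iter)
  n_report <- sum(colSums(filtered$W_filtered != 0) > 0)
  note("[%s] %d genes with surviving coefficients", m, n_report)
  if (n_report == 0) {
    out <- list(cell_type = m, status = "ok", n_cells = n_m,
                hvg_ids = hvg_ids, X = X, cv = cv, fit = fit,
                filtered = filtered, clustering = NULL,
                contributors = NULL, report = NULL)
    return(out)
  }

  # steps (v)-(vi): clustering and report tables
  clustering <- cluster_hvgs(filtered, kmin = config$cluster$kmin,
                             kmax = config$cluster$kmax,
                             nstart = config$cluster$nstart,
                             seed = .derive_seed(config$seed, m, "kmeans"))
  contributors <- assign_contributors(clustering, filtered)
  report <- build_report(clustering, filtered)
  note("[%s] %d gene clusters (k by silhouette)", m, clustering$k)
  list(cell_type = m, status = "ok", n_cells = n_m, hvg_ids = hvg_ids,
       X = X, cv = cv, fit = fit, filtered = filtered,
       clustering = clustering, contributors = contributors, report = report)
}

#' @export
print.nichepls_result <- function(x, ...) {
  cat(sprintf("nichepls_result: %d cell type(s) attempted (seed %d)\n",
              length(x$results), x$config$seed))
  for (r in x$results) {
    if (r$status == "skipped") {
      cat(sprintf("  %s: skipped (%s)\n", r$cell_type, r$reason))
    } else if (is.null(r$clustering)) {
      cat(sprintf("  %s: no surviving coefficients\n", r$cell_type))
    } else {
      cat(sprintf("  %s: %d HVGs -> %d reported genes in %d cluster(s), C = %d\n",
                  r$cell_type, length(r$hvg_ids),
                  length(r$clustering$gene_ids), r$clustering$k, r$fit$C))
    }
  }
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Writes, per completed cell type, `coefficients.tsv` (rows = neighbor
#' types, columns = reported genes), `clusters.tsv` (gene, cluster) and
#' `bipartite_edges.tsv` (cluster, neighbor_type, mean_coefficient), plus a
#' top-level `run_summary.json` with the seed, the resolved configuration,
#' per-type status and the step log.
#'
#' @param result A [run_nichepls()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
save_results <- function(result, dir) {
  stopifnot(inherits(result, "nichepls_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = result$config$seed, dist0 = result$dist0,
                  config = unclass(result$config), log = result$log,
                  cell_types = list())
  for (r in result$results) {
    entry <- list(status = r$status)
    if (r$status == "skipped") {
      entry$reason <- r$reason
    } else if (!is.null(r$clustering)) {
      tdir <- file.path(dir, r$cell_type)
      dir.create(tdir, showWarnings = FALSE)
      hm <- r$report$heatmap
      utils::write.table(
        data.frame(neighbor_type = rownames(hm), hm, check.names = FALSE),
        file.path(tdir, "coefficients.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(gene = names(r$clustering$labels),
                   cluster = unname(r$clustering$labels)),
        file.path(tdir, "clusters.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(r$report$edges,
                         file.path(tdir, "bipartite_edges.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      entry$n_reported <- length(r$clustering$gene_ids)
      entry$k <- r$clustering$k
      entry$C <- r$fit$C
    } else {
      entry$n_reported <- 0L
    }
    summary$cell_types[[r$cell_type]] <- entry
  }
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}
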