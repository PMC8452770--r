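#' Run the full inference pipeline and write its outputs
#'
#' Reads (or accepts) a cells x features matrix, fits the trajectory with
#' [trajwalk()], and writes the standard output bundle to `out_dir`:
#' `cluster_assignment.csv`, `cluster_graph.tsv`, `directed_graph.tsv`,
#' `pseudotime.csv`, `pseudotime_cells.csv`, `terminal_states.csv`,
#' `lineage_clusters.csv`, `lineage_cells.csv`, per-lineage trend curves for
#' the most variable features, and `manifest.json` (config + seed +
#' versions). Identical config and seed produce byte-identical outputs.
#'
#' @param input Path to a matrix file, or a matrix.
#' @param out_dir Output directory (created if needed).
#' @param root,root_mode,annotations Root specification, see [trajwalk()].
#' @param n_trend_features Number of top-variance features to write trend
#'   curves for (0 disables).
#' @param t_steps Diffusion steps for imputation before trend fitting.
#' @param ... Further arguments to [trajwalk()].
#' @return The `trajwalk` fit, invisibly.
#' @export
run_pipeline <- function(input, out_dir, root, root_mode = "cell_index",
                         annotations = NULL, n_trend_features = 1L,
                         t_steps = 3L, ...) {
  X <- if (is.character(input)) read_matrix(input) else input
  X <- as.matrix(X)
  fit <- trajwalk(X, root = root, root_mode = root_mode,
                  annotations = annotations, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- fit$config$seed
  cmt <- sprintf("trajwalk %s seed=%d",
                 as.character(utils::packageVersion("trajwalk")), seed)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)

  wcsv(data.frame(cell_id = rownames(fit$knn$adj),
                  cluster = fit$assignment$labels), "cluster_assignment.csv")
  W <- fit$cluster_graph$W
  idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  write_edge_list(data.frame(source = rownames(W)[idx[, 1]],
                             target = rownames(W)[idx[, 2]],
                             weight = W[idx]),
                  file.path(out_dir, "cluster_graph.tsv"), comment = cmt)
  dedges <- do.call(rbind, lapply(fit$directed_graph, function(dg) {
    if (is.null(dg)) return(NULL)
    di <- which(dg$Wd > 0, arr.ind = TRUE)
    data.frame(source = rownames(dg$Wd)[di[, 1]],
               target = rownames(dg$Wd)[di[, 2]],
               weight = dg$Wd[di], multiplier = dg$mult[di])
  }))
  write_edge_list(if (is.null(dedges))
    data.frame(source = character(0), target = character(0),
               weight = numeric(0), multiplier = numeric(0)) else dedges,
    file.path(out_dir, "directed_graph.tsv"), comment = cmt)
  wcsv(fit$pseudotime, "pseudotime.csv")
  wcsv(data.frame(cell_id = names(fit$pseudotime_cells),
                  pseudotime = unname(fit$pseudotime_cells)),
       "pseudotime_cells.csv")
  led <- fit$terminal_ledger
  wcsv(if (!is.null(led))
    data.frame(cluster_id = led$node[led$terminal],
                passed_votes = led$votes[led$terminal],
                t_refined = led$t_refined[led$terminal])
    else data.frame(cluster_id = character(0), passed_votes = integer(0),
                    t_refined = numeric(0)),
    "terminal_states.csv")
  wcsv(data.frame(cluster_id = rownames(fit$lineage_clusters),
                  fit$lineage_clusters, check.names = FALSE),
       "lineage_clusters.csv")
  wcsv(data.frame(cell_id = rownames(fit$lineage_cells),
                  fit$lineage_cells, check.names = FALSE),
       "lineage_cells.csv")
  if (n_trend_features > 0 && length(fit$terminals) > 0) {
    Ximp <- impute_features(X, fit$knn, t_steps = t_steps)
    vars <- apply(Ximp, 2L, stats::var)
    feats <- colnames(X)[order(-vars)][seq_len(min(n_trend_features,
                                                   ncol(X)))]
    for (f in feats) for (j in fit$terminals) {
      tc <- lineage_trend(Ximp[, f], fit$pseudotime_cells,
                          fit$lineage_cells[, j], lineage = j)
      wcsv(data.frame(grid_t = tc$grid, fitted_value = tc$fitted),
           sprintf("trend_%s_lineage_%s.csv", f, j))
    }
  }
  manifest <- list(package = "trajwalk",
                   version = as.character(utils::packageVersion("trajwalk")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed, root = as.character(root),
                   root_mode = root_mode, config = fit$config,
                   n_cells = nrow(X), n_features = ncol(X),
                   terminals = fit$terminals)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}
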