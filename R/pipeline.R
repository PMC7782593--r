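#' Two-stage alignment of tumor and cell-line expression data
#'
#' Runs the full alignment: (1) per-dataset SNN clustering in PCA space and
#' cluster-mean residualization, contrastive PCA of the intra-cluster
#' covariances, and removal of the leading tumor-enriched components from
#' both datasets; (2) moderated-F selection of cluster-variable genes,
#' asymmetric-k mutual-nearest-neighbor pairing on that gene subset, and
#' Gaussian-smoothed correction of the tumors toward the cell-line
#' reference. Cell lines are the fixed reference throughout.
#'
#' Parameters whose defaults exceed what a small cohort permits (`n_pcs`,
#' `k_tumor`, `k_cell_line`, `n_top_genes_per_dataset`, `snn_k`) are
#' clamped per dataset with a message, so desk-scale fixtures and
#' paper-scale cohorts run through the same code path.
#'
#' @param tumor,cell_lines [expression_matrix()] objects (any gene overlap
#'   is harmonized internally).
#' @param config A [pipeline_config()].
#' @return A list of class `AlignmentResult` with elements `config`,
#'   `clusters` (per-dataset `ClusterAssignment`s), `components`
#'   (`ContrastiveComponents`), `gene_set` (MNN gene universe), `pairing`
#'   (`MNNPairing`), `correction` (`CorrectionField`), `aligned` (list with
#'   `tumor` and `cell_lines` matrices), and `combined` (row-bound aligned
#'   matrix with a `dataset` attribute).
#' @export
align_cohorts <- function(tumor, cell_lines, config = pipeline_config()) {
  stopifnot(inherits(tumor, "ExpressionMatrix"),
            inherits(cell_lines, "ExpressionMatrix"),
            inherits(config, "PipelineConfig"))
  hz <- harmonize_genes(tumor, cell_lines)
  t_m <- hz$tumor$values
  cl_m <- hz$cell_lines$values

  # Community detection at a fixed resolution has a granularity scale tied
  # to graph size: on very small panels a resolution tuned for thousands of
  # samples shatters the graph into singletons, leaving the intra-cluster
  # residuals (and the moderated-F residual df) empty. If that happens the
  # resolution is halved until the average cluster holds >= 3 samples, with
  # a message; cohorts at the method's intended scale are unaffected.
  cluster_one <- function(m, tag) {
    n_pcs <- min(config$n_pcs, nrow(m) - 1L, ncol(m))
    if (n_pcs < config$n_pcs)
      message(tag, ": n_pcs clamped to ", n_pcs)
    scores <- pca_reduce(m, n_pcs)$scores
    k <- min(config$snn_k, nrow(m) - 1L)
    g <- build_snn_graph(scores, k, config$snn_prune)
    n <- nrow(m)
    cands <- config$snn_resolution / 2^seq(0, 12, by = 0.5)
    fallback <- NULL
    for (res in cands) {
      ca <- cluster_graph(g, res, config$rng_seed, dataset = tag)
      k_found <- length(unique(ca$labels))
      if (k_found >= 2 && k_found <= n / 3) {
        if (res < config$snn_resolution)
          message(tag, ": resolution ", config$snn_resolution,
                  " too fine for ", n, " samples; clustered at ", res)
        return(ca)
      }
      if (is.null(fallback) && k_found >= 2 && k_found < n)
        fallback <- list(ca = ca, res = res)
    }
    if (!is.null(fallback)) {
      message(tag, ": no resolution gave average cluster size >= 3; ",
              "using resolution ", fallback$res)
      return(fallback$ca)
    }
    stop(tag, ": could not obtain a non-degenerate clustering (>= 2 clusters)")
  }
  t_clusters <- cluster_one(t_m, "tumor")
  cl_clusters <- cluster_one(cl_m, "cell_line")

  t_resid <- subtract_cluster_means(t_m, t_clusters)
  cl_resid <- subtract_cluster_means(cl_m, cl_clusters)
  comps <- contrastive_components(intra_cluster_covariance(t_resid),
                                  intra_cluster_covariance(cl_resid),
                                  n_components = config$n_cpcs_removed,
                                  alpha = config$cpca_alpha)
  t_res <- regress_out_components(t_m, comps)
  cl_res <- regress_out_components(cl_m, comps)

  n_top <- min(config$n_top_genes_per_dataset, ncol(t_m))
  gene_set <- select_union_genes(moderated_f_stats(t_m, t_clusters),
                                 moderated_f_stats(cl_m, cl_clusters),
                                 n_top = n_top)

  k_cl <- min(config$k_cell_line, nrow(cl_res))
  k_t <- min(config$k_tumor, nrow(t_res))
  pairing <- find_mutual_nn(cl_res, t_res, gene_set, k_cl = k_cl, k_t = k_t)
  if (nrow(pairing$pairs) == 0L) {
    warning("no mutual nearest neighbor pairs found: ",
            "tumors left uncorrected after the contrastive stage")
    correction <- NULL
    t_aligned <- t_res
  } else {
    correction <- compute_correction(pairing, cl_res, t_res,
                                     sigma_multiplier = config$mnn_sigma_multiplier)
    t_aligned <- apply_correction(t_res, correction)
  }

  combined <- rbind(cl_res, t_aligned)
  attr(combined, "dataset") <- rep(c("cell_line", "tumor"),
                                   c(nrow(cl_res), nrow(t_aligned)))
  structure(list(config = config,
                 clusters = list(tumor = t_clusters, cell_line = cl_clusters),
                 components = comps, gene_set = gene_set, pairing = pairing,
                 correction = correction,
                 aligned = list(tumor = t_aligned, cell_lines = cl_res),
                 combined = combined),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf(paste0(
    "AlignmentResult: %d cell lines (reference) + %d tumors (corrected), ",
    "%d genes\n  clusters: %d tumor / %d cell line; %d cPCs removed; ",
    "%d MNN genes; %d MNN pairs\n"),
    nrow(x$aligned$cell_lines), nrow(x$aligned$tumor),
    ncol(x$aligned$tumor),
    length(unique(x$clusters$tumor$labels)),
    length(unique(x$clusters$cell_line$labels)),
    ncol(x$components$loadings), length(x$gene_set),
    if (is.null(x$pairing)) 0L else nrow(x$pairing$pairs)))
  invisible(x)
}

#' Write the main outputs of an alignment run to a directory
#'
#' Emits the aligned combined matrix, per-dataset cluster labels, MNN
#' pairs, contrastive loadings and eigenvalue scree, the MNN gene set, and
#' a JSON sidecar echoing the configuration.
#'
#' @param result An `AlignmentResult`.
#' @param dir Output directory (created if needed).
#' @export
write_alignment <- function(result, dir) {
  stopifnot(inherits(result, "AlignmentResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  combined <- data.frame(sample_id = rownames(result$combined),
                         dataset = attr(result$combined, "dataset"),
                         result$combined, check.names = FALSE)
  utils::write.table(combined, p("aligned_combined.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_cluster_assignment(result$clusters$tumor, p("clusters_tumor.tsv"))
  write_cluster_assignment(result$clusters$cell_line, p("clusters_cell_line.tsv"))
  write_contrastive_components(result$components, p("cpc_loadings.tsv"),
                               p("cpc_scree.tsv"))
  writeLines(result$gene_set, p("mnn_gene_set.txt"))
  if (!is.null(result$pairing)) write_mnn_pairs(result$pairing, p("mnn_pairs.tsv"))
  jsonlite::write_json(
    c(unclass(result$config),
      list(package_version = as.character(utils::packageVersion("tcalign")),
           r_version = R.version.string)),
    p("run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
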