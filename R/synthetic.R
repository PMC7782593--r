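#' Simulate a paired tumor / cell-line expression cohort with ground truth
#'
#' Generates two log2(TPM+1)-scale expression matrices sharing disease-type
#' cluster structure, with the confounders the alignment method is built to
#' remove:
#'
#' * per-tumor purity drawn from a Beta distribution; each tumor is a
#'   purity-weighted mixture of its cancer profile and a low-rank
#'   contamination component (a Dirichlet mixture of `r_contamination`
#'   contaminating-tissue profiles), so contamination scales with
#'   (1 - purity);
#' * a global plus type-specific tumor-vs-cell-line expression offset
#'   (systematic dataset differences);
#' * one tumor-only and one cell-line-only disease type (dataset-exclusive
#'   types);
#' * i.i.d. Gaussian noise at both the biological (cancer profile) and
#'   measurement level.
#'
#' Cancer profile of sample s = type centroid + N(0, noise_sd) noise (log2
#' scale); the observed cell line is the cancer profile plus measurement
#' noise. The observed tumor mixes cancer and contaminant transcriptomes
#' on the linear TPM scale — TPM_obs = purity x TPM_cancer + (1 - purity)
#' x TPM_contaminant — and is then logged, offset (global dataset shift
#' plus a type-specific shift) and measurement-noised. Linear-scale mixing
#' matters: genes dominated by the contaminant saturate in log space, so
#' low-purity tumors lose (not merely shrink) lineage signal, which is the
#' confound that degrades naive cross-dataset classification. Values are
#' clipped at 0 to respect the log-TPM scale; the clip fraction is
#' recorded and stays far below 1% at default noise.
#'
#' @param seed Integer seed; all draws are reproducible from it.
#' @param n_genes,n_types,n_cell_lines,n_tumors Cohort dimensions
#'   (defaults 2000 genes, 6 types, 60 cell lines, 600 tumors). `n_types`
#'   must be at least 3: the last type is tumor-only, the second-to-last
#'   cell-line-only, the rest shared.
#' @param r_contamination Rank of the contamination component (default 3).
#' @param purity_shape Beta shape parameters `c(a, b)` for tumor purity
#'   (default `c(4, 2)`, mean 2/3).
#' @param noise_sd Gaussian noise sd in log2 units, applied at both the
#'   biological (within-type heterogeneity) and measurement level
#'   (default 0.4).
#' @param offset_scale Per-gene sd of the global dataset offset; the
#'   type-specific offsets use `offset_scale / 2` (default 0.5).
#' @param type_sd Per-gene sd of type-centroid deviations from the shared
#'   baseline (default 0.5: most genes differ modestly between lineages,
#'   so the aggregate type signal across 2000 genes is solid but does not
#'   drown the purity confound).
#' @return A list with `tumor` and `cell_line` ([expression_matrix()]
#'   objects), `truth` (class `SyntheticTruth`: `type_labels`, `purity`,
#'   `contamination_loadings` — the genes x r contamination *signatures*,
#'   i.e. contaminant-minus-mean-cancer-profile difference vectors, which
#'   span the subspace along which contamination actually displaces a
#'   tumor profile — plus the raw `contaminant_profiles`,
#'   `dataset_offset`, `type_offsets`, `exclusive_types`, `seed`,
#'   `clip_fraction`), and `annotations` (a combined annotation
#'   data.frame).
#' @export
simulate_cohort <- function(seed, n_genes = 2000L, n_types = 6L,
                            n_cell_lines = 60L, n_tumors = 600L,
                            r_contamination = 3L, purity_shape = c(4, 2),
                            noise_sd = 0.4, offset_scale = 0.5, type_sd = 0.5) {
  if (n_types < 3L) stop("need n_types >= 3 (one tumor-only, one cell-line-only)")
  if (noise_sd <= 0 || offset_scale < 0 || type_sd <= 0)
    stop("scales must be positive")
  set.seed(as.integer(seed))
  types <- sprintf("type%02d", seq_len(n_types))
  tumor_only <- types[n_types]
  cl_only <- types[n_types - 1L]
  cl_types <- setdiff(types, tumor_only)
  t_types <- setdiff(types, cl_only)
  if (n_cell_lines < length(cl_types) || n_tumors < length(t_types))
    stop("fewer samples than types in one of the datasets")

  genes <- sprintf("G%04d", seq_len(n_genes))
  # baseline abundance of expressed protein-coding genes on the log2(TPM+1)
  # scale: location ~3-9, bounded away from 0 so clipping stays rare
  baseline <- 3 + stats::rgamma(n_genes, shape = 2, scale = 1.5)
  centroids <- baseline + matrix(stats::rnorm(n_genes * n_types, sd = type_sd),
                                 n_genes, n_types, dimnames = list(genes, types))
  # contaminating-tissue profiles are distinct transcriptomes with their own
  # baselines (stromal/immune populations, not perturbed cancer profiles);
  # their decorrelation from the cancer baseline is what makes raw
  # cross-dataset correlations purity-dominated before alignment
  w <- matrix(3 + stats::rgamma(n_genes * r_contamination, shape = 2, scale = 1.5) +
                stats::rnorm(n_genes * r_contamination),
              n_genes, r_contamination,
              dimnames = list(genes, paste0("contam", seq_len(r_contamination))))
  w[w < 0] <- 0
  dataset_offset <- stats::rnorm(n_genes, sd = offset_scale)
  type_offsets <- matrix(stats::rnorm(n_genes * n_types, sd = offset_scale / 2),
                         n_genes, n_types, dimnames = list(genes, types))

  # cell-line panels sample lineages roughly evenly; tumor compendia are
  # strongly unbalanced (common carcinomas dominate, rare entities are
  # scarce), one of the composition differences the alignment must absorb
  cl_lab <- rep(cl_types, length.out = n_cell_lines)
  t_w <- 0.55^(seq_along(t_types) - 1L)
  t_w[length(t_w)] <- t_w[2L]              # the tumor-only type is mid-sized
  t_n <- pmax(1L, round(n_tumors * t_w / sum(t_w)))
  t_n[1L] <- t_n[1L] + (n_tumors - sum(t_n))
  t_lab <- rep(t_types, times = t_n)
  cl_ids <- sprintf("CL%04d", seq_len(n_cell_lines))
  t_ids <- sprintf("T%04d", seq_len(n_tumors))

  cl_vals <- t(centroids[, cl_lab, drop = FALSE] +
                 matrix(stats::rnorm(n_genes * n_cell_lines, sd = noise_sd),
                        n_genes, n_cell_lines) +
                 matrix(stats::rnorm(n_genes * n_cell_lines, sd = noise_sd),
                        n_genes, n_cell_lines))
  dimnames(cl_vals) <- list(cl_ids, genes)

  # purity_shape = c(a, 0) is the degenerate fully-pure limit
  purity <- if (purity_shape[2] <= 0) rep(1, n_tumors)
            else stats::rbeta(n_tumors, purity_shape[1], purity_shape[2])
  names(purity) <- t_ids
  mix <- matrix(stats::rgamma(n_tumors * r_contamination, shape = 1),
                r_contamination, n_tumors)
  mix <- sweep(mix, 2L, colSums(mix), "/")            # Dirichlet(1) weights
  cancer <- centroids[, t_lab, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_tumors, sd = noise_sd), n_genes, n_tumors)
  # bulk RNA mixes on the linear TPM scale, not the log scale: a tumor's
  # transcriptome is a purity-weighted average of cancer-cell and
  # contaminating-cell TPM. Genes where the contaminant dominates saturate
  # in log space, which is what erases (rather than merely shrinks) the
  # lineage signal of low-purity tumors
  contam_tpm <- (2^w - 1) %*% mix
  mixed_tpm <- sweep(2^cancer - 1, 2L, purity, "*") +
    sweep(contam_tpm, 2L, 1 - purity, "*")
  t_vals <- log2(mixed_tpm + 1) +
    dataset_offset + type_offsets[, t_lab, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_tumors, sd = noise_sd), n_genes, n_tumors)
  t_vals <- t(t_vals)
  dimnames(t_vals) <- list(t_ids, genes)

  clip_fraction <- (sum(cl_vals < 0) + sum(t_vals < 0)) /
    (length(cl_vals) + length(t_vals))
  cl_vals[cl_vals < 0] <- 0
  t_vals[t_vals < 0] <- 0

  # The recoverable ground-truth contamination subspace holds the
  # *signatures*: the direction one unit of contamination by tissue j
  # displaces an observed (log-scale) tumor profile, evaluated at the mean
  # purity around the mean cancer TPM profile. This, not the raw
  # contaminant profiles, is what an unsupervised variance-based method
  # can see in the data. The raw contaminant profiles W are kept alongside.
  p0 <- purity_shape[1] / sum(purity_shape)
  cancer_ref_tpm <- rowMeans(2^centroids[, t_types, drop = FALSE] - 1)
  base_log <- log2(p0 * cancer_ref_tpm + 1)
  signatures <- apply(2^w - 1, 2L, function(tj)
    log2(p0 * cancer_ref_tpm + (1 - p0) * tj + 1) - base_log)
  dimnames(signatures) <- dimnames(w)

  truth <- structure(list(
    type_labels = stats::setNames(c(cl_lab, t_lab), c(cl_ids, t_ids)),
    purity = purity,
    contamination_loadings = signatures,
    contaminant_profiles = w,
    dataset_offset = dataset_offset,
    type_offsets = type_offsets,
    exclusive_types = list(tumor_only = tumor_only, cell_line_only = cl_only),
    seed = as.integer(seed),
    clip_fraction = clip_fraction), class = "SyntheticTruth")

  annotations <- data.frame(
    sample_id = c(cl_ids, t_ids),
    lineage = c(cl_lab, t_lab),
    subtype = NA_character_,
    dataset = rep(c("cell_line", "tumor"), c(n_cell_lines, n_tumors)),
    stringsAsFactors = FALSE)

  list(tumor = expression_matrix(t_vals, "tumor"),
       cell_line = expression_matrix(cl_vals, "cell_line"),
       truth = truth, annotations = annotations)
}

#' Recovery metrics of a pipeline run against simulation ground truth
#'
#' @param truth `SyntheticTruth` from [simulate_cohort()].
#' @param aligned_cell_lines,aligned_tumors Aligned samples x genes
#'   matrices from the pipeline.
#' @param comps `ContrastiveComponents` from the pipeline (for the planted
#'   contamination-subspace angle); may be `NULL`.
#' @param report_post `SimilarityReport` on the aligned data.
#' @param report_pre Optional `SimilarityReport` on the raw data.
#' @param k Neighbor count for the exclusive-type preservation check
#'   (default 25).
#' @return A one-row data.frame: `accuracy_pre`, `accuracy_post`,
#'   `contamination_cosine` (mean absolute cosine of principal angles
#'   between the planted contamination subspace and the top-r contrastive
#'   loadings), `exclusive_tumor_min_frac` and `exclusive_tumor_mean_frac`
#'   (fraction of tumors among each tumor-only-type member's k nearest
#'   neighbors in the aligned combined space, min and mean over members).
#' @export
evaluate_recovery <- function(truth, aligned_cell_lines, aligned_tumors,
                              comps = NULL, report_post = NULL,
                              report_pre = NULL, k = 25L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  r <- ncol(truth$contamination_loadings)
  cosine <- NA_real_
  if (!is.null(comps)) {
    q1 <- qr.Q(qr(truth$contamination_loadings))
    top <- comps$loadings[, seq_len(min(r, ncol(comps$loadings))), drop = FALSE]
    q2 <- qr.Q(qr(top[rownames(truth$contamination_loadings), , drop = FALSE]))
    cosine <- mean(svd(crossprod(q1, q2))$d)
  }
  excl <- exclusive_neighbor_fractions(truth, aligned_cell_lines,
                                       aligned_tumors, k)
  data.frame(
    accuracy_pre = if (is.null(report_pre)) NA_real_ else report_pre$agreement,
    accuracy_post = if (is.null(report_post)) NA_real_ else report_post$agreement,
    contamination_cosine = cosine,
    exclusive_tumor_min_frac = min(excl),
    exclusive_tumor_mean_frac = mean(excl))
}

# For each tumor of the tumor-only type: fraction of tumors among its k
# nearest neighbors (Pearson) in the combined aligned space.
exclusive_neighbor_fractions <- function(truth, aligned_cell_lines,
                                         aligned_tumors, k = 25L) {
  combined <- rbind(aligned_cell_lines, aligned_tumors)
  is_tumor <- c(rep(FALSE, nrow(aligned_cell_lines)),
                rep(TRUE, nrow(aligned_tumors)))
  excl_ids <- names(truth$type_labels)[
    truth$type_labels == truth$exclusive_types$tumor_only]
  excl_ids <- intersect(excl_ids, rownames(aligned_tumors))
  corr <- stats::cor(t(combined[excl_ids, , drop = FALSE]), t(combined))
  vapply(seq_along(excl_ids), function(i) {
    r <- corr[i, ]
    r[excl_ids[i]] <- -Inf                       # exclude self
    nn <- order(-r, colnames(corr), method = "radix")[seq_len(k)]
    mean(is_tumor[nn])
  }, numeric(1))
}

#' Write simulation ground truth as JSON
#' @param truth A `SyntheticTruth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(type_labels = as.list(truth$type_labels),
         purity = as.list(truth$purity),
         exclusive_types = truth$exclusive_types,
         seed = truth$seed, clip_fraction = truth$clip_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
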