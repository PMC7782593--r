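#' Construct an ExpressionMatrix
#'
#' The basic container of the pipeline: a samples x genes matrix of
#' log2(TPM+1) expression values tagged with the dataset it came from.
#' Values must be finite and non-negative (log2 of TPM+1 with TPM >= 0),
#' and sample/gene identifiers must be unique.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   rownames (sample ids) and colnames (gene ids).
#' @param dataset Either `"tumor"` or `"cell_line"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `dataset` (the tag).
#' @export
expression_matrix <- function(values, dataset = c("tumor", "cell_line")) {
  dataset <- match.arg(dataset)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have sample rownames and gene colnames")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- utils::head(bad, 5)
    stop(sprintf(
      "non-finite expression values, e.g. sample '%s' / gene '%s'%s",
      rownames(values)[ex[1, 1]], colnames(values)[ex[1, 2]],
      if (nrow(bad) > 1) sprintf(" (%d offending cells total)", nrow(bad)) else ""
    ))
  }
  if (any(values < 0))
    stop("negative expression values: input must be log2(TPM+1), which is >= 0")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids: ",
         paste(utils::head(unique(colnames(values)[duplicated(colnames(values))]), 5),
               collapse = ", "))
  structure(list(values = values, dataset = dataset), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d samples x %d genes\n",
              x$dataset, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) colnames(x$values)

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Load an expression matrix from a delimited text file
#'
#' Reads a TSV/CSV with one labeled axis per dimension (first column holds
#' the row ids, header holds the column ids). Orientation is auto-detected
#' from the corner label of the header: if it is one of `"gene"`,
#' `"gene_id"`, `"genes"` (case-insensitive) the file is genes-as-rows and
#' gets transposed; `"sample"`/`"sample_id"`/`"samples"` means samples are
#' rows. With an empty or unrecognized corner label the longer axis is
#' assumed to be genes, which is the usual case for transcriptome-wide data.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param dataset_tag `"tumor"` or `"cell_line"`.
#' @param orientation Override auto-detection: `"auto"`, `"samples_by_genes"`
#'   or `"genes_by_samples"`.
#' @return A validated [expression_matrix()].
#' @export
load_expression_matrix <- function(path, dataset_tag = c("tumor", "cell_line"),
                                   orientation = c("auto", "samples_by_genes",
                                                   "genes_by_samples")) {
  dataset_tag <- match.arg(dataset_tag)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE))
    stop("HDF5 input is not supported in this build; supply delimited text ",
         "(no R HDF5 binding is available)")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  corner <- tolower(trimws(gsub('"', "", header[1])))
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    nonnum <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                      !is.na(m), arr.ind = TRUE)
    if (nrow(nonnum) > 0)
      stop(sprintf("non-numeric entry at row '%s', column '%s'",
                   rownames(m)[nonnum[1, 1]], colnames(m)[nonnum[1, 2]]))
    stop("non-numeric columns in expression file: ",
         paste(utils::head(colnames(df)[bad], 5), collapse = ", "))
  }
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0)
    stop(sprintf("missing value at row '%s', column '%s'%s",
                 rownames(m)[nas[1, 1]], colnames(m)[nas[1, 2]],
                 if (nrow(nas) > 1) sprintf(" (%d total)", nrow(nas)) else ""))
  genes_as_rows <- switch(orientation,
    samples_by_genes = FALSE,
    genes_by_samples = TRUE,
    auto = if (corner %in% c("gene", "gene_id", "genes", "gene_symbol"))
      TRUE
    else if (corner %in% c("sample", "sample_id", "samples"))
      FALSE
    else nrow(m) > ncol(m)  # transcriptome-wide: genes outnumber samples
  )
  if (genes_as_rows) m <- t(m)
  expression_matrix(m, dataset_tag)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [load_expression_matrix()]: samples as rows, a `sample_id`
#' corner label, full precision (17 significant digits, round-trip exact).
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", gene_ids(x)), collapse = "\t"), con)
  utils::write.table(format(x$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene ids, in the
#' same (first-matrix) order. Idempotent; errors if no genes are shared.
#'
#' @param tumor,cell_lines `ExpressionMatrix` objects.
#' @return A list with elements `tumor` and `cell_lines`.
#' @export
harmonize_genes <- function(tumor, cell_lines) {
  stopifnot(inherits(tumor, "ExpressionMatrix"),
            inherits(cell_lines, "ExpressionMatrix"))
  shared <- intersect(gene_ids(tumor), gene_ids(cell_lines))
  if (length(shared) == 0L) stop("no shared genes between the two datasets")
  if (length(shared) < 2L) stop("fewer than 2 shared genes")
  list(
    tumor = expression_matrix(tumor$values[, shared, drop = FALSE], tumor$dataset),
    cell_lines = expression_matrix(cell_lines$values[, shared, drop = FALSE],
                                   cell_lines$dataset)
  )
}

#' Read a sample annotation table
#'
#' Expects a delimited file with columns `sample_id` and `lineage`
#' (optionally `subtype`). Samples present in the expression data but
#' missing from the annotation get lineage `"unknown"`; annotation rows
#' without expression are dropped with a warning.
#'
#' @param path Annotation TSV/CSV path, or `NULL`.
#' @param x `ExpressionMatrix` the annotations refer to.
#' @return A data.frame with columns `sample_id`, `lineage`, `subtype`,
#'   `dataset`, one row per sample of `x`, in sample order.
#' @export
read_sample_annotation <- function(path, x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ids <- sample_ids(x)
  out <- data.frame(sample_id = ids, lineage = "unknown", subtype = NA_character_,
                    dataset = x$dataset, stringsAsFactors = FALSE)
  if (is.null(path)) return(out)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "lineage") %in% colnames(ann)))
    stop("annotation file must have columns 'sample_id' and 'lineage'")
  orphan <- setdiff(ann$sample_id, ids)
  if (length(orphan) > 0)
    warning(length(orphan), " annotation rows without expression dropped")
  idx <- match(ids, ann$sample_id)
  hit <- !is.na(idx)
  out$lineage[hit] <- ann$lineage[idx[hit]]
  if ("subtype" %in% colnames(ann)) out$subtype[hit] <- ann$subtype[idx[hit]]
  out$lineage[is.na(out$lineage) | out$lineage == ""] <- "unknown"
  out
}

#' Pipeline configuration
#'
#' All numeric method parameters in one place, with defaults matching the
#' published configuration of the method: clustering in 70-dimensional PCA
#' space at SNN resolution 5, removal of the first 4 contrastive PCs, the
#' union of the top 1000 between-cluster-variable genes per dataset for the
#' neighbor search, asymmetric MNN neighbor counts k = 5 (cell lines) and
#' k = 50 (tumors), 25 tumor neighbors for type classification, and a UMAP
#' with 10 neighbors and min_dist 0.5 on 70 PCs.
#'
#' @param n_pcs Dimensionality of the PCA space used for clustering and the
#'   2D embedding (default 70; clamped per dataset to `n_samples - 1`).
#' @param snn_k Neighbor count for the shared-nearest-neighbor graph
#'   (default 20).
#' @param snn_prune Jaccard edge weights below this are dropped (default 1/15).
#' @param snn_resolution Modularity resolution for community detection
#'   (default 5).
#' @param n_cpcs_removed Number of tumor-enriched contrastive PCs regressed
#'   out of both datasets (default 4).
#' @param cpca_alpha Contrast weight on the cell-line covariance (default 1).
#' @param n_top_genes_per_dataset Genes per dataset entering the union gene
#'   set by moderated-F rank (default 1000).
#' @param k_cell_line Nearest cell lines per tumor in the MNN search
#'   (default 5).
#' @param k_tumor Nearest tumors per cell line in the MNN search (default 50).
#' @param mnn_sigma_multiplier Gaussian smoothing bandwidth as a multiple of
#'   the median squared tumor-to-pair distance (default 3).
#' @param k_classify Tumor neighbors voting on each cell line's type
#'   (default 25).
#' @param umap_n_neighbors,umap_min_dist UMAP parameters (defaults 10, 0.5).
#' @param rng_seed Seed for all stochastic stages (default 1).
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(n_pcs = 70L, snn_k = 20L, snn_prune = 1 / 15,
                            snn_resolution = 5, n_cpcs_removed = 4L,
                            cpca_alpha = 1, n_top_genes_per_dataset = 1000L,
                            k_cell_line = 5L, k_tumor = 50L,
                            mnn_sigma_multiplier = 3, k_classify = 25L,
                            umap_n_neighbors = 10L, umap_min_dist = 0.5,
                            rng_seed = 1L) {
  cfg <- list(n_pcs = as.integer(n_pcs), snn_k = as.integer(snn_k),
              snn_prune = snn_prune, snn_resolution = snn_resolution,
              n_cpcs_removed = as.integer(n_cpcs_removed),
              cpca_alpha = cpca_alpha,
              n_top_genes_per_dataset = as.integer(n_top_genes_per_dataset),
              k_cell_line = as.integer(k_cell_line),
              k_tumor = as.integer(k_tumor),
              mnn_sigma_multiplier = mnn_sigma_multiplier,
              k_classify = as.integer(k_classify),
              umap_n_neighbors = as.integer(umap_n_neighbors),
              umap_min_dist = umap_min_dist, rng_seed = as.integer(rng_seed))
  counts <- c("n_pcs", "snn_k", "n_cpcs_removed", "n_top_genes_per_dataset",
              "k_cell_line", "k_tumor", "k_classify", "umap_n_neighbors")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) stop("'", nm, "' must be a positive count")
  if (cfg$snn_resolution <= 0) stop("'snn_resolution' must be positive")
  if (cfg$mnn_sigma_multiplier <= 0) stop("'mnn_sigma_multiplier' must be positive")
  if (cfg$umap_min_dist < 0 || cfg$umap_min_dist >= 1)
    stop("'umap_min_dist' must be in [0, 1)")
  structure(cfg, class = "PipelineConfig")
}
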