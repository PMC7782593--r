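#' 2D UMAP embedding of the aligned combined data
#'
#' Reduces the combined aligned matrix to `n_pcs` principal components and
#' embeds them in 2D with UMAP (Euclidean metric, `n_neighbors = 10`,
#' `min_dist = 0.5` by default, matching the published visualization
#' settings). UMAP itself is visualization plumbing, not methodological
#' core, and is delegated to the umap-learn implementation available
#' through the `python` interpreter on the PATH; `random_state` is fixed
#' from the config seed so coordinates are reproducible.
#'
#' @param aligned_combined Samples x genes matrix of the aligned combined
#'   data (read-only; never modified).
#' @param config A [pipeline_config()] supplying `n_pcs`,
#'   `umap_n_neighbors`, `umap_min_dist`, and `rng_seed`.
#' @return A list of class `Embedding2D`: `sample_ids`, `coords` (samples x
#'   2), `params`.
#' @export
umap_embed <- function(aligned_combined, config = pipeline_config()) {
  stopifnot(is.matrix(aligned_combined))
  n <- nrow(aligned_combined)
  if (n < config$umap_n_neighbors + 1L)
    stop("need at least umap_n_neighbors + 1 samples")
  n_pcs <- min(config$n_pcs, n - 1L, ncol(aligned_combined))
  scores <- pca_reduce(aligned_combined, n_pcs)$scores
  coords <- run_umap_python(scores, config$umap_n_neighbors,
                            config$umap_min_dist, config$rng_seed)
  rownames(coords) <- rownames(aligned_combined)
  colnames(coords) <- c("umap1", "umap2")
  if (any(!is.finite(coords))) stop("UMAP returned non-finite coordinates")
  structure(list(sample_ids = rownames(aligned_combined), coords = coords,
                 params = list(n_pcs = n_pcs,
                               n_neighbors = config$umap_n_neighbors,
                               min_dist = config$umap_min_dist,
                               seed = config$rng_seed)),
            class = "Embedding2D")
}

run_umap_python <- function(scores, n_neighbors, min_dist, seed) {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "")
    stop("no 'python' interpreter on the PATH (required for the UMAP stage)")
  tmp_in <- tempfile(fileext = ".tsv")
  tmp_out <- tempfile(fileext = ".tsv")
  tmp_py <- tempfile(fileext = ".py")
  on.exit(unlink(c(tmp_in, tmp_out, tmp_py)))
  utils::write.table(scores, tmp_in, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import numpy as np",
    "import umap",
    "inp, outp, nn, md, seed = sys.argv[1:6]",
    "X = np.loadtxt(inp, delimiter='\\t', ndmin=2)",
    "emb = umap.UMAP(n_components=2, metric='euclidean',",
    "                n_neighbors=int(nn), min_dist=float(md),",
    "                random_state=int(seed), n_jobs=1).fit_transform(X)",
    "np.savetxt(outp, emb, delimiter='\\t')"
  ), tmp_py)
  status <- system2(python,
                    c(tmp_py, tmp_in, tmp_out, n_neighbors,
                      format(min_dist, digits = 17), seed),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp_out))
    stop("UMAP subprocess failed (exit status ", status,
         "); is umap-learn importable from 'python'?")
  as.matrix(utils::read.table(tmp_out, sep = "\t", header = FALSE))
}

#' Serialize an embedding as TSV
#' @param emb An `Embedding2D`.
#' @param path Output path.
#' @param annotations Optional data.frame with `sample_id`, `lineage`,
#'   `dataset` to merge in.
#' @export
write_embedding <- function(emb, path, annotations = NULL) {
  df <- data.frame(sample_id = emb$sample_ids,
                   umap1 = emb$coords[, 1], umap2 = emb$coords[, 2])
  if (!is.null(annotations)) {
    idx <- match(df$sample_id, annotations$sample_id)
    df$dataset <- annotations$dataset[idx]
    df$lineage <- annotations$lineage[idx]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
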