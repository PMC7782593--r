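#' Mutual nearest neighbors with asymmetric neighborhood sizes
#'
#' Finds cross-dataset pairs (c, t) such that cell line c is among tumor
#' t's `k_cl` nearest cell lines AND tumor t is among c's `k_t` nearest
#' tumors, with Euclidean distances computed on a gene subset. The
#' asymmetric k accounts for the tumor cohort being roughly an order of
#' magnitude larger than the cell-line panel. Neighbor search is exact
#' (brute force); ties are resolved by sample order, deterministically.
#'
#' @param cell_lines,tumors Samples x genes matrices on the same gene space
#'   (typically cPCA-residualized expression).
#' @param gene_subset Character vector of gene ids used for the distance
#'   computation (the union of cluster-variable genes).
#' @param k_cl Nearest cell lines per tumor (default 5).
#' @param k_t Nearest tumors per cell line (default 50).
#' @return A list of class `MNNPairing`: `pairs` (data.frame cell_line_id,
#'   tumor_id, distance), `k_cell_line`, `k_tumor`, `gene_subset`.
#' @export
find_mutual_nn <- function(cell_lines, tumors, gene_subset, k_cl = 5L, k_t = 50L) {
  stopifnot(is.matrix(cell_lines), is.matrix(tumors))
  if (length(gene_subset) == 0L) stop("empty gene subset")
  if (!all(gene_subset %in% colnames(cell_lines)) ||
      !all(gene_subset %in% colnames(tumors)))
    stop("gene_subset contains genes absent from the matrices")
  k_cl <- as.integer(k_cl); k_t <- as.integer(k_t)
  n_cl <- nrow(cell_lines); n_t <- nrow(tumors)
  if (k_cl < 1L || k_cl > n_cl) stop("k_cl must be in [1, n_cell_lines]")
  if (k_t < 1L || k_t > n_t) stop("k_t must be in [1, n_tumors]")
  u_cl <- cell_lines[, gene_subset, drop = FALSE]
  u_t <- tumors[, gene_subset, drop = FALSE]
  d2 <- euclidean_dist2(u_cl, u_t)                 # n_cl x n_t
  # for each tumor (column): k_cl nearest cell lines
  nn_cl_of_t <- apply(d2, 2L, function(col) order(col)[seq_len(k_cl)])
  nn_cl_of_t <- matrix(nn_cl_of_t, nrow = k_cl)
  # for each cell line (row): k_t nearest tumors
  nn_t_of_cl <- apply(d2, 1L, function(row) order(row)[seq_len(k_t)])
  nn_t_of_cl <- matrix(nn_t_of_cl, nrow = k_t)
  in_cl_nn <- matrix(FALSE, n_cl, n_t)
  in_cl_nn[cbind(as.integer(nn_cl_of_t), rep(seq_len(n_t), each = k_cl))] <- TRUE
  in_t_nn <- matrix(FALSE, n_cl, n_t)
  in_t_nn[cbind(rep(seq_len(n_cl), each = k_t), as.integer(nn_t_of_cl))] <- TRUE
  hit <- which(in_cl_nn & in_t_nn, arr.ind = TRUE)
  ord <- order(hit[, 1L], hit[, 2L])
  hit <- hit[ord, , drop = FALSE]
  pairs <- data.frame(
    cell_line_id = rownames(cell_lines)[hit[, 1L]],
    tumor_id = rownames(tumors)[hit[, 2L]],
    distance = sqrt(d2[hit]),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, k_cell_line = k_cl, k_tumor = k_t,
                 gene_subset = gene_subset),
            class = "MNNPairing")
}

#' @export
print.MNNPairing <- function(x, ...) {
  cat(sprintf("MNNPairing: %d pairs (%d cell lines, %d tumors; k = %d / %d)\n",
              nrow(x$pairs), length(unique(x$pairs$cell_line_id)),
              length(unique(x$pairs$tumor_id)), x$k_cell_line, x$k_tumor))
  invisible(x)
}

#' Gaussian-smoothed correction vectors for every tumor
#'
#' Each MNN pair p contributes a raw correction vector
#' d_p = expression(cell line) - expression(tumor) over ALL genes. The
#' correction assigned to tumor t is a Gaussian-kernel weighted average of
#' the d_p, with weights exp(-||u_t - u_tumor(p)||^2 / sigma^2) computed in
#' the gene-subset space and normalized to sum to one. The bandwidth is
#' sigma^2 = sigma_multiplier x median squared distance between tumors and
#' pair tumors, a scale-free default. Every tumor, paired or not, receives
#' a correction; a tumor with numerically zero total weight falls back to
#' the unweighted mean of all pair vectors, with a warning.
#'
#' @param pairing An `MNNPairing` (nonempty).
#' @param cell_lines,tumors The same matrices used for pairing.
#' @param sigma_multiplier Bandwidth multiplier (default 3).
#' @return A list of class `CorrectionField`: `tumor_ids`, `vectors`
#'   (tumors x genes), `sigma2`.
#' @export
compute_correction <- function(pairing, cell_lines, tumors, sigma_multiplier = 3) {
  stopifnot(inherits(pairing, "MNNPairing"))
  pairs <- pairing$pairs
  if (nrow(pairs) == 0L) stop("empty pairing")
  cl_idx <- match(pairs$cell_line_id, rownames(cell_lines))
  t_idx <- match(pairs$tumor_id, rownames(tumors))
  if (anyNA(cl_idx) || anyNA(t_idx)) stop("pairing refers to unknown samples")
  d_p <- cell_lines[cl_idx, , drop = FALSE] - tumors[t_idx, , drop = FALSE]
  u_t <- tumors[, pairing$gene_subset, drop = FALSE]
  u_pair <- u_t[t_idx, , drop = FALSE]
  d2 <- euclidean_dist2(u_t, u_pair)               # tumors x pairs
  sigma2 <- sigma_multiplier * stats::median(d2)
  w <- if (sigma2 <= .Machine$double.eps) (d2 == 0) * 1 else exp(-d2 / sigma2)
  tot <- rowSums(w)
  dead <- tot <= .Machine$double.xmin
  if (any(dead)) {
    warning(sum(dead), " tumors with zero total kernel weight: ",
            "falling back to the unweighted mean pair vector")
    w[dead, ] <- 1
    tot[dead] <- ncol(w)
  }
  vectors <- (w / tot) %*% d_p
  rownames(vectors) <- rownames(tumors)
  structure(list(tumor_ids = rownames(tumors), vectors = vectors,
                 sigma2 = sigma2),
            class = "CorrectionField")
}

#' Apply a correction field to the tumor matrix
#'
#' Adds each tumor's smoothed correction vector, moving tumors toward the
#' cell-line reference. Cell lines are left untouched by this stage.
#'
#' @param tumors Samples x genes tumor matrix.
#' @param field A `CorrectionField` covering all tumors.
#' @return Corrected tumors matrix, same shape and dimnames.
#' @export
apply_correction <- function(tumors, field) {
  stopifnot(is.matrix(tumors), inherits(field, "CorrectionField"))
  idx <- match(rownames(tumors), field$tumor_ids)
  if (anyNA(idx)) stop("correction field does not cover all tumor samples")
  if (ncol(field$vectors) != ncol(tumors)) stop("gene dimension mismatch")
  tumors + field$vectors[idx, , drop = FALSE]
}

#' Serialize MNN pairs as TSV
#' @param pairing An `MNNPairing`.
#' @param path Output path.
#' @export
write_mnn_pairs <- function(pairing, path) {
  utils::write.table(pairing$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
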