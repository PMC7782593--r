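#' Gene-centered principal component analysis
#'
#' PCA on the gene-mean-centered expression matrix (no variance scaling),
#' computed by dense SVD. The sign of each component is fixed by making the
#' largest-magnitude loading entry positive, so results are reproducible
#' across platforms.
#'
#' @param x An [expression_matrix()] or a plain samples x genes matrix.
#' @param n_pcs Number of components to retain; must not exceed
#'   `min(n_samples - 1, n_genes)`.
#' @return A list of class `PCAModel` with `loadings` (genes x n_pcs,
#'   orthonormal columns), `scores` (samples x n_pcs), `gene_means`, and
#'   `explained_variance` (nonincreasing).
#' @export
pca_reduce <- function(x, n_pcs) {
  m <- if (inherits(x, "ExpressionMatrix")) x$values else x
  stopifnot(is.matrix(m))
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1L || n_pcs > min(nrow(m) - 1L, ncol(m)))
    stop("n_pcs must be in [1, min(n_samples - 1, n_genes)]")
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  if (max(abs(xc)) == 0) {
    # all samples identical: zero centered variance, all scores exactly 0
    loadings <- diag(1, ncol(m), n_pcs)
    rownames(loadings) <- colnames(m)
    scores <- matrix(0, nrow(m), n_pcs, dimnames = list(rownames(m), NULL))
    return(structure(list(loadings = loadings, scores = scores,
                          gene_means = mu,
                          explained_variance = rep(0, n_pcs)),
                     class = "PCAModel"))
  }
  sv <- svd(xc, nu = n_pcs, nv = n_pcs)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  # fix sign: largest-|entry| loading coordinate positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(m)
  rownames(scores) <- rownames(m)
  structure(list(loadings = loadings, scores = scores, gene_means = mu,
                 explained_variance = sv$d[seq_len(n_pcs)]^2 / (nrow(m) - 1L)),
            class = "PCAModel")
}

euclidean_dist2 <- function(a, b = a) {
  # squared Euclidean distances between rows of a and rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Shared-nearest-neighbor graph
#'
#' Each sample's k nearest neighbors (Euclidean, self included) define a
#' neighbor set; the edge weight between two samples is the Jaccard overlap
#' of their neighbor sets. Edges below the prune threshold are removed.
#'
#' @param scores Samples x d numeric matrix (typically PCA scores).
#' @param k Neighbor count, `0 < k < n_samples`.
#' @param prune Minimum Jaccard weight for an edge to be kept (default 1/15).
#' @return A weighted undirected [igraph::graph] whose vertices are named by
#'   the rownames of `scores`.
#' @export
build_snn_graph <- function(scores, k, prune = 1 / 15) {
  stopifnot(is.matrix(scores))
  n <- nrow(scores)
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of samples")
  d2 <- euclidean_dist2(scores)
  # neighbor sets include self; ties resolved by index order (deterministic)
  nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.integer(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)          # |A_i intersect A_j|
  shared <- as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j                # upper triangle, no self loops
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k - shared@x[keep])   # Jaccard: |A^B|/|AvB|
  ok <- w >= prune
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  igraph::V(g)$name <- ids
  if (any(ok))
    g <- igraph::add_edges(g, rbind(i[ok], j[ok]), weight = w[ok])
  g
}

#' Graph community detection
#'
#' Leiden community detection maximizing resolution-parameterized modularity
#' on the (weighted) SNN graph. Deterministic for a fixed seed. A graph with
#' no edges yields one singleton cluster per node, with a warning.
#'
#' @param graph An igraph object with named vertices (edge attribute
#'   `weight` used if present).
#' @param resolution Modularity resolution; larger values give more,
#'   smaller communities.
#' @param rng_seed Integer seed.
#' @param dataset Tag stored on the result (`"tumor"`, `"cell_line"`, or
#'   any label for joint clusterings).
#' @return A list of class `ClusterAssignment` with `sample_ids`, `labels`
#'   (contiguous integers from 0), `dataset`, and `resolution`.
#' @export
cluster_graph <- function(graph, resolution, rng_seed = 1L, dataset = "combined") {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(graph)))
  if (igraph::ecount(graph) == 0L) {
    warning("graph has no edges: every node assigned its own cluster")
    labels <- seq_len(igraph::vcount(graph)) - 1L
  } else {
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, igraph::ecount(graph))
    set.seed(rng_seed)
    comm <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                   resolution = resolution, weights = w,
                                   n_iterations = 4L)
    memb <- igraph::membership(comm)
    # relabel to contiguous 0-based labels, ordered by first appearance
    labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  }
  structure(list(sample_ids = ids, labels = labels, dataset = dataset,
                 resolution = resolution), class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment [%s]: %d samples, %d clusters (resolution %g)\n",
              x$dataset, length(x$labels), length(unique(x$labels)), x$resolution))
  invisible(x)
}

#' Remove per-cluster mean expression
#'
#' Subtracts each cluster's mean profile from its member samples, leaving
#' residuals whose within-cluster mean is zero for every gene. These
#' residuals carry the intra-cluster (within-type) covariance that the
#' contrastive PCA stage contrasts between datasets.
#'
#' @param x An `ExpressionMatrix` or samples x genes matrix.
#' @param clusters A `ClusterAssignment` covering all samples of `x`.
#' @return Samples x genes residual matrix (same dimnames as the input).
#' @export
subtract_cluster_means <- function(x, clusters) {
  m <- if (inherits(x, "ExpressionMatrix")) x$values else x
  stopifnot(inherits(clusters, "ClusterAssignment"))
  idx <- match(rownames(m), clusters$sample_ids)
  if (anyNA(idx)) stop("clusters do not cover all samples of the matrix")
  lab <- clusters$labels[idx]
  if (length(unique(clusters$labels)) > length(unique(lab)))
    stop("cluster with zero samples in the matrix")
  f <- factor(lab)
  centers <- rowsum(m, f) / as.vector(table(f))
  m - centers[as.integer(f), , drop = FALSE]
}

#' Serialize a cluster assignment as TSV
#' @param clusters A `ClusterAssignment`.
#' @param path Output path.
#' @export
write_cluster_assignment <- function(clusters, path) {
  utils::write.table(
    data.frame(sample_id = clusters$sample_ids, cluster = clusters$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
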