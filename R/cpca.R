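#' Intra-cluster covariance operator
#'
#' Wraps the cluster-mean residual matrix R as the covariance operator
#' C = R'R / (n - 1) without ever forming the genes x genes matrix. The
#' operator supports matrix-vector products ([cov_apply()]) and, for small
#' gene spaces, densification ([cov_dense()]).
#'
#' @param residuals Samples x genes residual matrix from
#'   [subtract_cluster_means()].
#' @return A list of class `CovarianceOperator` with `residuals`, `n`, and
#'   `gene_ids`.
#' @export
intra_cluster_covariance <- function(residuals) {
  stopifnot(is.matrix(residuals))
  if (nrow(residuals) <= 1L) stop("need more than one sample")
  structure(list(residuals = residuals, n = nrow(residuals),
                 gene_ids = colnames(residuals)),
            class = "CovarianceOperator")
}

#' @rdname intra_cluster_covariance
#' @param op A `CovarianceOperator`.
#' @param v Genes x m matrix (or vector) to multiply.
#' @export
cov_apply <- function(op, v) {
  v <- as.matrix(v)
  crossprod(op$residuals, op$residuals %*% v) / (op$n - 1)
}

#' @rdname intra_cluster_covariance
#' @export
cov_dense <- function(op) crossprod(op$residuals) / (op$n - 1)

#' Contrastive principal components
#'
#' Eigen-decomposition of the covariance contrast
#' D = C_tumor - alpha * C_cell_line, returning the directions with the
#' largest algebraic eigenvalues: expression signatures whose intra-cluster
#' variance is enriched in tumors relative to cell lines (the contamination
#' axes). Below `dense_cutoff` genes the dense symmetric eigensolver is
#' used; above it, shifted subspace iteration on the implicit operator
#' (contracted to match the dense solve to 1e-6 relative eigenvalue error).
#'
#' @param c_tumor,c_cell_line `CovarianceOperator`s over the same gene space.
#' @param n_components Number of leading components to return.
#' @param alpha Contrast weight on the cell-line (background) covariance
#'   (default 1).
#' @param dense_cutoff Gene count above which the iterative solver is used
#'   (default 3000).
#' @return A list of class `ContrastiveComponents`: `loadings` (genes x
#'   n_components, orthonormal, sign-fixed), `eigenvalues` (nonincreasing),
#'   `contrast_alpha`, `gene_ids`.
#' @export
contrastive_components <- function(c_tumor, c_cell_line, n_components,
                                   alpha = 1, dense_cutoff = 3000L) {
  stopifnot(inherits(c_tumor, "CovarianceOperator"),
            inherits(c_cell_line, "CovarianceOperator"))
  p <- ncol(c_tumor$residuals)
  if (ncol(c_cell_line$residuals) != p)
    stop("operators are over different gene spaces")
  if (!is.null(c_tumor$gene_ids) && !is.null(c_cell_line$gene_ids) &&
      !identical(c_tumor$gene_ids, c_cell_line$gene_ids))
    stop("gene id order differs between the two operators")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > p)
    stop("n_components must be in [1, n_genes]")

  if (p <= dense_cutoff) {
    d <- cov_dense(c_tumor) - alpha * cov_dense(c_cell_line)
    es <- eigen(d, symmetric = TRUE)
    vals <- es$values[seq_len(n_components)]
    vecs <- es$vectors[, seq_len(n_components), drop = FALSE]
  } else {
    res <- top_eigen_contrast(c_tumor, c_cell_line, alpha, n_components)
    vals <- res$values
    vecs <- res$vectors
  }
  for (j in seq_len(n_components)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- c_tumor$gene_ids
  structure(list(loadings = vecs, eigenvalues = vals, contrast_alpha = alpha,
                 gene_ids = c_tumor$gene_ids),
            class = "ContrastiveComponents")
}

# Largest algebraic eigenpairs of D = C_t - alpha C_cl via shifted subspace
# iteration: iterate on D + sigma I (positive definite for sigma > ||D||),
# whose dominant eigenvectors are D's largest-algebraic ones.
top_eigen_contrast <- function(c_tumor, c_cell_line, alpha, k,
                               tol = 1e-9, max_iter = 500L) {
  p <- ncol(c_tumor$residuals)
  apply_d <- function(v) cov_apply(c_tumor, v) - alpha * cov_apply(c_cell_line, v)
  # crude spectral-norm bound via triangle inequality on the two PSD terms
  norm_est <- function(op) {
    v <- rep(1 / sqrt(p), p)
    for (i in 1:20) {
      w <- cov_apply(op, v)
      nv <- sqrt(sum(w^2))
      if (nv == 0) return(0)
      v <- w / nv
    }
    nv
  }
  sigma <- 1.1 * (norm_est(c_tumor) + abs(alpha) * norm_est(c_cell_line)) + 1e-12
  b <- min(p, k + 10L)
  # internal starting basis only; result is seed-independent at tol, and the
  # caller's RNG stream is left untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(2203L)
  q <- qr.Q(qr(matrix(stats::rnorm(p * b), p, b)))
  vals_old <- rep(Inf, k)
  for (it in seq_len(max_iter)) {
    z <- apply_d(q) + sigma * q
    q <- qr.Q(qr(z))
    h <- crossprod(q, apply_d(q))
    h <- (h + t(h)) / 2
    es <- eigen(h, symmetric = TRUE)
    vals <- es$values[seq_len(k)]
    if (max(abs(vals - vals_old) / pmax(abs(vals), 1e-12)) < tol) {
      q <- q %*% es$vectors
      return(list(values = vals, vectors = q[, seq_len(k), drop = FALSE]))
    }
    vals_old <- vals
    q <- q %*% es$vectors
  }
  stop("contrastive eigensolver did not converge in ", max_iter,
       " iterations (last eigenvalues: ", paste(signif(vals, 6), collapse = ", "), ")")
}

#' Regress contrastive components out of an expression matrix
#'
#' Computes sample scores S = X_centered V on the first `n_remove` loadings
#' and residualizes every gene on S by least squares, adding gene means
#' back. Because S is exactly the projection of the centered data on V, the
#' residual has zero covariance with S and zero loading on V, making the
#' operation idempotent. The same loadings (derived from the tumor-vs-cell-
#' line contrast) are applied to both datasets, each centered on its own
#' gene means.
#'
#' @param x An `ExpressionMatrix` or samples x genes matrix.
#' @param comps A `ContrastiveComponents` over the same genes.
#' @param n_remove How many leading components to remove (default: all in
#'   `comps`); `0` returns the input unchanged.
#' @return Samples x genes numeric matrix with the components removed.
#'   Residualized values are real-valued and no longer bounded below by 0,
#'   so a plain matrix (not an `ExpressionMatrix`) is returned even for
#'   `ExpressionMatrix` input.
#' @export
regress_out_components <- function(x, comps, n_remove = ncol(comps$loadings)) {
  is_em <- inherits(x, "ExpressionMatrix")
  m <- if (is_em) x$values else x
  stopifnot(is.matrix(m), inherits(comps, "ContrastiveComponents"))
  n_remove <- as.integer(n_remove)
  if (n_remove > ncol(comps$loadings)) stop("n_remove exceeds available components")
  if (n_remove == 0L) return(m)
  v <- comps$loadings[, seq_len(n_remove), drop = FALSE]
  if (!is.null(rownames(v))) {
    if (!all(colnames(m) %in% rownames(v))) stop("gene mismatch with loadings")
    v <- v[colnames(m), , drop = FALSE]
  }
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  s <- xc %*% v
  if (max(abs(s)) > 1e-12) {
    qs <- qr(s)
    xc <- qr.resid(qs, xc)
  }
  out <- sweep(xc, 2L, mu, "+")
  dimnames(out) <- dimnames(m)
  out
}

#' Serialize contrastive loadings and eigenvalue scree as TSV
#' @param comps A `ContrastiveComponents`.
#' @param loadings_path,scree_path Output paths (either may be `NULL`).
#' @export
write_contrastive_components <- function(comps, loadings_path = NULL,
                                         scree_path = NULL) {
  if (!is.null(loadings_path)) {
    df <- data.frame(gene_id = comps$gene_ids, comps$loadings,
                     check.names = FALSE)
    colnames(df)[-1] <- paste0("cPC", seq_len(ncol(comps$loadings)))
    utils::write.table(df, loadings_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(scree_path))
    utils::write.table(
      data.frame(rank = seq_along(comps$eigenvalues),
                 eigenvalue = comps$eigenvalues),
      scree_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(comps)
}
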