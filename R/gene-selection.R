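#' Empirical-Bayes moderated F-statistics for between-cluster variability
#'
#' Ranks genes by how strongly their expression varies across the clusters
#' of one dataset, using a one-way cluster-means model per gene with an
#' empirical-Bayes shrunken residual variance in the denominator.
#'
#' For gene g with cluster sizes n_c, cluster means xbar_cg and grand mean
#' xbar_g:
#'   MS_between_g = sum_c n_c (xbar_cg - xbar_g)^2 / (k - 1)
#'   s_g^2        = residual mean square, d = n - k degrees of freedom.
#' The prior (d0, s0^2) is estimated by matching the first two moments of
#' log s_g^2 to a scaled F distribution (Smyth's method of moments); the
#' moderated variance is s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d) and
#' F_g = MS_between_g / s~_g^2. Genes with zero variance everywhere get
#' F = 0. If the sample variances are too degenerate to fit the prior the
#' function falls back to d0 = Inf (pure prior variance) with a warning.
#'
#' @param x Samples x genes matrix (or `ExpressionMatrix`), log2(TPM+1).
#' @param clusters A `ClusterAssignment` covering the samples of `x`, with
#'   at least 2 clusters and residual degrees of freedom `n - k >= 1`.
#' @return A list of class `GeneVariabilityTable`: `gene_ids`, `f_stat`,
#'   `ms_between`, `s2`, `residual_df`, `prior_df` (d0), `prior_var` (s0^2),
#'   `dataset`.
#' @export
moderated_f_stats <- function(x, clusters) {
  m <- if (inherits(x, "ExpressionMatrix")) x$values else x
  stopifnot(is.matrix(m), inherits(clusters, "ClusterAssignment"))
  idx <- match(rownames(m), clusters$sample_ids)
  if (anyNA(idx)) stop("clusters do not cover all samples")
  f <- factor(clusters$labels[idx])
  k <- nlevels(f)
  n <- nrow(m)
  if (k < 2L) stop("need at least 2 clusters")
  d <- n - k
  if (d < 1L) stop("residual degrees of freedom n - n_clusters must be >= 1")
  nc <- as.vector(table(f))
  centers <- rowsum(m, f) / nc                      # k x genes cluster means
  grand <- colMeans(m)
  ms_between <- colSums(nc * sweep(centers, 2L, grand)^2) / (k - 1L)
  resid <- m - centers[as.integer(f), , drop = FALSE]
  s2 <- colSums(resid^2) / d

  prior <- fit_f_dist(s2, d)
  d0 <- prior$df
  s02 <- prior$scale
  s2_mod <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  fstat <- ifelse(ms_between == 0, 0, ms_between / s2_mod)
  if (any(!is.finite(fstat))) stop("non-finite moderated F-statistics")
  structure(list(gene_ids = colnames(m), f_stat = unname(fstat),
                 ms_between = unname(ms_between), s2 = unname(s2),
                 residual_df = d, prior_df = d0, prior_var = s02,
                 dataset = clusters$dataset),
            class = "GeneVariabilityTable")
}

# Smyth's moment estimator for an s^2 ~ s0^2 F(d, d0) model:
# z = log s^2 has mean log s0^2 + digamma(d/2) - log(d/2)
#                 - digamma(d0/2) + log(d0/2)
# and variance trigamma(d/2) + trigamma(d0/2).
fit_f_dist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    warning("degenerate sample variances: falling back to d0 = Inf")
    return(list(df = Inf, scale = if (any(ok)) exp(mean(log(s2[ok]))) else 1))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  target <- evar - trigamma(df / 2)
  if (is.na(target) || target <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df = d0, scale = s02)
}

# Newton solve of trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Union of the most cluster-variable genes of each dataset
#'
#' Takes the `n_top` genes with the highest moderated F-statistic from each
#' of the two tables and returns the union. Ties at the cutoff are broken by
#' gene id lexicographic order so the selection is deterministic.
#'
#' @param tumor_table,cl_table `GeneVariabilityTable`s over the same genes.
#' @param n_top Genes per dataset (default 1000).
#' @return Character vector of gene ids, lexicographically sorted; its size
#'   lies in `[n_top, 2 * n_top]`.
#' @export
select_union_genes <- function(tumor_table, cl_table, n_top = 1000L) {
  stopifnot(inherits(tumor_table, "GeneVariabilityTable"),
            inherits(cl_table, "GeneVariabilityTable"))
  if (!setequal(tumor_table$gene_ids, cl_table$gene_ids))
    stop("tables must share the same gene universe")
  n_top <- as.integer(n_top)
  if (n_top > length(tumor_table$gene_ids)) stop("n_top exceeds gene count")
  top_of <- function(tab) {
    ord <- order(-tab$f_stat, tab$gene_ids, method = "radix")
    tab$gene_ids[ord[seq_len(n_top)]]
  }
  sort(union(top_of(tumor_table), top_of(cl_table)), method = "radix")
}

#' @export
print.GeneVariabilityTable <- function(x, ...) {
  cat(sprintf("GeneVariabilityTable [%s]: %d genes, d = %g, d0 = %g, s0^2 = %.4g\n",
              x$dataset, length(x$gene_ids), x$residual_df, x$prior_df, x$prior_var))
  invisible(x)
}

#' Serialize a gene variability table as TSV
#' @param tab A `GeneVariabilityTable`.
#' @param path Output path.
#' @export
write_gene_variability <- function(tab, path) {
  utils::write.table(
    data.frame(gene_id = tab$gene_ids, f_stat = tab$f_stat, dataset = tab$dataset),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
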