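test_that("pca_reduce matches the closed-form eigendecomposition", {
  # construct data whose sample covariance is exactly [[2,1],[1,2]]:
  # eigenvectors (1,1)/sqrt(2), (1,-1)/sqrt(2), eigenvalues 3 and 1
  s1 <- c(sqrt(3), 0, -sqrt(3))          # crossprod/(n-1) = 3
  s2 <- c(1, -2, 1) / sqrt(3)            # crossprod/(n-1) = 1, orthogonal
  v <- cbind(c(1, 1), c(1, -1)) / sqrt(2)
  x <- cbind(s1, s2) %*% t(v) + 5
  dimnames(x) <- list(paste0("s", 1:3), c("gA", "gB"))
  p <- pca_reduce(x, 2)
  expect_equal(p$explained_variance, c(3, 1))
  expect_equal(abs(drop(crossprod(p$loadings[, 1], c(1, 1) / sqrt(2)))), 1,
               tolerance = 1e-12)
  # sign convention: largest-|entry| coordinate positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  # scores reproduce the centered data projection
  expect_equal(p$scores, sweep(x, 2, colMeans(x)) %*% p$loadings,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pca_reduce handles degenerate and full-rank inputs", {
  x <- matrix(3, 4, 3, dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  p <- pca_reduce(x, 2)
  expect_true(all(p$scores == 0))

  set.seed(7)
  y <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  p5 <- pca_reduce(y, 5)
  # orthonormal loadings and full reconstruction of the centered data
  expect_equal(crossprod(p5$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(p5$scores %*% t(p5$loadings), sweep(y, 2, colMeans(y)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p5$explained_variance) <= 1e-12))
  expect_error(pca_reduce(y, 8), "n_pcs")
})

test_that("SNN graph weights equal brute-force Jaccard overlaps", {
  set.seed(1)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("p", 1:10), NULL))
  g <- build_snn_graph(pts, 3, prune = 0)
  d2 <- as.matrix(dist(pts))^2
  nnsets <- lapply(1:10, function(i) order(d2[i, ])[1:3])
  ew <- igraph::as_data_frame(g)
  expect_gt(nrow(ew), 0)
  for (r in seq_len(nrow(ew))) {
    i <- match(ew$from[r], rownames(pts))
    j <- match(ew$to[r], rownames(pts))
    jac <- length(intersect(nnsets[[i]], nnsets[[j]])) /
      length(union(nnsets[[i]], nnsets[[j]]))
    expect_equal(ew$weight[r], jac, tolerance = 1e-12)
  }
  # all brute-force nonzero overlaps present as edges (prune = 0)
  n_overlap <- sum(utils::combn(10, 2, function(ij)
    length(intersect(nnsets[[ij[1]]], nnsets[[ij[2]]])) > 0))
  expect_identical(nrow(ew), as.integer(n_overlap))

  # identical neighbor sets give weight 1; disjoint sets give no edge
  two <- rbind(a = c(0, 0), b = c(0.1, 0), far1 = c(100, 100),
               far2 = c(100.1, 100))
  g2 <- build_snn_graph(two, 2, prune = 1 / 15)
  expect_equal(igraph::E(g2)$weight[igraph::get_edge_ids(g2, c("a", "b"))], 1)
  expect_identical(igraph::get_edge_ids(g2, c("a", "far1")), 0)
  expect_error(build_snn_graph(two, 0), "positive")
})

test_that("community detection recovers structure deterministically", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("v", 1:10)
  igraph::E(g)$weight <- 1
  c1 <- cluster_graph(g, resolution = 1, rng_seed = 7, dataset = "tumor")
  expect_identical(length(unique(c1$labels)), 2L)
  expect_identical(sort(unique(c1$labels)), 0:1)
  # the two cliques are exactly the two clusters
  expect_identical(length(unique(c1$labels[1:5])), 1L)
  expect_identical(length(unique(c1$labels[6:10])), 1L)
  expect_false(c1$labels[1] == c1$labels[6])
  c2 <- cluster_graph(g, resolution = 1, rng_seed = 7, dataset = "tumor")
  expect_identical(c1$labels, c2$labels)

  # higher resolution never yields fewer clusters on a frozen random graph
  set.seed(42)
  pts <- matrix(rnorm(120), 60, 2, dimnames = list(paste0("s", 1:60), NULL))
  gg <- build_snn_graph(pts, 8)
  n_lo <- length(unique(cluster_graph(gg, 0.5, 1)$labels))
  n_hi <- length(unique(cluster_graph(gg, 5, 1)$labels))
  expect_gte(n_hi, n_lo)

  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  expect_warning(c0 <- cluster_graph(g0, 1, 1), "no edges")
  expect_identical(c0$labels, 0:2)
})

test_that("subtract_cluster_means zeroes every within-cluster gene mean", {
  # single cluster reduces to ordinary column centering
  x <- matrix(runif(12), 4, 3, dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  cl1 <- make_clusters(rownames(x), rep(0, 4))
  expect_equal(subtract_cluster_means(x, cl1), sweep(x, 2, colMeans(x)),
               tolerance = 1e-12)

  # hand-computed two-cluster case
  y <- rbind(s1 = c(1, 3), s2 = c(3, 3), s3 = c(10, 0))
  colnames(y) <- c("g1", "g2")
  cl2 <- make_clusters(rownames(y), c(0, 0, 1))
  expect_equal(subtract_cluster_means(y, cl2),
               rbind(s1 = c(-1, 0), s2 = c(1, 0), s3 = c(0, 0)),
               ignore_attr = TRUE, tolerance = 1e-12)

  set.seed(3)
  z <- matrix(rnorm(100, mean = 4), 20, 5,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:5)))
  lab <- rep(0:2, c(7, 6, 7))
  cl3 <- make_clusters(rownames(z), lab)
  r <- subtract_cluster_means(z, cl3)
  for (l in 0:2)
    expect_lt(max(abs(colMeans(r[lab == l, , drop = FALSE]))), 1e-12)
  # cluster-indicator regressors explain none of the residual
  ind <- model.matrix(~ 0 + factor(lab))
  expect_lt(max(abs(crossprod(ind, r))), 1e-8)

  expect_error(subtract_cluster_means(z, make_clusters(rownames(z)[1:10],
                                                       rep(0, 10))),
               "cover")
  expect_error(subtract_cluster_means(z, make_clusters(rownames(z),
                                                       c(rep(0, 19), 5))),
               NA)  # two non-contiguous labels still fine: both populated
})
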