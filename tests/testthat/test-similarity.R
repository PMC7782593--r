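test_that("pairwise correlations match the textbook formula", {
  set.seed(20)
  cl <- matrix(rnorm(24, mean = 4), 4, 6,
               dimnames = list(paste0("c", 1:4), paste0("g", 1:6)))
  tm <- matrix(rnorm(18, mean = 4), 3, 6,
               dimnames = list(paste0("t", 1:3), paste0("g", 1:6)))
  co <- pairwise_correlation(cl, tm)
  for (i in 1:4) for (j in 1:3) {
    x <- cl[i, ]; y <- tm[j, ]
    want <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(co[i, j], want, tolerance = 1e-12)
  }
  # exact copy correlates at 1; anti-correlated construction at -1
  tm2 <- rbind(t1 = cl[1, ], t2 = mean(cl[2, ]) - (cl[2, ] - mean(cl[2, ])))
  colnames(tm2) <- colnames(cl)
  co2 <- pairwise_correlation(cl, tm2)
  expect_equal(co2[1, "t1"], 1, tolerance = 1e-12)
  expect_equal(co2[2, "t2"], -1, tolerance = 1e-12)

  flat <- rbind(t1 = rep(2, 6)); colnames(flat) <- colnames(cl)
  expect_error(pairwise_correlation(cl, flat), "zero-variance tumor.*t1")
})

test_that("classification takes the modal type with documented tie-breaks", {
  types <- setNames(rep(c("lung", "skin", "brain"), c(13, 12, 5)),
                    paste0("t", sprintf("%02d", 1:30)))
  # unanimity
  r_un <- setNames(c(seq(0.9, 0.8, length.out = 13), rep(0.1, 17)), names(types))
  co <- rbind(cl1 = r_un)
  expect_identical(classify_cell_lines(co, types, k = 13)$predicted_type, "lung")

  # engineered 13-vs-12 split among the top 25
  r_split <- setNames(c(seq(0.99, 0.90, length.out = 13),
                        seq(0.89, 0.80, length.out = 12), rep(0, 5)),
                      names(types))
  co2 <- rbind(cl1 = r_split)
  got <- classify_cell_lines(co2, types, k = 25)
  expect_identical(got$predicted_type, "lung")
  expect_identical(got$neighbor_ids[[1]][1], "t01")
  expect_identical(oracle_vote(r_split, types, 25), "lung")

  # 12-12-1 vote: the tie goes to the larger summed correlation
  types3 <- setNames(rep(c("a_low", "b_high", "c"), c(12, 12, 6)),
                     paste0("t", sprintf("%02d", 1:30)))
  r3 <- setNames(c(rep(0.5, 12), rep(0.6, 12), 0.7, rep(0, 5)), names(types3))
  co3 <- rbind(cl1 = r3)
  expect_identical(classify_cell_lines(co3, types3, k = 25)$predicted_type,
                   oracle_vote(r3, types3, 25))
  expect_identical(classify_cell_lines(co3, types3, k = 25)$predicted_type,
                   "b_high")

  # invariance to tumor reordering and to monotone transforms
  set.seed(21)
  co4 <- matrix(runif(3 * 30), 3, 30,
                dimnames = list(paste0("c", 1:3), names(types)))
  base <- classify_cell_lines(co4, types, k = 7)$predicted_type
  perm <- sample(30)
  expect_identical(
    classify_cell_lines(co4[, perm], types, k = 7)$predicted_type, base)
  expect_identical(
    classify_cell_lines(tanh(2 * co4), types, k = 7)$predicted_type, base)
})

test_that("agreement_score filters on the tumor type universe", {
  pred <- setNames(c("lung", "skin", "lung", "gut", "eye"), paste0("c", 1:5))
  ann <- setNames(c("lung", "lung", "lung", "gut", "rare"), paste0("c", 1:5))
  sc <- agreement_score(pred, ann, c("lung", "skin", "gut"))
  expect_identical(sc$n_evaluated, 4L)     # 'rare' not among tumors
  expect_equal(sc$agreement, 3 / 4)
  expect_equal(agreement_score(ann, ann, unique(ann))$agreement, 1)
  expect_error(agreement_score(pred, ann, "mars"), "no cell line")

  # hand count: 10 cell lines, 7 evaluable, 4 matches
  pred10 <- setNames(c(rep("a", 5), rep("b", 5)), paste0("c", 1:10))
  ann10 <- setNames(c("a", "a", "b", "b", "x", "b", "b", "a", "x", "x"),
                    paste0("c", 1:10))
  sc10 <- agreement_score(pred10, ann10, c("a", "b"))
  expect_identical(sc10$n_evaluated, 7L)
  expect_equal(sc10$agreement, 4 / 7)
})

test_that("cluster composition counts, fractions and flags", {
  ca <- make_clusters(c(paste0("c", 1:3), "t1", "t2", "t3"),
                      c(0, 0, 0, 0, 1, 1), dataset = "combined")
  ann <- data.frame(sample_id = c(paste0("c", 1:3), "t1", "t2"),
                    lineage = c("lung", "lung", "skin", "lung", "skin"),
                    dataset = c(rep("cell_line", 3), "tumor", "tumor"))
  comp <- cluster_composition(ca, ann)
  s <- comp$summary
  expect_equal(s$cell_line_fraction[s$cluster == 0], 0.75)
  expect_true(s$flagged[s$cluster == 0])
  expect_false(s$flagged[s$cluster == 1])
  # unannotated sample counted as lineage 'unknown'
  lc <- comp$lineage_counts
  expect_identical(lc$n[lc$cluster == 1 & lc$lineage == "unknown"], 1L)
})

test_that("alignment restores cell-line type classification", {
  run <- default_run()
  expect_gte(run$rep_post$agreement, 0.9)
  # pre-alignment agreement is materially lower (purity-dominated ranking)
  expect_lt(run$rep_pre$agreement, run$rep_post$agreement - 0.1)
  expect_identical(run$rep_post$n_evaluated,
                   sum(run$cl_ann$lineage %in% run$t_ann$lineage))
})

test_that("a planted cell-line-only state is flagged in the joint clustering", {
  # constructed combined dataset: two well-mixed tumor/cell-line states and
  # one isolated cell-line-only state
  set.seed(23)
  p <- 40
  centers <- matrix(rnorm(3 * p, sd = 4), 3, p)
  mk <- function(center, n, prefix)
    matrix(rnorm(n * p, sd = 0.5), n, p,
           dimnames = list(paste0(prefix, seq_len(n)), paste0("g", 1:p))) +
      rep(center, each = n)
  combined <- rbind(mk(centers[1, ], 30, "tA"), mk(centers[1, ], 10, "cA"),
                    mk(centers[2, ], 40, "tB"), mk(centers[2, ], 5, "cB"),
                    mk(centers[3, ], 12, "cX"))
  ann <- data.frame(
    sample_id = rownames(combined),
    lineage = rep(c("A", "A", "B", "B", "X"), c(30, 10, 40, 5, 12)),
    dataset = rep(c("tumor", "cell_line", "tumor", "cell_line", "cell_line"),
                  c(30, 10, 40, 5, 12)))
  scores <- pca_reduce(combined, 10)$scores
  ca <- cluster_graph(build_snn_graph(scores, 10), resolution = 1,
                      rng_seed = 1, dataset = "combined")
  comp <- cluster_composition(ca, ann)
  flagged <- comp$summary$cluster[comp$summary$flagged]
  expect_gt(length(flagged), 0)
  truth_ids <- paste0("cX", 1:12)
  jac <- vapply(flagged, function(k) {
    members <- ca$sample_ids[ca$labels == k]
    length(intersect(members, truth_ids)) / length(union(members, truth_ids))
  }, numeric(1))
  expect_gte(max(jac), 0.9)
})
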