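test_that("duplicate datasets give the identity matching and exact correction", {
  set.seed(14)
  m <- matrix(rnorm(60, mean = 5), 12, 5,
              dimnames = list(paste0("x", 1:12), paste0("g", 1:5)))
  cl <- m; rownames(cl) <- paste0("c", 1:12)
  tm <- m; rownames(tm) <- paste0("t", 1:12)
  pr <- find_mutual_nn(cl, tm, colnames(m), k_cl = 1, k_t = 1)
  expect_identical(nrow(pr$pairs), 12L)
  expect_identical(pr$pairs$cell_line_id, paste0("c", 1:12))
  expect_identical(pr$pairs$tumor_id, paste0("t", 1:12))
  expect_lt(max(pr$pairs$distance), 1e-6)
  fld <- compute_correction(pr, cl, tm, sigma_multiplier = 3)
  corrected <- apply_correction(tm, fld)
  expect_lt(max(abs(corrected - unname(cl))), 1e-8)
})

test_that("pair set equals the exhaustive double-loop oracle", {
  set.seed(15)
  cl <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("c", 1:8), c("g1", "g2")))
  tm <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("t", sprintf("%02d", 1:20)),
                                                 c("g1", "g2")))
  pr <- find_mutual_nn(cl, tm, c("g1", "g2"), k_cl = 2, k_t = 5)
  got <- pr$pairs[order(pr$pairs$cell_line_id, pr$pairs$tumor_id), ]
  want <- oracle_mnn(cl, tm, 2, 5)
  expect_identical(got$cell_line_id, want$cell_line_id)
  expect_identical(got$tumor_id, want$tumor_id)
  expect_equal(got$distance, want$distance, tolerance = 1e-12)
  expect_error(find_mutual_nn(cl, tm, character(0), 2, 5), "empty gene subset")
})

test_that("corrections are Gaussian-smoothed weighted averages of pair vectors", {
  set.seed(16)
  tm <- matrix(rnorm(5 * 4, mean = 3), 5, 4,
               dimnames = list(paste0("t", 1:5), paste0("g", 1:4)))
  cl <- matrix(rnorm(3 * 4, mean = 3), 3, 4,
               dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  pairing <- structure(list(
    pairs = data.frame(cell_line_id = c("c1", "c2", "c3"),
                       tumor_id = c("t1", "t3", "t4"), distance = 0),
    k_cell_line = 1L, k_tumor = 1L, gene_subset = colnames(tm)),
    class = "MNNPairing")
  fld <- compute_correction(pairing, cl, tm, sigma_multiplier = 2.5)
  want <- oracle_correction(pairing$pairs, cl, tm, colnames(tm), 2.5)
  expect_lt(max(abs(fld$vectors - want)), 1e-10)

  # identical pair vectors: every tumor receives exactly that vector
  d <- c(1, -2, 0.5, 3)
  cl2 <- rbind(c1 = tm["t1", ] + d, c2 = tm["t3", ] + d, c3 = tm["t4", ] + d)
  colnames(cl2) <- colnames(tm)
  fld2 <- compute_correction(pairing, cl2, tm, sigma_multiplier = 3)
  expect_equal(fld2$vectors, matrix(d, 5, 4, byrow = TRUE,
                                    dimnames = dimnames(fld2$vectors)),
               tolerance = 1e-12)

  # translation equivariance: shifting all tumors by u shifts corrections by -u
  u <- c(2, 0, -1, 4)
  fld3 <- compute_correction(pairing, cl, sweep(tm, 2, u, "+"),
                             sigma_multiplier = 2.5)
  expect_equal(fld3$vectors, fld$vectors - matrix(u, 5, 4, byrow = TRUE),
               tolerance = 1e-10)
})

test_that("apply_correction validates coverage and handles the zero field", {
  tm <- matrix(runif(12), 3, 4, dimnames = list(paste0("t", 1:3), paste0("g", 1:4)))
  zero <- structure(list(tumor_ids = rownames(tm),
                         vectors = matrix(0, 3, 4,
                                          dimnames = list(rownames(tm), NULL)),
                         sigma2 = 1), class = "CorrectionField")
  expect_identical(apply_correction(tm, zero), tm)
  expect_error(apply_correction(tm[, 1:3], zero), "mismatch")
  bad <- zero; bad$tumor_ids <- c("t1", "t2", "zz")
  expect_error(apply_correction(tm, bad), "cover")
})

test_that("mutuality is symmetric and the pair count is monotone in k_t", {
  set.seed(17)
  cl <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("c", 1:10), paste0("g", 1:3)))
  tm <- matrix(rnorm(90), 30, 3, dimnames = list(paste0("t", 1:30), paste0("g", 1:3)))
  a <- find_mutual_nn(cl, tm, paste0("g", 1:3), k_cl = 3, k_t = 6)
  # swap roles: the same pairs must emerge with the neighbor counts exchanged
  b <- find_mutual_nn(tm, cl, paste0("g", 1:3), k_cl = 6, k_t = 3)
  key_a <- sort(paste(a$pairs$cell_line_id, a$pairs$tumor_id))
  key_b <- sort(paste(b$pairs$tumor_id, b$pairs$cell_line_id))
  expect_identical(key_a, key_b)

  counts <- sapply(c(2, 5, 10, 20), function(k)
    nrow(find_mutual_nn(cl, tm, paste0("g", 1:3), k_cl = 3, k_t = k)$pairs))
  expect_true(all(diff(counts) >= 0))
})

test_that("correction moves matched-type tumors toward cell-line centroids", {
  run <- default_run()
  lab <- run$sim$truth$type_labels
  shared <- setdiff(unique(lab), unlist(run$sim$truth$exclusive_types))
  before <- run$sim$tumor$values
  after <- run$res$aligned$tumor
  cl_aligned <- run$res$aligned$cell_lines
  dist_to_cl <- function(tumors) {
    mean(sapply(shared, function(ty) {
      ct <- colMeans(cl_aligned[lab[rownames(cl_aligned)] == ty, , drop = FALSE])
      tt <- colMeans(tumors[lab[rownames(tumors)] == ty, , drop = FALSE])
      sqrt(sum((ct - tt)^2))
    }))
  }
  expect_lt(dist_to_cl(after), dist_to_cl(before))
})

test_that("tumor-only tumors keep tumor neighborhoods after correction", {
  run <- default_run()
  expect_gte(run$metrics$exclusive_tumor_min_frac, 0.9)
})
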