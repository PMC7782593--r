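# Independent brute-force oracles. These are deliberately naive, loop-based
# implementations of the stated formulas, kept free of any code shared with
# the package internals.

# one-way moderated F, straight from the definitions
oracle_moderated_f <- function(m, labels) {
  f <- factor(labels)
  k <- nlevels(f)
  n <- nrow(m)
  d <- n - k
  ms_between <- s2 <- numeric(ncol(m))
  for (g in seq_len(ncol(m))) {
    x <- m[, g]
    grand <- mean(x)
    msb <- 0
    rss <- 0
    for (lv in levels(f)) {
      xi <- x[f == lv]
      msb <- msb + length(xi) * (mean(xi) - grand)^2
      rss <- rss + sum((xi - mean(xi))^2)
    }
    ms_between[g] <- msb / (k - 1)
    s2[g] <- rss / d
  }
  # Smyth moment matching on log s^2
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- sum((e - mean(e))^2) / (length(e) - 1)
  target <- evar - trigamma(d / 2)
  if (target > 0) {
    # invert trigamma by bisection (independent of the package's Newton solve)
    lo <- 1e-8; hi <- 1e8
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > target) lo <- mid else hi <- mid
    }
    d0 <- 2 * sqrt(lo * hi)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_mod <- (d0 * s02 + d * s2) / (d0 + d)
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
    s2_mod <- rep(s02, length(s2))
  }
  list(f_stat = ifelse(ms_between == 0, 0, ms_between / s2_mod),
       d0 = d0, s02 = s02, s2 = s2, ms_between = ms_between)
}

# exhaustive double-loop mutual nearest neighbors
oracle_mnn <- function(cl, tm, k_cl, k_t) {
  pairs <- NULL
  d <- matrix(0, nrow(cl), nrow(tm))
  for (i in seq_len(nrow(cl)))
    for (j in seq_len(nrow(tm)))
      d[i, j] <- sqrt(sum((cl[i, ] - tm[j, ])^2))
  for (i in seq_len(nrow(cl))) {
    nn_t <- order(d[i, ])[seq_len(k_t)]
    for (j in nn_t) {
      nn_c <- order(d[, j])[seq_len(k_cl)]
      if (i %in% nn_c)
        pairs <- rbind(pairs, data.frame(cell_line_id = rownames(cl)[i],
                                         tumor_id = rownames(tm)[j],
                                         distance = d[i, j]))
    }
  }
  pairs[order(pairs$cell_line_id, pairs$tumor_id), ]
}

# direct weighted-average correction, one tumor at a time
oracle_correction <- function(pairs, cl, tm, subset, mult) {
  d_p <- t(vapply(seq_len(nrow(pairs)), function(p)
    cl[pairs$cell_line_id[p], ] - tm[pairs$tumor_id[p], ],
    numeric(ncol(tm))))
  d2 <- matrix(0, nrow(tm), nrow(pairs))
  for (t in seq_len(nrow(tm)))
    for (p in seq_len(nrow(pairs)))
      d2[t, p] <- sum((tm[t, subset] - tm[pairs$tumor_id[p], subset])^2)
  sigma2 <- mult * median(d2)
  out <- matrix(0, nrow(tm), ncol(tm), dimnames = dimnames(tm))
  for (t in seq_len(nrow(tm))) {
    w <- exp(-d2[t, ] / sigma2)
    out[t, ] <- colSums(d_p * (w / sum(w)))
  }
  out
}

# brute-force k-NN vote with the documented tie-breaks
oracle_vote <- function(r, types, k) {
  ord <- order(-r, names(r), method = "radix")[seq_len(k)]
  ty <- types[names(r)[ord]]
  votes <- table(ty)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- sapply(top, function(x) sum(r[ord][ty == x]))
    top <- top[sums == max(sums)]
    top <- sort(top)[1]
  }
  top
}
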