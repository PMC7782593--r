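#' Cell-line x tumor Pearson correlation matrix
#'
#' Correlates every cell line's gene vector with every tumor's gene vector
#' in the aligned space (all shared genes). Errors if any sample has zero
#' variance across genes, naming the sample.
#'
#' @param cell_lines,tumors Samples x genes matrices on the same gene space.
#' @return Matrix of Pearson correlations, cell lines in rows, tumors in
#'   columns, values in `[-1, 1]`.
#' @export
pairwise_correlation <- function(cell_lines, tumors) {
  stopifnot(is.matrix(cell_lines), is.matrix(tumors))
  if (ncol(cell_lines) != ncol(tumors)) stop("gene spaces differ")
  flat <- function(m, what) {
    v <- apply(m, 1L, stats::sd)
    if (any(v == 0))
      stop("zero-variance ", what, " sample: ",
           paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
  }
  flat(cell_lines, "cell line")
  flat(tumors, "tumor")
  stats::cor(t(cell_lines), t(tumors))
}

#' Classify cell lines by their most correlated tumor neighbors
#'
#' For each cell line, takes its `k` highest-correlated tumors and returns
#' the most frequent tumor type among them. Ties in the vote are broken by
#' the larger summed correlation over the tied types, then lexicographically
#' by type name, so the prediction is deterministic.
#'
#' @param correlations Cell-line x tumor correlation matrix from
#'   [pairwise_correlation()].
#' @param tumor_types Named character vector (or data.frame with
#'   `sample_id`, `lineage`) giving each tumor's annotated type.
#' @param k Number of tumor neighbors in the vote (default 25).
#' @return A data.frame with `cell_line_id`, `predicted_type`, and a
#'   `neighbor_ids` list-column of each cell line's `k` tumor neighbors in
#'   decreasing correlation order.
#' @export
classify_cell_lines <- function(correlations, tumor_types, k = 25L) {
  stopifnot(is.matrix(correlations))
  if (is.data.frame(tumor_types))
    tumor_types <- stats::setNames(tumor_types$lineage, tumor_types$sample_id)
  if (!all(colnames(correlations) %in% names(tumor_types)))
    stop("tumor_types must cover every tumor column")
  k <- as.integer(k)
  if (k < 1L || k > ncol(correlations)) stop("k must be in [1, n_tumors]")
  tids <- colnames(correlations)
  out <- lapply(seq_len(nrow(correlations)), function(i) {
    r <- correlations[i, ]
    ord <- order(-r, tids, method = "radix")[seq_len(k)]
    types <- tumor_types[tids[ord]]
    votes <- table(types)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(ty) sum(r[ord][types == ty]), numeric(1))
      top <- top[sums == max(sums)]
      top <- sort(top, method = "radix")[1L]
    }
    list(predicted = top, neighbors = tids[ord])
  })
  data.frame(
    cell_line_id = rownames(correlations),
    predicted_type = vapply(out, `[[`, character(1), "predicted"),
    neighbor_ids = I(lapply(out, `[[`, "neighbors")),
    stringsAsFactors = FALSE)
}

#' Agreement between predicted and annotated cell-line types
#'
#' The fraction of cell lines whose predicted tumor type equals their
#' annotation, evaluated only over cell lines whose annotated type occurs
#' among the tumor annotations (types exclusive to the cell-line panel
#' cannot be recovered by construction and are excluded from the
#' denominator).
#'
#' @param predicted,annotated Character vectors named by (or aligned on)
#'   cell line id.
#' @param tumor_type_universe Character vector of types present among the
#'   tumors.
#' @return List with `agreement` (fraction in `[0, 1]`) and `n_evaluated`.
#' @export
agreement_score <- function(predicted, annotated, tumor_type_universe) {
  if (!is.null(names(predicted)) && !is.null(names(annotated)))
    annotated <- annotated[names(predicted)]
  if (length(predicted) != length(annotated))
    stop("predictions and annotations must align")
  eval_mask <- annotated %in% tumor_type_universe
  n_eval <- sum(eval_mask)
  if (n_eval == 0L) stop("no cell line has an annotated type present among tumors")
  list(agreement = mean(predicted[eval_mask] == annotated[eval_mask]),
       n_evaluated = n_eval)
}

#' Full similarity report on the aligned data
#'
#' Convenience wrapper running [pairwise_correlation()],
#' [classify_cell_lines()] and [agreement_score()] in one step.
#'
#' @param cell_lines,tumors Aligned samples x genes matrices.
#' @param cl_annotation,tumor_annotation Annotation data.frames with
#'   `sample_id` and `lineage` columns (as from [read_sample_annotation()]).
#' @param k Tumor neighbors in the classification vote (default 25).
#' @return A list of class `SimilarityReport`: `correlations`,
#'   `predictions` (with annotated type and match flag), `agreement`,
#'   `n_evaluated`.
#' @export
similarity_report <- function(cell_lines, tumors, cl_annotation,
                              tumor_annotation, k = 25L) {
  corr <- pairwise_correlation(cell_lines, tumors)
  tumor_types <- stats::setNames(tumor_annotation$lineage,
                                 tumor_annotation$sample_id)
  pred <- classify_cell_lines(corr, tumor_types, k = k)
  ann <- stats::setNames(cl_annotation$lineage, cl_annotation$sample_id)
  pred$annotated_type <- unname(ann[pred$cell_line_id])
  universe <- unique(tumor_annotation$lineage)
  pred$match <- pred$predicted_type == pred$annotated_type &
    pred$annotated_type %in% universe
  sc <- agreement_score(stats::setNames(pred$predicted_type, pred$cell_line_id),
                        ann, universe)
  structure(list(correlations = corr, predictions = pred,
                 agreement = sc$agreement, n_evaluated = sc$n_evaluated),
            class = "SimilarityReport")
}

#' @export
print.SimilarityReport <- function(x, ...) {
  cat(sprintf("SimilarityReport: %d cell lines x %d tumors; agreement %.3f (n = %d)\n",
              nrow(x$correlations), ncol(x$correlations), x$agreement,
              x$n_evaluated))
  invisible(x)
}

#' Composition of joint clusters by dataset and lineage
#'
#' Summarizes a clustering of the combined aligned data: per cluster, the
#' number of cell lines and tumors, the cell-line fraction, and a flag for
#' clusters whose cell-line fraction exceeds a threshold (candidate
#' dataset-skewed clusters, e.g. an undifferentiated cell-line group that
#' matches no tumor type).
#'
#' @param combined_labels A `ClusterAssignment` over the combined data.
#' @param annotations Data.frame with `sample_id`, `lineage`, `dataset`
#'   covering the clustered samples (missing samples count as lineage
#'   `"unknown"`).
#' @param flag_threshold Cell-line fraction above which a cluster is
#'   flagged (default 0.5).
#' @return List with `summary` (one row per cluster) and `lineage_counts`
#'   (long data.frame cluster x dataset x lineage x n).
#' @export
cluster_composition <- function(combined_labels, annotations,
                                flag_threshold = 0.5) {
  stopifnot(inherits(combined_labels, "ClusterAssignment"))
  idx <- match(combined_labels$sample_ids, annotations$sample_id)
  lineage <- ifelse(is.na(idx), "unknown", annotations$lineage[idx])
  dataset <- ifelse(is.na(idx), "unknown", annotations$dataset[idx])
  df <- data.frame(cluster = combined_labels$labels, dataset = dataset,
                   lineage = lineage, stringsAsFactors = FALSE)
  long <- as.data.frame(table(cluster = df$cluster, dataset = df$dataset,
                              lineage = df$lineage), stringsAsFactors = FALSE)
  long <- long[long$Freq > 0, ]
  names(long)[names(long) == "Freq"] <- "n"
  long$cluster <- as.integer(long$cluster)
  cl_n <- table(factor(df$cluster)[df$dataset == "cell_line"])
  t_n <- table(factor(df$cluster)[df$dataset == "tumor"])
  clusters <- sort(unique(df$cluster))
  n_cl <- as.integer(cl_n[as.character(clusters)]); n_cl[is.na(n_cl)] <- 0L
  n_t <- as.integer(t_n[as.character(clusters)]); n_t[is.na(n_t)] <- 0L
  frac <- n_cl / (n_cl + n_t)
  summary <- data.frame(cluster = clusters, n_cell_lines = n_cl, n_tumors = n_t,
                        cell_line_fraction = frac,
                        flagged = frac > flag_threshold)
  list(summary = summary, lineage_counts = long)
}
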