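#' Inner-product association scores for index pairs
#'
#' The preference score of drug i and gene j is the inner product of their
#' final embeddings, \eqn{P_{ij} = \langle e_i^{(d)}, e_j^{(g)} \rangle}.
#'
#' @param final_drug,final_gene final embedding matrices.
#' @param pairs two-column integer matrix of (drug, gene) indices.
#' @return numeric score vector, one per pair.
#' @export
score_pairs <- function(final_drug, final_gene, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > nrow(final_drug)) ||
      any(pairs[, 2L] < 1L | pairs[, 2L] > nrow(final_gene))) {
    stop("pair index out of range")
  }
  rowSums(final_drug[pairs[, 1L], , drop = FALSE] *
            final_gene[pairs[, 2L], , drop = FALSE])
}

#' Link-prediction metrics: AUC, AUPR, recall, precision, F1
#'
#' AUC is computed exactly from the rank statistic (tied scores count one
#' half). AUPR uses step-wise integration of the precision-recall curve
#' (average precision). The binary confusion metrics binarize at the top-k
#' rule: the `n_pos` highest-scoring pairs are predicted positive (ties
#' broken by stable index order), which is deterministic and scale-free;
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2 * precision * recall / (precision + recall) (0 when the
#' denominator is 0).
#'
#' @param scores numeric score vector.
#' @param labels binary labels (0/1 or logical), same length.
#' @param threshold optional fixed score threshold; when supplied, pairs
#'   with `score >= threshold` are predicted positive instead of the top-k
#'   rule.
#' @return object of class `"metrics_report"`: list with `auc`, `aupr`,
#'   `recall`, `precision`, `f1`, `n_pos`, `n_neg`, `threshold_used`.
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L) stop("no positive labels")
  if (n_neg == 0L) stop("no negative labels")

  r <- rank(scores) # average ranks: ties count half
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(-scores, seq_along(scores)) # stable: ties by index
  lab_sorted <- labels[ord]
  tp_cum <- cumsum(lab_sorted)
  prec_at <- tp_cum / seq_along(lab_sorted)
  # average precision: sum of precision at each recall step
  aupr <- sum(prec_at[lab_sorted == 1L]) / n_pos

  if (is.null(threshold)) {
    pred <- integer(length(labels))
    pred[ord[seq_len(n_pos)]] <- 1L
    threshold_used <- scores[ord[n_pos]]
  } else {
    pred <- as.integer(scores >= threshold)
    threshold_used <- threshold
  }
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0

  structure(list(auc = auc, aupr = aupr, recall = recall,
                 precision = precision, f1 = f1,
                 n_pos = n_pos, n_neg = n_neg,
                 threshold_used = threshold_used),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.4f | AUPR %.4f | Recall %.4f | Precision %.4f | F1 %.4f  (%d pos, %d neg)\n",
              x$auc, x$aupr, x$recall, x$precision, x$f1, x$n_pos, x$n_neg))
  invisible(x)
}

#' k-fold cross-validation for link prediction
#'
#' Partitions the observed edges into `k` folds. For each fold the model is
#' trained on the remaining edges only — the SVD view and negative sampling
#' never see held-out edges — and evaluated on the held-out edges against an
#' equal number (times `neg_ratio`) of uniformly sampled non-edges.
#'
#' @param graph a `bg_graph`.
#' @param control a [gclink_control()].
#' @param k folds (default 5).
#' @param neg_ratio test negatives per test edge (default 1).
#' @param seed integer seed (folds, negatives, and each fold's training).
#' @return object of class `"gclink_cv"`: list with `folds` (list of
#'   `metrics_report`), `mean` (named numeric vector of metric means),
#'   and `table` (data.frame, one row per fold plus the mean row).
#' @export
cross_validate <- function(graph, control = gclink_control(), k = 5,
                           neg_ratio = 1, seed = 1) {
  folds <- cv_folds(graph, k = k, neg_ratio = neg_ratio, seed = seed)
  reports <- lapply(folds, function(fold) {
    tg <- subgraph_from_edges(graph, fold$train)
    fit <- gclink(tg, control, seed = seed + fold$fold)
    pairs <- rbind(fold$test, fold$neg)
    labels <- rep(c(1L, 0L), c(nrow(fold$test), nrow(fold$neg)))
    sc <- score_pairs(fit$final_drug, fit$final_gene, pairs)
    compute_metrics(sc, labels)
  })
  metric_names <- c("auc", "aupr", "recall", "precision", "f1")
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(fold = i, t(unlist(reports[[i]][metric_names])))
  }))
  means <- colMeans(tab[metric_names])
  tab <- rbind(tab, data.frame(fold = NA, t(means)))
  structure(list(folds = reports, mean = means, table = tab),
            class = "gclink_cv")
}

#' @exportS3Method base::print
print.gclink_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", length(x$folds)))
  tab <- x$table
  tab$fold <- ifelse(is.na(tab$fold), "Avg.", as.character(tab$fold))
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Rank candidate partners for a query drug or gene
#'
#' Scores every counterpart node, optionally excludes the query's known
#' associations, and returns the `top_k` best in strictly descending score
#' order (ties broken by stable index order). This is the case-study
#' procedure: candidate genes for a drug (or drugs for a gene) that are not
#' yet recorded in the input data.
#'
#' @param fit a fitted `gclink` model.
#' @param query a drug or gene identifier present in the model vocabulary.
#' @param top_k rows to return (default 15).
#' @param exclude_known drop counterparts already associated with the query
#'   in the training data (default TRUE).
#' @return data.frame with columns `rank`, `id`, `score`.
#' @export
rank_candidates <- function(fit, query, top_k = 15, exclude_known = TRUE) {
  stopifnot(inherits(fit, "gclink"))
  di <- match(query, fit$drug_ids)
  gi <- match(query, fit$gene_ids)
  if (is.na(di) && is.na(gi)) {
    near <- utils::head(c(fit$drug_ids, fit$gene_ids)[
      order(utils::adist(query, c(fit$drug_ids, fit$gene_ids)))], 3L)
    stop("unknown identifier '", query, "'; nearest known ids: ",
         paste(near, collapse = ", "))
  }
  if (!is.na(di)) {
    scores <- as.numeric(fit$final_gene %*% fit$final_drug[di, ])
    ids <- fit$gene_ids
    known <- fit$edges[fit$edges[, 1L] == di, 2L]
  } else {
    scores <- as.numeric(fit$final_drug %*% fit$final_gene[gi, ])
    ids <- fit$drug_ids
    known <- fit$edges[fit$edges[, 2L] == gi, 1L]
  }
  keep <- seq_along(scores)
  if (exclude_known) keep <- setdiff(keep, known)
  ord <- keep[order(-scores[keep], keep)]
  sel <- utils::head(ord, top_k)
  data.frame(rank = seq_along(sel), id = ids[sel], score = scores[sel])
}

#' Export final embeddings as a 2-D scatter (plumbing helper)
#'
#' Projects the final drug and gene embeddings onto their first two
#' principal components and returns (and optionally plots) the coordinates.
#' No clustering quality is asserted; this is a convenience for visual
#' inspection.
#'
#' @param fit a `gclink`.
#' @param plot draw a base-graphics scatter (default FALSE).
#' @return data.frame with `id`, `type` ("drug"/"gene"), `x`, `y`.
#' @export
embedding_scatter <- function(fit, plot = FALSE) {
  X <- rbind(fit$final_drug, fit$final_gene)
  pc <- stats::prcomp(X, rank. = 2)
  df <- data.frame(id = c(fit$drug_ids, fit$gene_ids),
                   type = rep(c("drug", "gene"),
                              c(nrow(fit$final_drug), nrow(fit$final_gene))),
                   x = pc$x[, 1L], y = pc$x[, 2L])
  if (plot) {
    graphics::plot(df$x, df$y, col = ifelse(df$type == "drug", 2L, 4L),
                   pch = 20, xlab = "PC1", ylab = "PC2",
                   main = "Final embeddings")
  }
  invisible(df)
}
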