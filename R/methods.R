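#' @exportS3Method base::print
print.gclink <- function(x, ...) {
  ctl <- x$control
  cat("Graph-contrastive link-prediction model\n")
  cat(sprintf("  variant %s | %d drugs x %d genes | %d training edges\n",
              ctl$variant, length(x$drug_ids), length(x$gene_ids),
              nrow(x$edges)))
  cat(sprintf("  d = %d, layers = %d, svd rank = %d, epochs trained = %d\n",
              ctl$d, ctl$n_layers, ctl$svd_rank, nrow(x$log)))
  if (nrow(x$log) > 0) {
    cat(sprintf("  final loss: total %.4g (ranking %.4g, contrastive %.4g)\n",
                x$log$total[nrow(x$log)], x$log$L_r[nrow(x$log)],
                x$log$L_s_drug[nrow(x$log)] + x$log$L_s_gene[nrow(x$log)]))
  }
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object a `gclink`.
#' @param ... ignored.
#' @return list with the configuration, graph dimensions, loss trajectory
#'   endpoints, and embedding norms.
#' @exportS3Method base::summary
summary.gclink <- function(object, ...) {
  out <- list(
    variant = object$control$variant,
    m = length(object$drug_ids), n = length(object$gene_ids),
    n_edges = nrow(object$edges),
    d = object$control$d, n_layers = object$control$n_layers,
    epochs = nrow(object$log),
    first_loss = if (nrow(object$log)) object$log$total[1L] else NA_real_,
    final_loss = if (nrow(object$log)) object$log$total[nrow(object$log)]
      else NA_real_,
    mean_drug_norm = mean(sqrt(rowSums(object$E_drug^2))),
    mean_gene_norm = mean(sqrt(rowSums(object$E_gene^2)))
  )
  class(out) <- "summary.gclink"
  out
}

#' @exportS3Method base::print
print.summary.gclink <- function(x, ...) {
  cat(sprintf("gclink '%s' fit: %d x %d graph, %d edges, d = %d, L = %d\n",
              x$variant, x$m, x$n, x$n_edges, x$d, x$n_layers))
  cat(sprintf("  loss %.4g -> %.4g over %d epochs\n",
              x$first_loss, x$final_loss, x$epochs))
  cat(sprintf("  mean embedding norm: drugs %.3f, genes %.3f\n",
              x$mean_drug_norm, x$mean_gene_norm))
  invisible(x)
}

#' Extract model parameters
#'
#' The model's only learnable parameters are the base embedding tables.
#'
#' @param object a `gclink`.
#' @param ... ignored.
#' @return list with `E_drug` and `E_gene`.
#' @export
coef.gclink <- function(object, ...) {
  list(E_drug = object$E_drug, E_gene = object$E_gene)
}

#' Predict association scores
#'
#' Scores drug-gene pairs with the inner product of their final embeddings.
#' Supply either `pairs` (a two-column matrix/data.frame of identifiers or
#' indices) or both `drug` and `gene` vectors (recycled pairwise).
#'
#' @param object a fitted `gclink`.
#' @param pairs two-column matrix or data.frame of (drug, gene) identifiers
#'   (character) or 1-based indices (numeric).
#' @param drug,gene alternative to `pairs`: parallel identifier vectors.
#' @param ... ignored.
#' @return numeric score vector.
#' @export
predict.gclink <- function(object, pairs = NULL, drug = NULL, gene = NULL,
                           ...) {
  if (is.null(pairs)) {
    if (is.null(drug) || is.null(gene)) {
      stop("supply 'pairs' or both 'drug' and 'gene'")
    }
    pairs <- cbind(drug, gene)
  }
  pairs <- as.matrix(pairs)
  if (is.character(pairs)) {
    di <- match(pairs[, 1L], object$drug_ids)
    gi <- match(pairs[, 2L], object$gene_ids)
    if (anyNA(di)) stop("unknown drug id: ", pairs[which(is.na(di))[1L], 1L])
    if (anyNA(gi)) stop("unknown gene id: ", pairs[which(is.na(gi))[1L], 2L])
    pairs <- cbind(di, gi)
  }
  score_pairs(object$final_drug, object$final_gene, pairs)
}

#' Plot the training loss trajectory
#'
#' Draws the total loss and its components (ranking, contrastive, L2) per
#' epoch on a log scale.
#'
#' @param x a `gclink`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gclink <- function(x, ...) {
  if (nrow(x$log) == 0L) stop("model was trained for 0 epochs; nothing to plot")
  comp <- cbind(total = x$log$total, ranking = x$log$L_r,
                contrastive = x$log$L_s_drug + x$log$L_s_gene,
                L2 = x$log$L2)
  graphics::matplot(x$log$epoch, comp, type = "l", lty = 1, lwd = 2,
                    col = c(1, 2, 4, 8), xlab = "epoch", ylab = "loss",
                    main = "Training loss", ...)
  graphics::legend("topright", colnames(comp), col = c(1, 2, 4, 8),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
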