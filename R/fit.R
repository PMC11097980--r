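#' Training configuration for [gclink()]
#'
#' Collects every hyperparameter of the model and optimizer. Defaults follow
#' the reference setting: 256-dimensional embeddings, a 2-layer GCN, rank-5
#' SVD view, temperature 0.2, contrastive weight 0.1, L2 weight 1e-5, edge
#' dropout 0.25, node keep-probability 0.5 for the contrastive term, one
#' sampled negative per positive, 300 epochs of Adam at learning rate 1e-3.
#'
#' @param d embedding width.
#' @param n_layers GCN layers (the same depth is used on both views).
#' @param svd_rank retained rank t of the SVD view.
#' @param tau InfoNCE temperature.
#' @param lambda1 contrastive loss weight.
#' @param lambda2 L2 regularization weight.
#' @param edge_dropout edge dropout rate on the main view (training only).
#' @param cl_keep_prob probability that a batch node stays active in the
#'   contrastive loss ("node inactivation" regularization).
#' @param neg_per_pos sampled negatives per positive pair in the hinge loss.
#' @param epochs training epochs.
#' @param batch_size positive pairs per gradient step.
#' @param learning_rate Adam step size.
#' @param variant model variant: `"svd"` (full model), `"none"` (plain GCN,
#'   no contrastive term), `"edge_drop"`, `"node_drop"`, `"random_walk"`
#'   (perturbation-based augmented views), or `"mf"` (matrix factorization:
#'   no propagation, base embeddings only).
#' @param activation `"leaky_relu"` (default) or `"identity"`.
#' @param node_drop_frac fraction of node rows zeroed by the `"node_drop"`
#'   augmentation.
#' @param svd_oversample,svd_power_iters randomized-SVD accuracy knobs.
#' @return a `gclink_control` list.
#' @export
gclink_control <- function(d = 256, n_layers = 2, svd_rank = 5,
                           tau = 0.2, lambda1 = 0.1, lambda2 = 1e-5,
                           edge_dropout = 0.25, cl_keep_prob = 0.5,
                           neg_per_pos = 1, epochs = 300, batch_size = 1024,
                           learning_rate = 1e-3, variant = "svd",
                           activation = "leaky_relu", node_drop_frac = 0.1,
                           svd_oversample = 10, svd_power_iters = 4) {
  variant <- match.arg(variant, c("svd", "none", "edge_drop", "node_drop",
                                  "random_walk", "mf"))
  stopifnot(d >= 1, n_layers >= 1, svd_rank >= 1, tau > 0, lambda1 >= 0,
            lambda2 >= 0, edge_dropout >= 0, edge_dropout < 1,
            cl_keep_prob > 0, cl_keep_prob <= 1, neg_per_pos >= 1,
            epochs >= 0, batch_size >= 1, learning_rate > 0,
            node_drop_frac >= 0, node_drop_frac < 1)
  structure(as.list(environment()), class = "gclink_control")
}

## Build the per-layer operator list for the augmented view of a variant.
## Draws from the current RNG stream (fresh masks per batch, and per layer
## for the random-walk variant). The SVD view is precomputed once per fit.
variant_ops <- function(variant, A_norm, svd_view, control) {
  L <- control$n_layers
  switch(variant,
    svd = rep(list(op_factored(svd_view)), L),
    edge_drop = rep(list(op_sparse(drop_edges(A_norm, control$edge_dropout))), L),
    node_drop = {
      m <- nrow(A_norm); n <- ncol(A_norm)
      kd <- stats::runif(m) >= control$node_drop_frac
      kg <- stats::runif(n) >= control$node_drop_frac
      M <- Matrix::Diagonal(x = as.numeric(kd)) %*% A_norm %*%
        Matrix::Diagonal(x = as.numeric(kg))
      rep(list(op_sparse(M)), L)
    },
    random_walk = lapply(seq_len(L), function(l) {
      op_sparse(drop_edges(A_norm, control$edge_dropout))
    }),
    stop("variant '", variant, "' has no augmented view")
  )
}

## Minimal Adam optimizer state and update.
adam_init <- function(shape) {
  list(m = matrix(0, shape[1L], shape[2L]),
       v = matrix(0, shape[1L], shape[2L]), t = 0L)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Fit a graph-contrastive link-prediction model
#'
#' Trains learnable drug and gene embeddings on a bipartite association
#' graph. Each mini-batch of observed edges is scored through a multi-layer
#' GCN over the (edge-dropped) normalized adjacency; the full model also
#' encodes a second, globally smoothed view — the truncated-SVD
#' reconstruction of the same adjacency — and aligns the two views with a
#' per-layer InfoNCE contrastive loss. Observed pairs are fit with a
#' pairwise hinge ranking loss against uniformly sampled unobserved pairs,
#' plus L2 regularization on the embeddings; the sum is optimized with Adam.
#' All parameters live in the base embedding tables — the propagation layers
#' are weight-free.
#'
#' The SVD view is computed once, from the training graph only, before the
#' loop; perturbation-based ablation views redraw their masks every batch.
#'
#' @param graph a `bg_graph` of training associations.
#' @param control a [gclink_control()] configuration.
#' @param seed integer seed governing initialization, dropout, sampling.
#' @return an object of class `"gclink"`: embeddings (`E_drug`, `E_gene`),
#'   final propagated embeddings (`final_drug`, `final_gene`, evaluation
#'   mode), the `svd_view` (full model), the per-epoch loss `log`
#'   (data.frame with columns epoch, L_r, L_s_drug, L_s_gene, L2, total),
#'   `control`, `seed`, and the graph vocabularies.
#' @seealso [predict.gclink()], [rank_candidates()], [cross_validate()]
#' @export
gclink <- function(graph, control = gclink_control(), seed = 1) {
  stopifnot(inherits(graph, "bg_graph"))
  if (nrow(graph$edges) == 0L) stop("graph has no edges")
  m <- length(graph$drug_ids)
  n <- length(graph$gene_ids)
  ctl <- control
  use_aug <- ctl$variant %in% c("svd", "edge_drop", "node_drop", "random_walk") &&
    ctl$lambda1 > 0
  is_mf <- ctl$variant == "mf"

  svd_view <- NULL
  if (ctl$variant == "svd") {
    svd_view <- randomized_svd(graph$A_norm, t = min(ctl$svd_rank, m, n),
                               oversample = ctl$svd_oversample,
                               power_iters = ctl$svd_power_iters,
                               seed = seed + 1L)
  }

  emb <- init_embeddings(m, n, ctl$d, seed = seed)
  E_d <- emb$E_drug; E_g <- emb$E_gene
  st_d <- adam_init(dim(E_d)); st_g <- adam_init(dim(E_g))
  edges <- graph$edges
  ne <- nrow(edges)
  log_rows <- vector("list", ctl$epochs)

  with_seed(seed + 2L, for (ep in seq_len(ctl$epochs)) {
    ord <- sample.int(ne)
    comp <- c(L_r = 0, L_s_drug = 0, L_s_gene = 0, L2 = 0)
    total <- 0
    for (start in seq(1L, ne, by = ctl$batch_size)) {
      idx <- ord[start:min(start + ctl$batch_size - 1L, ne)]
      anchors <- edges[idx, 1L]
      pos <- edges[idx, 2L]
      neg <- sample_negatives(graph, anchors, ctl$neg_per_pos)
      ops_main <- if (is_mf) list() else lapply(seq_len(ctl$n_layers),
        function(l) op_sparse(drop_edges(graph$A_norm, ctl$edge_dropout)))
      ops_aug <- NULL
      act_d <- integer(0); act_g <- integer(0)
      if (use_aug) {
        ops_aug <- variant_ops(ctl$variant, graph$A_norm, svd_view, ctl)
        bd <- unique(anchors)
        bg <- unique(c(pos, as.vector(neg)))
        act_d <- bd[stats::runif(length(bd)) < ctl$cl_keep_prob]
        act_g <- bg[stats::runif(length(bg)) < ctl$cl_keep_prob]
      }
      lg <- loss_and_grad(ops_main, ops_aug, E_d, E_g,
                          list(anchors = anchors, pos = pos, neg = neg),
                          act_d, act_g, tau = ctl$tau,
                          lambda1 = if (use_aug) ctl$lambda1 else 0,
                          lambda2 = ctl$lambda2,
                          activation = ctl$activation)
      if (!is.finite(lg$loss)) {
        bad <- names(lg$components)[!is.finite(lg$components)]
        stop("non-finite loss at epoch ", ep,
             if (length(bad)) paste0(" (component ", bad[1L], ")"))
      }
      st_d <- adam_step(st_d, lg$gE_drug, ctl$learning_rate)
      st_g <- adam_step(st_g, lg$gE_gene, ctl$learning_rate)
      E_d <- E_d + st_d$delta
      E_g <- E_g + st_g$delta
      comp <- comp + lg$components
      total <- total + lg$loss
    }
    log_rows[[ep]] <- data.frame(epoch = ep, L_r = comp[["L_r"]],
                                 L_s_drug = comp[["L_s_drug"]],
                                 L_s_gene = comp[["L_s_gene"]],
                                 L2 = comp[["L2"]], total = total)
  })

  fit <- structure(
    list(E_drug = E_d, E_gene = E_g, svd_view = svd_view,
         control = ctl, seed = seed,
         drug_ids = graph$drug_ids, gene_ids = graph$gene_ids,
         edges = graph$edges,
         log = if (ctl$epochs > 0) do.call(rbind, log_rows) else
           data.frame(epoch = integer(), L_r = numeric(),
                      L_s_drug = numeric(), L_s_gene = numeric(),
                      L2 = numeric(), total = numeric())),
    class = "gclink")
  fin <- final_embeddings(fit, graph)
  fit$final_drug <- fin$final_drug
  fit$final_gene <- fin$final_gene
  fit
}

## Evaluation-mode final embeddings (no dropout): base embeddings for the
## MF variant, layer-summed GCN outputs otherwise.
final_embeddings <- function(fit, graph) {
  ctl <- fit$control
  if (ctl$variant == "mf") {
    return(list(final_drug = fit$E_drug, final_gene = fit$E_gene))
  }
  fwd <- encode(graph, list(E_drug = fit$E_drug, E_gene = fit$E_gene),
                n_layers = ctl$n_layers, edge_dropout = 0,
                activation = ctl$activation, training = FALSE)
  list(final_drug = fwd$final_drug, final_gene = fwd$final_gene)
}

#' Save / load a fitted model checkpoint
#'
#' Writes the fitted embeddings, SVD factors, configuration, and loss log
#' with a versioned header; loading verifies the version and basic shape
#' consistency and reproduces identical scores.
#'
#' @param fit a `gclink` object.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `gclink` object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gclink"))
  saveRDS(list(format = "gclink-checkpoint", version = 1L, fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param d_expected optional embedding width the caller requires; a
#'   mismatch is an error naming both widths.
#' @export
load_checkpoint <- function(path, d_expected = NULL) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable checkpoint '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "gclink-checkpoint")) {
    stop("'", path, "' is not a gclink checkpoint")
  }
  if (!identical(obj$version, 1L)) {
    stop("checkpoint version ", obj$version, " not supported (expected 1)")
  }
  fit <- obj$fit
  if (!is.null(d_expected) && ncol(fit$E_drug) != d_expected) {
    stop("checkpoint embedding width ", ncol(fit$E_drug),
         " does not match expected d = ", d_expected)
  }
  fit
}
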