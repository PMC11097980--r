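## Propagation operators -----------------------------------------------------
##
## A "view" of the bipartite graph is, per GCN layer, a linear operator Op
## (m x n) applied as  z_drug = sigma(Op %*% prev_gene),
##                     z_gene = sigma(t(Op) %*% prev_drug).
## Two representations:
##   * sparse:   Op is a (possibly edge-dropped) normalized adjacency;
##   * factored: Op = U diag(d) t(V), the truncated-SVD reconstruction,
##     applied without ever materializing the m x n product.
## The factored gene-side application is exactly the transpose operator, so
## backpropagation through either representation reuses the forward kernels.

op_sparse <- function(M) list(kind = "sparse", M = M)
op_factored <- function(view) list(kind = "factored", u = view$u,
                                   d = view$d, v = view$v)

op_apply_drug <- function(op, X_gene) {
  if (op$kind == "sparse") as.matrix(op$M %*% X_gene)
  else op$u %*% (op$d * crossprod(op$v, X_gene))
}

op_apply_gene <- function(op, X_drug) {
  if (op$kind == "sparse") as.matrix(Matrix::crossprod(op$M, X_drug))
  else op$v %*% (op$d * crossprod(op$u, X_drug))
}

## Edge dropout: zero each nonzero of a sparse operator independently with
## probability `rate`, rescaling survivors by 1/(1 - rate) so the operator is
## unbiased in expectation. Draws from the current RNG stream.
drop_edges <- function(M, rate) {
  if (rate <= 0) return(M)
  M <- methods::as(M, "CsparseMatrix")
  keep <- stats::runif(length(M@x)) >= rate
  M@x <- ifelse(keep, M@x / (1 - rate), 0)
  M
}

## Activations ---------------------------------------------------------------

act_fun <- function(name) {
  switch(name,
    leaky_relu = list(
      f = function(x) ifelse(x > 0, x, 0.5 * x),
      grad = function(x) ifelse(x > 0, 1, 0.5)
    ),
    identity = list(
      f = function(x) x,
      grad = function(x) array(1, dim = dim(x))
    ),
    stop("unknown activation '", name, "'")
  )
}

#' Initialize learnable base embeddings
#'
#' Drug and gene embedding tables are the model's only parameters (the GCN
#' layers have no weight matrices). Entries are drawn Xavier-uniform,
#' `U(-a, a)` with `a = sqrt(6 / (rows + d))`, deterministically under
#' `seed`.
#'
#' @param m,n drug / gene counts.
#' @param d embedding width.
#' @param seed integer seed.
#' @return list with matrices `E_drug` (m x d) and `E_gene` (n x d).
#' @export
init_embeddings <- function(m, n, d, seed = 1) {
  stopifnot(d >= 1)
  with_seed(seed, {
    ad <- sqrt(6 / (m + d))
    ag <- sqrt(6 / (n + d))
    list(E_drug = matrix(stats::runif(m * d, -ad, ad), m, d),
         E_gene = matrix(stats::runif(n * d, -ag, ag), n, d))
  })
}

#' One GCN propagation step over the bipartite graph
#'
#' Computes `z_drug = sigma(p(A_norm) %*% prev_gene)` and
#' `z_gene = sigma(t(p(A_norm)) %*% prev_drug)`, where `p()` applies edge
#' dropout (zeroing each edge independently and rescaling survivors) in
#' training mode and is the identity in evaluation mode.
#'
#' @param A_norm normalized adjacency (m x n, sparse or dense).
#' @param prev_drug,prev_gene previous-layer embeddings (m x d, n x d).
#' @param edge_dropout dropout rate in \[0, 1).
#' @param activation `"leaky_relu"` (slope 0.5, default) or `"identity"`.
#' @param training logical; dropout is only applied when `TRUE`.
#' @return list with `z_drug`, `z_gene`.
#' @export
propagate_layer <- function(A_norm, prev_drug, prev_gene, edge_dropout = 0,
                            activation = "leaky_relu", training = FALSE) {
  stopifnot(edge_dropout >= 0, edge_dropout < 1)
  if (nrow(prev_gene) != ncol(A_norm) || nrow(prev_drug) != nrow(A_norm) ||
      ncol(prev_drug) != ncol(prev_gene)) {
    stop("shape mismatch between adjacency and embeddings")
  }
  M <- Matrix::Matrix(A_norm, sparse = TRUE)
  if (training && edge_dropout > 0) M <- drop_edges(M, edge_dropout)
  act <- act_fun(activation)
  op <- op_sparse(M)
  list(z_drug = act$f(op_apply_drug(op, prev_gene)),
       z_gene = act$f(op_apply_gene(op, prev_drug)))
}

#' Sum per-layer embeddings into final embeddings
#'
#' The final representation of each node is the elementwise sum of its
#' embeddings across all layers (layer 0 = the learnable base embedding).
#'
#' @param layers non-empty list of same-shaped matrices.
#' @return matrix of the same shape.
#' @export
aggregate_layers <- function(layers) {
  if (length(layers) == 0L) stop("empty layer list")
  Reduce(`+`, layers)
}

## Full forward pass over one view.
##
## ops: list of length L of propagation operators (one per layer; the same
## operator repeated is fine). Returns per-layer embeddings Zd/Zg (length
## L + 1, index 1 = base), pre-activations Pd/Pg (length L), and the
## layer-summed finals.
forward_view <- function(ops, E_drug, E_gene, activation = "leaky_relu") {
  act <- act_fun(activation)
  L <- length(ops)
  Zd <- vector("list", L + 1L); Zg <- vector("list", L + 1L)
  Pd <- vector("list", L); Pg <- vector("list", L)
  Zd[[1L]] <- E_drug; Zg[[1L]] <- E_gene
  for (l in seq_len(L)) {
    Pd[[l]] <- op_apply_drug(ops[[l]], Zg[[l]])
    Pg[[l]] <- op_apply_gene(ops[[l]], Zd[[l]])
    Zd[[l + 1L]] <- act$f(Pd[[l]])
    Zg[[l + 1L]] <- act$f(Pg[[l]])
  }
  list(Zd = Zd, Zg = Zg, Pd = Pd, Pg = Pg,
       final_drug = aggregate_layers(Zd),
       final_gene = aggregate_layers(Zg))
}

## Reverse-mode pass through forward_view.
##
## g_final_*: gradient of the loss w.r.t. the layer-summed final embeddings
##   (zero matrices if the view does not feed the score head).
## g_layers_*: optional lists (length L + 1) of per-layer gradients, e.g.
##   from a contrastive loss acting on every layer; NULL entries allowed.
## Returns gradients w.r.t. the base embedding matrices.
backward_view <- function(fwd, ops, g_final_drug, g_final_gene,
                          g_layers_drug = NULL, g_layers_gene = NULL,
                          activation = "leaky_relu") {
  act <- act_fun(activation)
  L <- length(ops)
  layer_grad <- function(lst, l, template) {
    if (is.null(lst) || is.null(lst[[l]])) 0 else lst[[l]]
  }
  acc_d <- g_final_drug + layer_grad(g_layers_drug, L + 1L)
  acc_g <- g_final_gene + layer_grad(g_layers_gene, L + 1L)
  for (l in rev(seq_len(L))) {
    gPd <- acc_d * act$grad(fwd$Pd[[l]])
    gPg <- acc_g * act$grad(fwd$Pg[[l]])
    # Zd[[l]] feeds: the final sum, its own per-layer loss, and Pg[[l]]
    acc_d <- g_final_drug + layer_grad(g_layers_drug, l) +
      op_apply_drug(ops[[l]], gPg)
    acc_g <- g_final_gene + layer_grad(g_layers_gene, l) +
      op_apply_gene(ops[[l]], gPd)
  }
  list(gE_drug = acc_d, gE_gene = acc_g)
}

#' Encode a graph: multi-layer GCN with layer-sum aggregation
#'
#' Runs `n_layers` propagation steps over the normalized adjacency, feeding
#' each layer the previous layer's outputs (layer 0 is the base embedding),
#' and sums all layers into the final drug and gene embeddings.
#'
#' @param graph a `bg_graph`.
#' @param embeddings list with `E_drug`, `E_gene` (see [init_embeddings()]).
#' @param n_layers number of GCN layers, `>= 1`.
#' @param edge_dropout edge dropout rate (training mode only).
#' @param activation activation name.
#' @param training logical; enables dropout (a fresh mask per layer).
#' @return list with per-layer embeddings `Zd`, `Zg` and the layer-summed
#'   `final_drug`, `final_gene`.
#' @export
encode <- function(graph, embeddings, n_layers = 2, edge_dropout = 0,
                   activation = "leaky_relu", training = FALSE) {
  stopifnot(n_layers >= 1)
  ops <- lapply(seq_len(n_layers), function(l) {
    M <- graph$A_norm
    if (training && edge_dropout > 0) M <- drop_edges(M, edge_dropout)
    op_sparse(M)
  })
  forward_view(ops, embeddings$E_drug, embeddings$E_gene, activation)
}

#' Encode over the SVD-reconstructed view
#'
#' Propagates the same base embeddings over the low-rank reconstruction
#' `U diag(d) t(V)` of the normalized adjacency, in factored form (the
#' dense reconstruction is never materialized). No dropout is applied on
#' this view: the low-rank smoothing is itself the augmentation.
#'
#' @param view an `svd_view` from [randomized_svd()].
#' @param embeddings list with `E_drug`, `E_gene`.
#' @param n_layers number of layers (matching the main view).
#' @param activation activation name.
#' @return same structure as [encode()].
#' @export
encode_augmented <- function(view, embeddings, n_layers = 2,
                             activation = "leaky_relu") {
  stopifnot(n_layers >= 1)
  ops <- rep(list(op_factored(view)), n_layers)
  forward_view(ops, embeddings$E_drug, embeddings$E_gene, activation)
}
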