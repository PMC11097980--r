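#' Sample negative genes for anchor drugs
#'
#' For each anchor drug, draws `S` genes uniformly from the genes it is NOT
#' associated with in the training graph (rejection sampling against the
#' edge set). Used by the pairwise hinge loss.
#'
#' @param graph training `bg_graph`.
#' @param anchors integer vector of drug indices (may repeat).
#' @param S negatives per anchor.
#' @return integer matrix, `length(anchors)` x `S`.
#' @export
sample_negatives <- function(graph, anchors, S = 1) {
  m <- length(graph$drug_ids)
  n <- length(graph$gene_ids)
  deg <- Matrix::rowSums(graph$A)
  if (any(deg[anchors] >= n)) {
    stop("an anchor drug is associated with every gene; cannot sample negatives")
  }
  edge_code <- .pair_code(graph$edges[, 1L], graph$edges[, 2L], m)
  out <- matrix(NA_integer_, length(anchors), S)
  pending <- which(is.na(out), arr.ind = TRUE)
  while (nrow(pending)) {
    cand <- sample.int(n, nrow(pending), replace = TRUE)
    code <- .pair_code(anchors[pending[, 1L]], cand, m)
    ok <- !(code %in% edge_code)
    out[pending[ok, , drop = FALSE]] <- cand[ok]
    pending <- pending[!ok, , drop = FALSE]
  }
  out
}

## Cosine-similarity matrix with the zero-norm convention: any row of Z or H
## with zero norm has cosine 0 against everything (and zero gradient).
.row_normalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  inv <- ifelse(nrm > 0, 1 / nrm, 0)
  list(Xn = X * inv, inv = inv)
}

#' Cross-view InfoNCE contrastive loss (one side, one or more layers)
#'
#' For each active node i and layer l, pulls together the main-view
#' embedding `z_{i,l}` and the augmented-view embedding `h_{i,l}` while
#' pushing apart the pairs (i, i') for other active nodes i', via a
#' temperature-scaled softmax over cosine similarities:
#' \deqn{L = \sum_i \sum_l -\log \frac{\exp(\cos(z_{i,l}, h_{i,l})/\tau)}
#'   {\sum_{i'} \exp(\cos(z_{i,l}, h_{i',l})/\tau)}}
#' Inactive nodes contribute nothing and never appear as negatives. The
#' softmax is stabilized by subtracting each row's maximum.
#'
#' @param main_layers,aug_layers lists of per-layer embedding matrices for
#'   the two views (same length and shapes; typically layers 0..L).
#' @param active logical or integer vector selecting the active rows.
#' @param tau temperature (> 0).
#' @param grad if `TRUE`, also return per-layer gradients w.r.t. both views
#'   (full-size matrices, zero on inactive rows).
#' @return the scalar loss, or (with `grad`) a list
#'   `list(loss, g_main, g_aug)`.
#' @export
info_nce <- function(main_layers, aug_layers, active, tau = 0.2,
                     grad = FALSE) {
  stopifnot(tau > 0, length(main_layers) == length(aug_layers))
  nr <- nrow(main_layers[[1L]])
  idx <- if (is.logical(active)) which(active) else as.integer(active)
  loss <- 0
  g_main <- if (grad) lapply(main_layers, function(M) M * 0) else NULL
  g_aug <- if (grad) lapply(aug_layers, function(M) M * 0) else NULL
  if (length(idx) == 0L) {
    return(if (grad) list(loss = 0, g_main = g_main, g_aug = g_aug) else 0)
  }
  for (l in seq_along(main_layers)) {
    Z <- main_layers[[l]][idx, , drop = FALSE]
    H <- aug_layers[[l]][idx, , drop = FALSE]
    zn <- .row_normalize(Z); hn <- .row_normalize(H)
    C <- tcrossprod(zn$Xn, hn$Xn) # cosine: C[i, i'] = cos(z_i, h_i')
    S <- C / tau
    rowmax <- apply(S, 1L, max)
    E <- exp(S - rowmax)
    denom <- rowSums(E)
    loss <- loss + sum(-(diag(S) - rowmax) + log(denom))
    if (grad) {
      # dL/dS = softmax - I
      P <- E / denom
      G <- (P - diag(nrow(P))) / tau # dL/dC
      # through cosine: C = Zn %*% t(Hn)
      dZn <- G %*% hn$Xn
      dHn <- crossprod(G, zn$Xn)
      # through row normalization: dX = (dXn - (dXn . Xn) Xn) / ||x||
      dZ <- (dZn - rowSums(dZn * zn$Xn) * zn$Xn) * zn$inv
      dH <- (dHn - rowSums(dHn * hn$Xn) * hn$Xn) * hn$inv
      g_main[[l]][idx, ] <- g_main[[l]][idx, , drop = FALSE] + dZ
      g_aug[[l]][idx, ] <- g_aug[[l]][idx, , drop = FALSE] + dH
    }
  }
  if (grad) list(loss = loss, g_main = g_main, g_aug = g_aug) else loss
}

#' Pairwise hinge ranking loss
#'
#' \deqn{L_r = \sum_i \sum_s \max(0,\; 1 - P_{pos,i} + P_{neg,i,s})}
#' Every observed pair should outscore each of its sampled unobserved pairs
#' by a margin of 1.
#'
#' @param pos_scores numeric vector of positive-pair scores.
#' @param neg_scores matrix `length(pos_scores)` x S of negative-pair scores
#'   (a vector is treated as one column).
#' @return scalar loss.
#' @export
hinge_loss <- function(pos_scores, neg_scores) {
  neg_scores <- as.matrix(neg_scores)
  if (nrow(neg_scores) != length(pos_scores)) stop("shape mismatch")
  sum(pmax(0, 1 - pos_scores + neg_scores))
}

#' Joint training objective
#'
#' \deqn{L = L_r + \lambda_1 (L_s^{(d)} + L_s^{(g)}) + \lambda_2 \|\Theta\|_2^2}
#' where `L_r` is the hinge ranking loss, the `L_s` are the drug- and
#' gene-side contrastive losses, and `Theta` collects the learnable base
#' embeddings.
#'
#' @param L_r hinge loss.
#' @param L_s_drug,L_s_gene contrastive losses.
#' @param param_sq_norm squared L2 norm of all parameters.
#' @param lambda1 contrastive weight.
#' @param lambda2 L2 weight.
#' @return scalar.
#' @export
total_loss <- function(L_r, L_s_drug, L_s_gene, param_sq_norm,
                       lambda1 = 0.1, lambda2 = 1e-5) {
  L_r + lambda1 * (L_s_drug + L_s_gene) + lambda2 * param_sq_norm
}

## Full objective + gradient w.r.t. the base embeddings for one batch.
##
## ops_main:  list of L sparse operators (dropout already applied).
## ops_aug:   list of L operators for the augmented view, or NULL (no
##            contrastive term; plain-GCN and MF ablations).
## batch:     list(anchors, pos, neg) — drug indices, positive gene indices,
##            negative gene index matrix (|anchors| x S).
## active_*:  indices of nodes participating in the contrastive loss.
## Returns loss components and gradients; pure given its inputs (all
## stochastic choices — masks, negatives — are made by the caller), which is
## what makes the finite-difference gradient check possible.
loss_and_grad <- function(ops_main, ops_aug, E_drug, E_gene, batch,
                          active_drugs, active_genes,
                          tau = 0.2, lambda1 = 0.1, lambda2 = 1e-5,
                          activation = "leaky_relu") {
  fwd <- forward_view(ops_main, E_drug, E_gene, activation)
  fd <- fwd$final_drug; fg <- fwd$final_gene

  # hinge ranking loss on the batch
  a <- batch$anchors; p <- batch$pos
  neg <- as.matrix(batch$neg)
  S <- ncol(neg)
  pos_sc <- rowSums(fd[a, , drop = FALSE] * fg[p, , drop = FALSE])
  g_fd <- fd * 0; g_fg <- fg * 0
  L_r <- 0
  for (s in seq_len(S)) {
    ns <- neg[, s]
    neg_sc <- rowSums(fd[a, , drop = FALSE] * fg[ns, , drop = FALSE])
    marg <- 1 - pos_sc + neg_sc
    L_r <- L_r + sum(pmax(0, marg)) # NaN margins propagate to the loss
    viol <- !is.na(marg) & marg > 0
    if (any(viol)) {
      av <- a[viol]; pv <- p[viol]; nv <- ns[viol]
      dfd <- fg[nv, , drop = FALSE] - fg[pv, , drop = FALSE]
      g_fd <- g_fd + rowsum_into(dfd, av, nrow(fd))
      g_fg <- g_fg + rowsum_into(-fd[av, , drop = FALSE], pv, nrow(fg))
      g_fg <- g_fg + rowsum_into(fd[av, , drop = FALSE], nv, nrow(fg))
    }
  }

  # contrastive term
  L_s_d <- 0; L_s_g <- 0
  gl_main_d <- NULL; gl_main_g <- NULL
  fwd_aug <- NULL; gl_aug_d <- NULL; gl_aug_g <- NULL
  if (!is.null(ops_aug) && lambda1 > 0) {
    fwd_aug <- forward_view(ops_aug, E_drug, E_gene, activation)
    cd <- info_nce(fwd$Zd, fwd_aug$Zd, active_drugs, tau, grad = TRUE)
    cg <- info_nce(fwd$Zg, fwd_aug$Zg, active_genes, tau, grad = TRUE)
    L_s_d <- cd$loss; L_s_g <- cg$loss
    scale_l <- function(lst) lapply(lst, function(M) lambda1 * M)
    gl_main_d <- scale_l(cd$g_main); gl_aug_d <- scale_l(cd$g_aug)
    gl_main_g <- scale_l(cg$g_main); gl_aug_g <- scale_l(cg$g_aug)
  }

  sqn <- sum(E_drug^2) + sum(E_gene^2)
  L <- total_loss(L_r, L_s_d, L_s_g, sqn, lambda1, lambda2)

  bk <- backward_view(fwd, ops_main, g_fd, g_fg,
                      gl_main_d, gl_main_g, activation)
  gE_d <- bk$gE_drug
  gE_g <- bk$gE_gene
  if (!is.null(fwd_aug)) {
    zero_d <- g_fd * 0; zero_g <- g_fg * 0
    bka <- backward_view(fwd_aug, ops_aug, zero_d, zero_g,
                         gl_aug_d, gl_aug_g, activation)
    gE_d <- gE_d + bka$gE_drug
    gE_g <- gE_g + bka$gE_gene
  }
  gE_d <- gE_d + 2 * lambda2 * E_drug
  gE_g <- gE_g + 2 * lambda2 * E_gene

  list(loss = L,
       components = c(L_r = L_r, L_s_drug = L_s_d, L_s_gene = L_s_g,
                      L2 = lambda2 * sqn),
       gE_drug = gE_d, gE_gene = gE_g)
}

## Scatter-add rows of X into an nrow_out-row accumulator at indices idx
## (idx may repeat).
rowsum_into <- function(X, idx, nrow_out) {
  acc <- matrix(0, nrow_out, ncol(X))
  rs <- rowsum(X, group = idx)
  acc[as.integer(rownames(rs)), ] <- rs
  acc
}
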