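# Shared fixtures and independent oracles for the test suite.

# A 4-drug x 3-gene toy graph used by gradient and propagation tests.
toy_graph <- function() {
  bipartite_graph(c("D1", "D1", "D2", "D3", "D4", "D3"),
                  c("G1", "G2", "G2", "G3", "G1", "G1"))
}

# Dense triple-loop oracle for one propagation step (no dropout,
# identity activation): z_drug[i, k] = sum_j A[i, j] * Xg[j, k].
dense_propagate_oracle <- function(A, Xg) {
  A <- as.matrix(A)
  out <- matrix(0, nrow(A), ncol(Xg))
  for (i in seq_len(nrow(A)))
    for (k in seq_len(ncol(Xg)))
      for (j in seq_len(ncol(A)))
        out[i, k] <- out[i, k] + A[i, j] * Xg[j, k]
  out
}

# Brute-force InfoNCE oracle: double loop over active nodes and layers,
# cosine similarities computed pairwise.
info_nce_oracle <- function(main_layers, aug_layers, active, tau) {
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  loss <- 0
  for (l in seq_along(main_layers)) {
    Z <- main_layers[[l]]; H <- aug_layers[[l]]
    for (i in active) {
      num <- exp(cosine(Z[i, ], H[i, ]) / tau)
      den <- sum(vapply(active, function(ip) {
        exp(cosine(Z[i, ], H[ip, ]) / tau)
      }, numeric(1)))
      loss <- loss - log(num / den)
    }
  }
  loss
}

# O(n^2) concordant-pair AUC oracle (ties count one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# Naive AUPR oracle: recompute precision/recall from scratch at every
# distinct threshold, then step-integrate (average precision).
aupr_recount_oracle <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1)
  ap <- 0
  for (k in which(y == 1)) {
    tp <- sum(y[1:k] == 1)
    ap <- ap + tp / k
  }
  ap / n_pos
}

# Exact top-t singular values via eigendecomposition of t(A) %*% A
# (a route independent of svd() and of the randomized algorithm).
exact_singular_values <- function(A, t) {
  ev <- eigen(crossprod(as.matrix(A)), symmetric = TRUE)$values
  sqrt(pmax(ev[seq_len(t)], 0))
}
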