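#' Ablation suite: compare model variants on shared splits
#'
#' Trains each requested variant on identical train/test splits (one
#' 80/20 holdout per seed, drawn once and reused by every variant) and
#' reports the mean of each link-prediction metric per variant. This
#' reproduces, at synthetic desk scale, the ablation comparison between the
#' full SVD-contrastive model, the plain GCN without contrastive learning,
#' the perturbation-based augmentations, and plain matrix factorization.
#'
#' @param graph a `bg_graph`.
#' @param control base [gclink_control()]; each variant overrides only
#'   `variant`.
#' @param variants character vector of variant names (>= 2).
#' @param seeds integer vector of seeds; metrics are averaged over seeds.
#' @return data.frame, one row per variant, columns
#'   `variant, auc, aupr, recall, precision, f1`.
#' @export
ablation_suite <- function(graph, control = gclink_control(epochs = 50),
                           variants = c("svd", "none", "edge_drop",
                                        "node_drop", "random_walk"),
                           seeds = 1:5) {
  stopifnot(length(variants) >= 2, length(seeds) >= 1)
  splits <- lapply(seeds, function(s) cv_folds(graph, k = 5, seed = s)[[1L]])
  rows <- lapply(variants, function(v) {
    ctl <- control; ctl$variant <- v
    reps <- mapply(function(split, s) {
      tg <- subgraph_from_edges(graph, split$train)
      fit <- gclink(tg, ctl, seed = s)
      pairs <- rbind(split$test, split$neg)
      labels <- rep(c(1L, 0L), c(nrow(split$test), nrow(split$neg)))
      rep <- compute_metrics(score_pairs(fit$final_drug, fit$final_gene,
                                         pairs), labels)
      unlist(rep[c("auc", "aupr", "recall", "precision", "f1")])
    }, splits, seeds)
    data.frame(variant = v, t(rowMeans(as.matrix(reps))))
  })
  do.call(rbind, rows)
}

#' Parameter sensitivity sweep
#'
#' Re-trains the model across a grid of one hyperparameter (embedding width
#' `d` or layer count `n_layers`), averaging held-out metrics over seeds.
#' No monotonicity is asserted; the optimum is data-dependent.
#'
#' @param graph a `bg_graph`.
#' @param control base [gclink_control()].
#' @param parameter `"d"` or `"n_layers"`.
#' @param values values to sweep (reference grids: d in 64/128/256/512/1024,
#'   layers in 1..4).
#' @param seeds integer seeds.
#' @return data.frame, one row per value, columns
#'   `parameter, value, auc, aupr, recall, precision, f1`.
#' @export
sensitivity_sweep <- function(graph, control = gclink_control(epochs = 50),
                              parameter = c("d", "n_layers"),
                              values = NULL, seeds = 1:3) {
  parameter <- match.arg(parameter)
  if (is.null(values)) {
    values <- switch(parameter, d = c(64, 128, 256, 512, 1024),
                     n_layers = 1:4)
  }
  stopifnot(length(values) >= 1, length(seeds) >= 1)
  splits <- lapply(seeds, function(s) cv_folds(graph, k = 5, seed = s)[[1L]])
  rows <- lapply(values, function(val) {
    ctl <- control; ctl[[parameter]] <- val
    reps <- mapply(function(split, s) {
      tg <- subgraph_from_edges(graph, split$train)
      fit <- gclink(tg, ctl, seed = s)
      pairs <- rbind(split$test, split$neg)
      labels <- rep(c(1L, 0L), c(nrow(split$test), nrow(split$neg)))
      rep <- compute_metrics(score_pairs(fit$final_drug, fit$final_gene,
                                         pairs), labels)
      unlist(rep[c("auc", "aupr", "recall", "precision", "f1")])
    }, splits, seeds)
    data.frame(parameter = parameter, value = val,
               t(rowMeans(as.matrix(reps))))
  })
  do.call(rbind, rows)
}
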