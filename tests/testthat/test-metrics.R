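test_that("inner-product scoring matches hand arithmetic", {
  fd <- rbind(c(1, 2), c(3, 0))
  fg <- rbind(c(3, -1), c(0, 5), c(1, 2))
  expect_equal(score_pairs(fd, fg, cbind(1, 1)), 1) # 1*3 + 2*(-1)
  expect_equal(score_pairs(fd, fg, cbind(2, 2)), 0) # orthogonal
  expect_equal(score_pairs(rbind(c(1, 2)), rbind(c(1, 2)), cbind(1, 1)), 5)
  expect_error(score_pairs(fd, fg, cbind(3, 1)), "range")
})

test_that("perfect separation yields all metrics equal to one", {
  rep <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(rep[c("auc", "aupr", "recall", "precision", "f1")]),
               c(auc = 1, aupr = 1, recall = 1, precision = 1, f1 = 1))
})

test_that("the confusion metrics follow the top-k binarization rule", {
  # 4 positives; top-4 scores contain 3 of them -> TP=3, FP=1, FN=1
  scores <- c(0.95, 0.90, 0.85, 0.80, 0.70, 0.60, 0.50)
  labels <- c(1, 1, 1, 0, 1, 0, 0)
  rep <- compute_metrics(scores, labels)
  expect_equal(rep$precision, 0.75)
  expect_equal(rep$recall, 0.75)
  expect_equal(rep$f1, 0.75)
  # fixed-threshold alternative
  rep2 <- compute_metrics(scores, labels, threshold = 0.65)
  expect_equal(rep2$recall, 1) # all 5 top scores predicted positive? no: 4 pos
  expect_error(compute_metrics(c(1, 2), c(1, 1)), "negative")
  expect_error(compute_metrics(c(1, 2), c(0, 0)), "positive")
})

test_that("AUC equals the O(n^2) concordant-pair count, ties included", {
  set.seed(12)
  scores <- round(rnorm(200), 1) # rounding forces ties
  labels <- rbinom(200, 1, 0.4)
  expect_equal(compute_metrics(scores, labels)$auc,
               auc_pair_oracle(scores, labels), tolerance = 1e-9)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.5)
  expect_equal(compute_metrics(exp(scores), labels)$auc,
               compute_metrics(scores, labels)$auc, tolerance = 1e-12)
})

test_that("label-permuted scores give chance-level AUC", {
  set.seed(77)
  scores <- rnorm(120)
  labels <- rep(c(1, 0), 60)
  aucs <- replicate(200, compute_metrics(scores, sample(labels))$auc)
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("ROC/PR integration agrees with independent references", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (r in 1:50) {
    n <- sample(30:80, 1)
    labels <- rbinom(n, 1, 0.5)
    scores <- rnorm(n) + labels
    if (sum(labels) == 0 || sum(labels) == n) next
    rep <- compute_metrics(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rep$auc, ref, tolerance = 1e-6)
    expect_equal(rep$aupr, aupr_recount_oracle(scores, labels),
                 tolerance = 1e-6)
  }
})

test_that("cross-validation aggregates fold reports reproducibly", {
  g <- synthetic_bipartite(30, 20, 2, 0.35, 0.05, seed = 5)
  ctl <- gclink_control(d = 16, epochs = 5, batch_size = 64, svd_rank = 3)
  cv <- cross_validate(g, ctl, k = 2, seed = 11)
  expect_length(cv$folds, 2L)
  expect_s3_class(cv$folds[[1]], "metrics_report")
  for (mname in c("auc", "aupr", "recall", "precision", "f1")) {
    expect_equal(cv$mean[[mname]],
                 mean(vapply(cv$folds, `[[`, numeric(1), mname)))
  }
  cv2 <- cross_validate(g, ctl, k = 2, seed = 11)
  expect_equal(cv$mean, cv2$mean, tolerance = 1e-12)
})

test_that("candidate ranking excludes known partners and matches a full sort", {
  g <- synthetic_bipartite(30, 20, 2, 0.35, 0.05, seed = 5)
  ctl <- gclink_control(d = 16, epochs = 5, batch_size = 64, svd_rank = 3)
  fit <- gclink(g, ctl, seed = 2)
  q <- g$drug_ids[1]
  top <- rank_candidates(fit, q, top_k = 15)
  expect_equal(nrow(top), 15L)
  known <- g$gene_ids[g$edges[g$edges[, 1] == 1L, 2]]
  expect_false(any(top$id %in% known))
  # full-sort oracle over all non-excluded candidates
  all_sc <- score_pairs(fit$final_drug, fit$final_gene,
                        cbind(1L, seq_len(20)))
  cand <- setdiff(seq_len(20), match(known, g$gene_ids))
  oracle <- cand[order(-all_sc[cand], cand)][1:15]
  expect_equal(top$id, g$gene_ids[oracle])
  expect_true(all(diff(top$score) <= 0))
  # known associations can be kept if asked
  top_all <- rank_candidates(fit, q, top_k = 20, exclude_known = FALSE)
  expect_equal(nrow(top_all), 20L)
  expect_error(rank_candidates(fit, "NOPE"), "nearest")
})

test_that("predict and the embedding scatter operate on identifiers", {
  g <- synthetic_bipartite(12, 8, 2, 0.5, 0.1, seed = 3)
  fit <- gclink(g, gclink_control(d = 8, epochs = 2, batch_size = 32,
                                  svd_rank = 2), seed = 1)
  sc <- predict(fit, drug = g$drug_ids[c(1, 2)], gene = g$gene_ids[c(1, 2)])
  expect_length(sc, 2L)
  expect_equal(sc, score_pairs(fit$final_drug, fit$final_gene,
                               cbind(c(1, 2), c(1, 2))))
  expect_error(predict(fit, drug = "XX", gene = g$gene_ids[1]), "unknown")
  df <- embedding_scatter(fit)
  expect_equal(nrow(df), 20L)
  expect_true(all(c("drug", "gene") %in% df$type))
})
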