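test_that("edge lists load with first-appearance indexing and deduplication", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("D1\tG1", "D1\tG2", "D2\tG1"), f)
  g <- read_edge_list(f)
  expect_equal(length(g$drug_ids), 2L)
  expect_equal(length(g$gene_ids), 2L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$drug_ids, c("D1", "D2"))

  writeLines(c("D1\tG1", "D1\tG1"), f)
  expect_equal(nrow(read_edge_list(f)$edges), 1L)

  writeLines(c("drug\tgene", "D1\tG1", "D2\tG2"), f)
  gh <- read_edge_list(f)
  expect_equal(nrow(gh$edges), 2L)
  expect_false("drug" %in% gh$drug_ids)
})

test_that("a 20-row file reproduces an independently built incidence matrix", {
  set.seed(31)
  rows <- unique(data.frame(d = sprintf("D%d", sample(1:6, 20, TRUE)),
                            g = sprintf("G%d", sample(1:5, 20, TRUE))))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rows, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- read_edge_list(f)
  # independent construction: a dict-of-sets walk over the rows
  sets <- list()
  for (r in seq_len(nrow(rows))) {
    sets[[rows$d[r]]] <- union(sets[[rows$d[r]]], rows$g[r])
  }
  A_hand <- matrix(0, length(g$drug_ids), length(g$gene_ids),
                   dimnames = list(g$drug_ids, g$gene_ids))
  for (d in names(sets)) for (gg in sets[[d]]) A_hand[d, gg] <- 1
  expect_equal(unname(as.matrix(g$A)), unname(A_hand))
})

test_that("malformed and empty edge-list files are rejected with line info", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(read_edge_list(f), "no associations")
  writeLines(c("D1\tG1", "only-one-field"), f)
  expect_error(read_edge_list(f), "line 2")
})

test_that("degree normalization matches the hand-computed scheme", {
  expect_equal(as.matrix(normalize_adjacency(matrix(1, 1, 1))),
               matrix(1, 1, 1), ignore_attr = TRUE)
  A <- matrix(c(1, 0, 1, 1), 2, 2) # rows: deg 2, 1; cols: deg 1, 2
  expect_equal(as.matrix(normalize_adjacency(A)),
               matrix(c(1 / sqrt(2), 0, 0.5, 1 / sqrt(2)), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  Az <- rbind(c(1, 1), c(0, 0))
  An <- as.matrix(normalize_adjacency(Az))
  expect_equal(An[2, ], c(0, 0))
  expect_false(anyNA(An))
})

test_that("normalization preserves support and stays within [0, 1]", {
  set.seed(4)
  for (rep in 1:5) {
    A <- matrix(rbinom(48, 1, 0.4), 8, 6)
    An <- as.matrix(normalize_adjacency(A))
    expect_identical(An > 0, A > 0)
    expect_true(all(An >= 0 & An <= 1))
  }
})

test_that("cv folds partition the edges with near-equal sizes, deterministically", {
  g <- synthetic_bipartite(20, 15, 2, 0.25, 0.05, seed = 9)
  k <- 5
  folds <- cv_folds(g, k = k, seed = 17)
  sizes <- vapply(folds, function(f) nrow(f$test), integer(1))
  expect_true(max(sizes) - min(sizes) <= 1L)
  expect_equal(sum(sizes), nrow(g$edges))
  all_test <- do.call(rbind, lapply(folds, `[[`, "test"))
  expect_equal(nrow(unique(all_test)), nrow(g$edges)) # disjoint union
  for (f in folds) {
    expect_equal(nrow(f$train) + nrow(f$test), nrow(g$edges))
    expect_equal(nrow(f$neg), nrow(f$test)) # balanced negatives
    # negatives never collide with any observed edge
    codes_e <- paste(g$edges[, 1], g$edges[, 2])
    expect_false(any(paste(f$neg[, 1], f$neg[, 2]) %in% codes_e))
  }
  folds2 <- cv_folds(g, k = k, seed = 17)
  expect_identical(folds, folds2)
  expect_error(cv_folds(g, k = nrow(g$edges) + 1L), "exceeds")
})

test_that("a 46892-edge split yields fold sizes 9378 and 9379 (twice)", {
  set.seed(100)
  m <- 500; n <- 300
  code <- sample.int(m * n, 46892)
  g <- bipartite_graph(sprintf("D%d", (code - 1) %% m + 1),
                       sprintf("G%d", (code - 1) %/% m + 1))
  expect_equal(nrow(g$edges), 46892L)
  sizes <- sort(vapply(cv_folds(g, k = 5, seed = 1), function(f)
    nrow(f$test), integer(1)))
  expect_equal(sizes, c(9378L, 9378L, 9378L, 9379L, 9379L))
})

test_that("synthetic generator plants the requested block structure", {
  # deterministic limit: p_in = 1, p_out = 0 gives exactly same-block pairs
  g <- synthetic_bipartite(8, 6, 2, 1, 0, seed = 1)
  db <- attr(g, "drug_blocks"); gb <- attr(g, "gene_blocks")
  same <- which(outer(db, gb, "=="), arr.ind = TRUE)
  expect_equal(nrow(g$edges), nrow(same))
  expect_true(all(db[g$edges[, 1]] == gb[g$edges[, 2]]))

  # edge count near the binomial expectation at the reference spec
  g2 <- synthetic_bipartite(100, 60, 4, 0.3, 0.02, seed = 5)
  db <- attr(g2, "drug_blocks"); gb <- attr(g2, "gene_blocks")
  n_in <- sum(outer(db, gb, "=="))
  n_out <- 100 * 60 - n_in
  mu <- 0.3 * n_in + 0.02 * n_out
  sdev <- sqrt(0.3 * 0.7 * n_in + 0.02 * 0.98 * n_out)
  expect_lt(abs(nrow(g2$edges) - mu), 4 * sdev)

  # different seeds give different edge sets
  g3 <- synthetic_bipartite(100, 60, 4, 0.3, 0.02, seed = 6)
  expect_false(identical(g2$edges, g3$edges))
  expect_error(synthetic_bipartite(5, 5, 2, p_in = 0.3, p_out = 0.4),
               "p_out")
})

test_that("within-block edge frequency converges to p_in on larger graphs", {
  g <- synthetic_bipartite(400, 400, 4, 0.3, 0.02, seed = 21)
  db <- attr(g, "drug_blocks"); gb <- attr(g, "gene_blocks")
  same <- outer(db, gb, "==")
  inblock_edges <- sum(same[g$edges])
  expect_lt(abs(inblock_edges / sum(same) - 0.3), 0.02)
})
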