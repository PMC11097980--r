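#' Bipartite drug-gene association graph
#'
#' Constructs the core data container: an ordered drug vocabulary, an ordered
#' gene vocabulary, the binary m x n association matrix `A` (sparse), and its
#' symmetric degree-normalized counterpart `A_norm` with entries
#' \eqn{\tilde A_{ij} = A_{ij} / \sqrt{d_i \, d_j}} where \eqn{d_i} is the
#' degree of drug i and \eqn{d_j} the degree of gene j.
#'
#' Duplicate (drug, gene) rows are collapsed: an association is binary.
#' Zero-degree rows/columns of `A_norm` are all-zero (such nodes simply
#' receive no messages during propagation).
#'
#' @param drug character vector of drug identifiers, one per association.
#' @param gene character vector of gene identifiers, same length as `drug`.
#' @param drug_ids,gene_ids optional explicit vocabularies. Defaults to the
#'   identifiers in first-appearance order; supplying them lets a training
#'   fold share the full graph's index space.
#' @return An object of class `"bg_graph"`: a list with elements `drug_ids`,
#'   `gene_ids`, `edges` (two-column integer matrix of 1-based indices, one
#'   row per unique association), `A` (sparse binary `dgCMatrix`), and
#'   `A_norm` (sparse real `dgCMatrix`).
#' @examples
#' g <- bipartite_graph(c("D1", "D1", "D2"), c("G1", "G2", "G1"))
#' g$A
#' @export
bipartite_graph <- function(drug, gene, drug_ids = NULL, gene_ids = NULL) {
  drug <- as.character(drug)
  gene <- as.character(gene)
  if (length(drug) != length(gene)) {
    stop("'drug' and 'gene' must have the same length")
  }
  if (length(drug) == 0L) stop("no associations")
  if (is.null(drug_ids)) drug_ids <- unique(drug)
  if (is.null(gene_ids)) gene_ids <- unique(gene)
  i <- match(drug, drug_ids)
  j <- match(gene, gene_ids)
  if (anyNA(i) || anyNA(j)) {
    stop("identifiers found outside the supplied vocabulary")
  }
  keep <- !duplicated(cbind(i, j))
  edges <- cbind(drug = i[keep], gene = j[keep])
  m <- length(drug_ids)
  n <- length(gene_ids)
  A <- Matrix::sparseMatrix(i = edges[, 1L], j = edges[, 2L], x = 1,
                            dims = c(m, n))
  structure(
    list(drug_ids = drug_ids, gene_ids = gene_ids, edges = edges,
         A = A, A_norm = normalize_adjacency(A)),
    class = "bg_graph"
  )
}

#' @exportS3Method base::print
print.bg_graph <- function(x, ...) {
  m <- length(x$drug_ids); n <- length(x$gene_ids); ne <- nrow(x$edges)
  cat(sprintf("Bipartite association graph: %d drugs x %d genes, %d edges (density %.4f)\n",
              m, n, ne, ne / (m * n)))
  invisible(x)
}

#' Graph summary
#'
#' @param object a `bg_graph`.
#' @param ... ignored.
#' @return list with `m`, `n`, `n_edges`, `density`.
#' @exportS3Method base::summary
summary.bg_graph <- function(object, ...) {
  m <- length(object$drug_ids); n <- length(object$gene_ids)
  ne <- nrow(object$edges)
  list(m = m, n = n, n_edges = ne, density = ne / (m * n))
}

#' Read a drug-gene association edge list
#'
#' Reads a tab-delimited file whose first two columns are drug identifier and
#' gene identifier (e.g. an export from DGIdb). Indices are assigned in
#' first-appearance order; duplicate rows collapse to one edge.
#'
#' @param path path to a TSV file.
#' @param header `TRUE`, `FALSE`, or `"auto"` (default): with `"auto"` the
#'   first line is treated as a header if its fields never reappear as a data
#'   row pair.
#' @return a [bipartite_graph()] object.
#' @export
read_edge_list <- function(path, header = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no associations in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop("malformed row (fewer than 2 tab-separated fields) at line ", bad[1L])
  }
  pair <- vapply(fields, function(f) paste(f[1L], f[2L], sep = "\t"),
                 character(1))
  drop_first <- isTRUE(header) ||
    (identical(header, "auto") && length(pair) > 1L &&
       !pair[1L] %in% pair[-1L] &&
       grepl("drug|gene|id|name", pair[1L], ignore.case = TRUE))
  if (drop_first) pair <- pair[-1L]
  if (length(pair) == 0L) stop("no associations in '", path, "'")
  d <- vapply(strsplit(pair, "\t", fixed = TRUE), `[`, character(1), 1L)
  g <- vapply(strsplit(pair, "\t", fixed = TRUE), `[`, character(1), 2L)
  bipartite_graph(d, g)
}

#' Write an edge list to TSV
#'
#' @param graph a `bg_graph`.
#' @param path output file.
#' @param header write a header line (default TRUE).
#' @export
write_edge_list <- function(graph, path, header = TRUE) {
  df <- data.frame(drug = graph$drug_ids[graph$edges[, 1L]],
                   gene = graph$gene_ids[graph$edges[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Symmetric degree normalization of a bipartite adjacency
#'
#' \eqn{\tilde A = D_d^{-1/2} A D_g^{-1/2}}: each entry is divided by the
#' square root of the product of its drug degree and gene degree. Rows or
#' columns with no edges stay all-zero (no NaN/Inf). The sparsity pattern is
#' preserved and every entry lies in \[0, 1\].
#'
#' @param A binary m x n matrix (dense or sparse).
#' @return sparse `dgCMatrix` of the same dimension.
#' @examples
#' normalize_adjacency(matrix(c(1, 0, 1, 1), 2, 2))
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dd <- Matrix::rowSums(A)
  dg <- Matrix::colSums(A)
  sd <- ifelse(dd > 0, 1 / sqrt(dd), 0)
  sg <- ifelse(dg > 0, 1 / sqrt(dg), 0)
  Matrix::Diagonal(x = sd) %*% A %*% Matrix::Diagonal(x = sg)
}

## Encode an (i, j) pair as a single double for fast set membership.
## Safe for m * n < 2^53.
.pair_code <- function(i, j, m) (as.numeric(j) - 1) * m + as.numeric(i)

#' Cross-validation folds for link prediction
#'
#' Partitions the known edges uniformly at random into `k` parts whose sizes
#' differ by at most one. Each fold holds one part out as test edges and
#' pairs it with `neg_ratio` times as many negatives sampled uniformly
#' without replacement from the unobserved (non-edge) pairs. Fully
#' determined by `seed`.
#'
#' @param graph a `bg_graph`.
#' @param k number of folds (default 5).
#' @param neg_ratio negatives per test edge (default 1, a balanced test set).
#' @param seed integer seed.
#' @return list of `k` folds; each is a list with `fold`, `train`
#'   (edge index matrix), `test`, and `neg` (non-edge index matrix).
#' @export
cv_folds <- function(graph, k = 5, neg_ratio = 1, seed = 1) {
  stopifnot(inherits(graph, "bg_graph"), k >= 2)
  ne <- nrow(graph$edges)
  if (k > ne) stop("k = ", k, " exceeds the number of edges (", ne, ")")
  m <- length(graph$drug_ids)
  n <- length(graph$gene_ids)
  edge_code <- .pair_code(graph$edges[, 1L], graph$edges[, 2L], m)
  with_seed(seed, {
    perm <- sample.int(ne)
    fold_of <- rep_len(seq_len(k), ne)[order(perm)] # sizes differ by <= 1
    lapply(seq_len(k), function(f) {
      test_idx <- which(fold_of == f)
      n_neg <- round(neg_ratio * length(test_idx))
      neg <- sample_nonedges(edge_code, m, n, n_neg)
      list(fold = f,
           train = graph$edges[-test_idx, , drop = FALSE],
           test = graph$edges[test_idx, , drop = FALSE],
           neg = neg)
    })
  })
}

## Uniform sample of n_neg distinct non-edges by rejection; errors when the
## complement pool is too small.
sample_nonedges <- function(edge_code, m, n, n_neg) {
  pool <- m * n - length(edge_code)
  if (n_neg > pool) {
    stop("requested ", n_neg, " negatives but only ", pool, " non-edges exist")
  }
  got <- numeric(0)
  while (length(got) < n_neg) {
    need <- n_neg - length(got)
    cand <- .pair_code(sample.int(m, 2L * need + 10L, replace = TRUE),
                       sample.int(n, 2L * need + 10L, replace = TRUE), m)
    cand <- setdiff(cand, c(edge_code, got))
    got <- c(got, cand[seq_len(min(need, length(cand)))])
  }
  code <- got[seq_len(n_neg)]
  cbind(drug = as.integer((code - 1) %% m + 1),
        gene = as.integer((code - 1) %/% m + 1))
}

#' Synthetic bipartite graph with planted block structure
#'
#' Drugs and genes are assigned to `n_blocks` communities round-robin; each
#' (drug, gene) pair is an edge independently with probability `p_in` when
#' the two nodes share a block and `p_out` otherwise. This emulates the
#' clustered sparsity of curated drug-gene interaction databases, so that
#' recovering held-out edges is a meaningful test of the model.
#'
#' @param m,n number of drugs / genes.
#' @param n_blocks planted community count.
#' @param p_in within-block association probability.
#' @param p_out cross-block association probability (`p_out < p_in`).
#' @param seed integer seed.
#' @return a `bg_graph` with extra attributes `drug_blocks` and
#'   `gene_blocks` (integer block labels, for assertions on planted
#'   structure).
#' @export
synthetic_bipartite <- function(m = 100, n = 60, n_blocks = 4,
                                p_in = 0.3, p_out = 0.02, seed = 1) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, n_blocks <= min(m, n))
  db <- rep_len(seq_len(n_blocks), m)
  gb <- rep_len(seq_len(n_blocks), n)
  with_seed(seed, {
    p <- ifelse(outer(db, gb, "=="), p_in, p_out)
    hit <- which(matrix(stats::runif(m * n), m, n) < p, arr.ind = TRUE)
    if (nrow(hit) == 0L) {
      stop("synthetic graph has zero edges; increase p_in or the graph size")
    }
    ids_d <- sprintf("D%03d", seq_len(m))
    ids_g <- sprintf("G%03d", seq_len(n))
    g <- bipartite_graph(ids_d[hit[, 1L]], ids_g[hit[, 2L]],
                         drug_ids = ids_d, gene_ids = ids_g)
    attr(g, "drug_blocks") <- db
    attr(g, "gene_blocks") <- gb
    g
  })
}

## Restrict a graph to a training edge subset, keeping the full vocabulary.
subgraph_from_edges <- function(graph, edges) {
  bipartite_graph(graph$drug_ids[edges[, 1L]], graph$gene_ids[edges[, 2L]],
                  drug_ids = graph$drug_ids, gene_ids = graph$gene_ids)
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
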