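# Word-association graph: windowed co-occurrence counts -> positive PMI ->
# low-rank embedding -> cosine k-nearest-neighbour graph.

#' Build a word-association graph from tokenized posts
#'
#' Pipeline: (1) co-occurrence counts between token positions within a
#' symmetric window inside each post (default: the whole post, appropriate
#' for short texts and for percentile tags appended at the end); (2)
#' positive pointwise mutual information weighting with context-distribution
#' smoothing (context marginals raised to `cds`, the standard 0.75 exponent,
#' which counteracts PMI's bias toward rare contexts); (3) low-rank spectral
#' embedding of the symmetrized PPMI matrix over its positive eigenvalues
#' (rows scaled by the square root of the eigenvalues); (4) k-nearest-neighbour graph under cosine similarity
#' with edge weight `max(cosine, 0)`, symmetrized by mutual max. No
#' self-loops.
#'
#' @param token_lists List of character vectors (one per post), as returned
#'   by [tokenize()].
#' @param window Maximum distance between co-occurring positions (default
#'   `Inf`: all pairs within a post).
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary.
#' @param rank Embedding rank (capped at vocabulary size minus one).
#' @param k Neighbours per token in the kNN step.
#' @param cds Context-distribution smoothing exponent (1 = plain PPMI).
#' @return An `assoc_graph`: `vocabulary` (tibble token, count), sparse
#'   symmetric weight matrix `weights`, and `params`.
#' @export
build_graph <- function(token_lists, window = Inf, min_count = 3L,
                        rank = 64L, k = 50L, cds = 0.75) {
  if (length(token_lists) == 0L) wx_abort("corpus is empty")
  lens <- lengths(token_lists)
  dt <- data.table::data.table(
    post = rep.int(seq_along(token_lists), lens),
    pos = unlist(lapply(lens, seq_len), use.names = FALSE),
    tok = unlist(token_lists, use.names = FALSE))
  counts <- dt[, .N, by = "tok"]
  vocab <- counts[counts$N >= min_count, ]
  data.table::setorderv(vocab, "tok")
  if (nrow(vocab) == 0L) wx_abort("vocabulary empty after min_count pruning")
  dt <- dt[dt$tok %in% vocab$tok, ]
  dt[, `:=`(tid = match(dt$tok, vocab$tok))]

  # all unordered position pairs within the window, per post
  pairs <- dt[dt, on = "post", allow.cartesian = TRUE]
  pairs <- pairs[pairs$pos < pairs$i.pos &
                   (pairs$i.pos - pairs$pos) <= window, ]
  pairs <- pairs[pairs$tid != pairs$i.tid, ]  # no self-loops
  if (nrow(pairs) == 0L) wx_abort("no co-occurrences found")
  ii <- pmin(pairs$tid, pairs$i.tid)
  jj <- pmax(pairs$tid, pairs$i.tid)
  V <- nrow(vocab)
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(V, V))
  C <- C + Matrix::t(C)  # symmetric joint counts

  # PPMI with context-distribution smoothing
  total <- sum(C)
  rs <- Matrix::rowSums(C)
  ctx <- rs^cds
  ctx <- ctx / sum(ctx)
  Ct <- methods::as(C, "TsparseMatrix")
  pmi <- log((Ct@x / total) / (rs[Ct@i + 1L] / total * ctx[Ct@j + 1L]))
  keep <- pmi > 0
  P <- Matrix::sparseMatrix(i = Ct@i[keep] + 1L, j = Ct@j[keep] + 1L,
                            x = pmi[keep], dims = c(V, V),
                            dimnames = list(vocab$tok, vocab$tok))

  # low-rank embedding: spectral decomposition of the symmetrized PPMI,
  # keeping only positive-eigenvalue directions (the PSD projection of the
  # similarity kernel). Unlike a plain SVD this preserves first-order
  # association: an exclusively co-occurring pair embeds onto its shared
  # positive component instead of splitting across a +/- eigenpair.
  # Vocabularies here are small enough (hundreds to low thousands) for LAPACK.
  Psym <- as.matrix((P + Matrix::t(P)) / 2)
  eg <- eigen(Psym, symmetric = TRUE)
  npos <- sum(eg$values > 1e-10)
  if (npos == 0L) wx_abort("PPMI matrix has no positive spectrum")
  r <- min(rank, npos)
  emb <- eg$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(r)]), r, r)
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  en <- emb / nrm
  S <- en %*% t(en)
  diag(S) <- -Inf

  kk <- min(k, V - 1L)
  W <- matrix(0, V, V)
  for (i in seq_len(V)) {
    nb <- order(S[i, ], decreasing = TRUE)[seq_len(kk)]
    W[i, nb] <- pmax(S[i, nb], 0)
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  dimnames(W) <- list(vocab$tok, vocab$tok)

  structure(list(
    vocabulary = tibble::tibble(token = vocab$tok, count = vocab$N),
    weights = methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
    ppmi = P,
    params = list(window = window, min_count = min_count, rank = r, k = kk,
                  cds = cds)),
    class = "assoc_graph")
}

#' @export
print.assoc_graph <- function(x, ...) {
  cat("<assoc_graph>", nrow(x$vocabulary), "tokens,",
      Matrix::nnzero(x$weights) / 2, "edges (window",
      x$params$window, ", min_count", x$params$min_count, ", rank",
      x$params$rank, ", k", x$params$k, ")\n")
  invisible(x)
}
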