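# Random-walk-with-restart label propagation over the word-association
# graph, combining two polarity walks into a [-1, +1] valence lexicon.

#' Seed specification for label propagation
#'
#' Two opposite-polarity sets of (token, weight) pairs. Weights must be
#' positive and finite; the sets must be disjoint.
#'
#' @param positive,negative Named numeric vectors (names are tokens, values
#'   are weights), or character vectors (unit weights).
#' @param name Scale label.
#' @return A `seed_spec`.
#' @export
seed_spec <- function(positive, negative, name = "scale") {
  as_wts <- function(x) {
    if (is.character(x)) x <- setNames(rep(1, length(x)), x)
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      wx_abort("seeds must be named")
    }
    if (any(!is.finite(x)) || any(x <= 0)) {
      wx_abort("seed weights must be positive and finite")
    }
    x
  }
  positive <- as_wts(positive); negative <- as_wts(negative)
  if (length(intersect(names(positive), names(negative)))) {
    wx_abort("positive and negative seed sets must be disjoint")
  }
  structure(list(positive = positive, negative = negative, name = name),
            class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat("<seed_spec>", x$name, "-", length(x$positive), "positive /",
      length(x$negative), "negative seeds\n")
  invisible(x)
}

#' Default sentiment seed words
#'
#' Twenty strongly positive and twenty strongly negative everyday evaluative
#' words (unit weights), in the tradition of rule-based social-media
#' sentiment lexicons, which anchor their scales with a generous set of
#' unambiguously polar words; a larger seed set averages away
#' corpus-sampling noise in the association graph. Seeds absent from a given
#' corpus vocabulary are simply dropped at propagation time. The list is
#' configurable: any [seed_spec()] can be passed to
#' [induce_sentiment_lexicon()].
#'
#' @return A `seed_spec` named "sentiment".
#' @export
default_sentiment_seeds <- function() {
  seed_spec(
    positive = c("excellent", "wonderful", "amazing", "lovely", "happy",
                 "joy", "brilliant", "beautiful", "fabulous", "superb",
                 "gorgeous", "glorious", "delightful", "stunning", "perfect",
                 "cheerful", "bliss", "enjoyable", "good", "nice"),
    negative = c("terrible", "horrible", "awful", "dreadful", "miserable",
                 "misery", "nasty", "foul", "grim", "dismal", "atrocious",
                 "abysmal", "appalling", "horrendous", "vile", "horrid",
                 "depressing", "rubbish", "lousy", "woeful"),
    name = "sentiment")
}

# one random-walk-with-restart score vector
rwr_scores <- function(P, e, restart, tol, max_iter) {
  s <- e
  for (it in seq_len(max_iter)) {
    s_new <- as.numeric((1 - restart) * Matrix::crossprod(P, s)) + restart * e
    if (max(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
  }
  wx_abort("random walk did not converge within max_iter")
}

#' Propagate seed polarity over a word-association graph
#'
#' Two random-walk-with-restart score vectors are computed over the
#' row-normalized edge weights, one per polarity, with restart mass
#' distributed over that polarity's seeds proportional to their weights.
#' Token polarity is `p = (pos - neg) / (pos + neg)` (0 where both are 0,
#' e.g. unreachable nodes); the returned valence is `p` standardized over
#' the vocabulary and squashed to `[-1, +1]` with `tanh`. Swapping the two
#' seed sets negates the lexicon exactly.
#'
#' @param graph An `assoc_graph`.
#' @param seeds A [seed_spec()]; at least one seed of each polarity must be
#'   present in the graph vocabulary.
#' @param restart Restart (teleport) probability in (0, 1). The default
#'   0.15 corresponds to the conventional walk-continuation probability of
#'   0.85: at each step the walk continues along an edge with probability
#'   1 - restart and teleports back to the seed set otherwise.
#' @param tol Max-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `token_lexicon` (token, valence, count) named after the seeds.
#' @export
propagate <- function(graph, seeds, restart = 0.15, tol = 1e-6,
                      max_iter = 10000L) {
  stopifnot(inherits(graph, "assoc_graph"), inherits(seeds, "seed_spec"))
  if (restart <= 0 || restart >= 1) wx_abort("restart must be in (0, 1)")
  vocab <- graph$vocabulary$token
  W <- graph$weights
  rs <- Matrix::rowSums(W)
  Dinv <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0))
  P <- Dinv %*% W  # row-stochastic (zero rows stay zero)

  seed_vec <- function(w) {
    w <- w[names(w) %in% vocab]
    if (length(w) == 0L) {
      wx_abort("no seeds of one polarity present in the vocabulary")
    }
    e <- numeric(length(vocab))
    e[match(names(w), vocab)] <- w / sum(w)
    e
  }
  pos <- rwr_scores(P, seed_vec(seeds$positive), restart, tol, max_iter)
  neg <- rwr_scores(P, seed_vec(seeds$negative), restart, tol, max_iter)
  tot <- pos + neg
  p <- ifelse(tot > 0, (pos - neg) / tot, 0)
  sdp <- sd(p)
  val <- if (is.na(sdp) || sdp == 0) rep(0, length(p)) else {
    tanh((p - mean(p)) / sdp)
  }
  token_lexicon(tibble::tibble(token = vocab, valence = val,
                               count = graph$vocabulary$count),
                scale_name = seeds$name)
}
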