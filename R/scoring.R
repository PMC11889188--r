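# Modifier-aware scoring of posts on a lexicon scale. The modifier constants
# follow the familiar rule-based social-media sentiment conventions
# (negation damping -0.74, alpha = 15 normalization); all are configurable.

#' Grammatical modifier configuration for scoring
#'
#' @param negators Tokens that flip and damp a valence when they occur within
#'   `negation_scope` tokens before it.
#' @param intensifiers Named numeric vector: token -> multiplicative factor
#'   applied to the immediately following valence (factors above 1 amplify,
#'   below 1 dampen).
#' @param negation_factor Multiplier applied under negation (sign flip plus
#'   damping).
#' @param negation_scope How many preceding tokens are searched for a
#'   negator.
#' @param caps_boost Magnitude increment for all-caps lexicon tokens.
#' @param excl_boost Magnitude increment per exclamation mark (at most
#'   `excl_max` count).
#' @param excl_max Maximum exclamation marks counted.
#' @param alpha Normalization constant: summed valence `v` maps to
#'   `v / sqrt(v^2 + alpha)`.
#' @param enabled Master switch; when `FALSE` only the bare lexicon lookup
#'   and normalization are applied.
#' @return A `modifier_config` list.
#' @export
modifier_config <- function(
    negators = c("not", "no", "never", "none", "neither", "nor", "cannot",
                 "can't", "don't", "doesn't", "didn't", "isn't", "wasn't",
                 "aren't", "won't", "wouldn't", "couldn't", "shouldn't",
                 "ain't", "hardly", "barely", "scarcely", "without"),
    intensifiers = c(very = 1.3, really = 1.3, extremely = 1.4,
                     absolutely = 1.4, so = 1.2, totally = 1.3,
                     incredibly = 1.4, utterly = 1.4, quite = 1.1,
                     pretty = 1.1, super = 1.3, bloody = 1.25,
                     proper = 1.15, too = 1.15, rather = 1.05,
                     slightly = 0.8, somewhat = 0.85, fairly = 0.9,
                     marginally = 0.8),
    negation_factor = -0.74, negation_scope = 3L,
    caps_boost = 0.25, excl_boost = 0.292, excl_max = 3L,
    alpha = 15, enabled = TRUE) {
  structure(list(negators = negators, intensifiers = intensifiers,
                 negation_factor = negation_factor,
                 negation_scope = as.integer(negation_scope),
                 caps_boost = caps_boost, excl_boost = excl_boost,
                 excl_max = as.integer(excl_max), alpha = alpha,
                 enabled = isTRUE(enabled)),
            class = "modifier_config")
}

# Vectorized scoring core over a flat token table.
# details: list as from tokenize_detail(); returns list(score, flat table)
score_core <- function(details, lexicon, modifiers) {
  n <- length(details)
  lens <- vapply(details, function(d) length(d$tokens), integer(1))
  n_excl <- vapply(details, `[[`, integer(1), "n_excl")
  flat <- data.table::data.table(
    post = rep.int(seq_len(n), lens),
    tok = unlist(lapply(details, `[[`, "tokens"), use.names = FALSE),
    caps = unlist(lapply(details, `[[`, "allcaps"), use.names = FALSE))
  if (nrow(flat) == 0L) {
    flat[, `:=`(valence = numeric(0), applied = numeric(0))]
    return(list(score = rep(0, n), flat = flat))
  }
  v <- lexicon$valence[match(flat$tok, lexicon$token)]
  v[is.na(v)] <- 0

  if (modifiers$enabled) {
    is_neg <- flat$tok %in% modifiers$negators
    int_f <- modifiers$intensifiers[flat$tok]
    int_f[is.na(int_f)] <- 1
    shift_in_post <- function(x, by, fill) {
      y <- data.table::shift(x, by, fill = fill)
      samepost <- data.table::shift(flat$post, by, fill = -1L) == flat$post
      ifelse(samepost, y, fill)
    }
    prev_int <- shift_in_post(unname(int_f), 1L, 1)
    negated <- rep(FALSE, nrow(flat))
    for (b in seq_len(modifiers$negation_scope)) {
      negated <- negated | shift_in_post(is_neg, b, FALSE)
    }
    applied <- v * prev_int
    applied[negated] <- applied[negated] * modifiers$negation_factor
    boost <- flat$caps & applied != 0
    applied[boost] <- applied[boost] + sign(applied[boost]) * modifiers$caps_boost
  } else {
    applied <- v
  }
  flat[, `:=`(valence = v, applied = applied)]
  sums <- rep(0, n)
  agg <- flat[, list(s = sum(.SD$applied)), by = "post"]
  sums[agg$post] <- agg$s
  if (modifiers$enabled) {
    ne <- pmin(n_excl, modifiers$excl_max)
    sums <- sums + sign(sums) * modifiers$excl_boost * ne
  }
  list(score = sums / sqrt(sums^2 + modifiers$alpha), flat = flat)
}

#' Score one text on a lexicon scale
#'
#' Token valences are looked up in the lexicon; a negator within the
#' preceding `negation_scope` tokens flips and damps the valence; an
#' intensifier scales the next valence; all-caps lexicon tokens and
#' exclamation marks amplify. The summed valence `v` is normalized to
#' `v / sqrt(v^2 + alpha)`, so scores lie strictly inside `[-1, +1]`. Empty
#' or fully out-of-vocabulary text scores 0.
#'
#' @param text A single string.
#' @param lexicon A `token_lexicon`.
#' @param modifiers A [modifier_config()].
#' @return A `scored_post`: list with `score`, `scale_name`,
#'   `contributing_tokens` (tibble token, valence, applied — the trace from
#'   which the score is exactly recomputable) and `n_excl`.
#' @export
score_text <- function(text, lexicon, modifiers = modifier_config()) {
  stopifnot(length(text) == 1L)
  if (nrow(lexicon) == 0L) wx_abort("lexicon is empty")
  details <- tokenize_detail(text)
  res <- score_core(details, lexicon, modifiers)
  contrib <- tibble::as_tibble(res$flat[res$flat$applied != 0,
                                        c("tok", "valence", "applied")])
  names(contrib)[1] <- "token"
  structure(list(score = res$score[1],
                 scale_name = scale_name(lexicon) %||% "scale",
                 contributing_tokens = contrib,
                 n_excl = details[[1]]$n_excl),
            class = "scored_post")
}

#' @export
print.scored_post <- function(x, ...) {
  cat("<scored_post>", x$scale_name, "score", round(x$score, 4), "from",
      nrow(x$contributing_tokens), "contributing tokens\n")
  invisible(x)
}

#' Score a corpus on a lexicon scale
#'
#' Element-wise [score_text()] over the corpus (single vectorized pass;
#' order-preserving, stateless and deterministic). Adds a
#' `score_<scale>` column.
#'
#' @param posts Corpus tibble with a `text` column.
#' @param lexicon A `token_lexicon`.
#' @param modifiers A [modifier_config()].
#' @return `posts` with a `score_<scale_name>` column appended.
#' @export
score_corpus <- function(posts, lexicon, modifiers = modifier_config()) {
  if (nrow(lexicon) == 0L) wx_abort("lexicon is empty")
  col <- paste0("score_", scale_name(lexicon) %||% "scale")
  if (nrow(posts) == 0L) {
    posts[[col]] <- numeric(0)
    return(posts)
  }
  res <- score_core(tokenize_detail(posts$text), lexicon, modifiers)
  posts[[col]] <- res$score
  posts
}
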