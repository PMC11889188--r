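# Token lexicons, percentile tagging of extreme-weather posts, and the two
# induction entry points (sentiment and per-condition weather severity).

#' Token valence lexicon
#'
#' @param entries Tibble with columns `token` (unique; emojis allowed) and
#'   `valence` (in `[-1, +1]`); an optional `count` column records corpus
#'   frequency.
#' @param scale_name Scale label ("sentiment" or a weather condition).
#' @return A `token_lexicon`.
#' @export
token_lexicon <- function(entries, scale_name = "sentiment") {
  stopifnot(all(c("token", "valence") %in% names(entries)))
  if (anyDuplicated(entries$token)) wx_abort("lexicon tokens must be unique")
  if (any(!is.finite(entries$valence)) ||
      any(abs(entries$valence) > 1 + 1e-12)) {
    wx_abort("valences must lie in [-1, +1]")
  }
  entries$valence <- pmin(1, pmax(-1, entries$valence))
  structure(tibble::as_tibble(entries),
            scale_name = scale_name,
            class = c("token_lexicon", class(tibble::tibble())))
}

#' @export
print.token_lexicon <- function(x, ...) {
  cat("<token_lexicon>", attr(x, "scale_name"), "-", nrow(x), "tokens\n")
  ord <- order(x$valence)
  show <- unique(c(head(ord, 3), tail(ord, 3)))
  print(tibble::as_tibble(x)[show, ], n = length(show))
  invisible(x)
}

#' Scale name of a lexicon
#' @param lexicon A `token_lexicon`.
#' @return The scale label.
#' @export
scale_name <- function(lexicon) attr(lexicon, "scale_name")

#' Percentile tagging scheme for a continuous covariate
#'
#' Posts in the extreme percentile bands of a condition's z-score get an
#' artificial tag token appended once: the top `cuts[1]` fraction gets
#' `high_tags[1]`, the `(cuts[1], cuts[2]]` band `high_tags[2]`, the
#' `(cuts[2], cuts[3]]` band `high_tags[3]`, mirrored at the bottom with
#' `low_tags`. Tag weights (one per band, strictly decreasing outward-in is
#' conventional) later serve as seed weights.
#'
#' @param cuts Strictly increasing percentile boundaries, all below 0.5.
#' @param high_tags,low_tags Tag labels (must not occur in the corpus).
#' @param tag_weights Positive per-band seed weights.
#' @return A `tag_scheme`.
#' @export
tag_scheme <- function(cuts = c(0.01, 0.02, 0.03),
                       high_tags = c("top1", "top2", "top3"),
                       low_tags = c("low1", "low2", "low3"),
                       tag_weights = c(3, 2, 1)) {
  if (is.unsorted(cuts, strictly = TRUE) || any(cuts >= 0.5) ||
      any(cuts <= 0)) {
    wx_abort("cuts must be strictly increasing, in (0, 0.5)")
  }
  stopifnot(length(high_tags) == length(cuts),
            length(low_tags) == length(cuts),
            length(tag_weights) == length(cuts))
  if (any(tag_weights <= 0)) wx_abort("tag weights must be positive")
  structure(list(cuts = cuts, high_tags = high_tags, low_tags = low_tags,
                 tag_weights = tag_weights),
            class = "tag_scheme")
}

#' Tag posts in extreme percentile bands of a condition z-score
#'
#' Posts with a non-missing `z_<condition>` are ranked (descending for the
#' high bands, ascending for the low bands; ties broken by original row
#' order, a stable rule). Band sizes are rank-based:
#' `floor(n * cuts[k]) - floor(n * cuts[k-1])` posts in band `k`. The tag is
#' appended once to the post's text and recorded in a `tag` column; all
#' other posts are unchanged. A post receives at most one tag; in the fully
#' degenerate case where the same post qualifies for both extremes (all
#' z-scores equal), the low tag wins — low bands are assigned after high
#' bands.
#'
#' @param posts Annotated corpus tibble (needs `z_<condition>`).
#' @param condition One of [weather_conditions()].
#' @param scheme A [tag_scheme()].
#' @return `posts` with `tag` column and tags appended to `text`.
#' @export
tag_percentiles <- function(posts, condition, scheme = tag_scheme()) {
  zcol <- paste0("z_", condition)
  if (!zcol %in% names(posts)) {
    wx_abort(paste0("posts carry no ", zcol, " column"))
  }
  z <- posts[[zcol]]
  ok <- which(!is.na(z))
  n <- length(ok)
  tag <- rep(NA_character_, nrow(posts))
  sizes <- floor(n * scheme$cuts)
  band_n <- diff(c(0L, sizes))
  if (any(band_n == 0L)) {
    warning("some percentile bands are empty at n = ", n)
  }
  # stable: order() is stable for ties, preserving original row order
  hi <- ok[order(-z[ok])]
  lo <- ok[order(z[ok])]
  upto <- 0L
  for (b in seq_along(band_n)) {
    if (band_n[b] > 0L) {
      tag[hi[(upto + 1L):(upto + band_n[b])]] <- scheme$high_tags[b]
      tag[lo[(upto + 1L):(upto + band_n[b])]] <- scheme$low_tags[b]
    }
    upto <- upto + band_n[b]
  }
  posts$tag <- tag
  tagged <- !is.na(tag)
  posts$text[tagged] <- paste(posts$text[tagged], tag[tagged])
  posts
}

#' Induce a corpus-specific sentiment lexicon
#'
#' Composition of [tokenize()], [build_graph()] and [propagate()] with the
#' sentiment seed words.
#'
#' @param posts Filtered corpus tibble with a `text` column.
#' @param seeds A [seed_spec()] (default [default_sentiment_seeds()]).
#' @param window,min_count,rank,k,cds Graph parameters, see [build_graph()].
#' @param restart,tol,max_iter Propagation parameters, see [propagate()].
#' @return A `token_lexicon` with scale name "sentiment".
#' @export
induce_sentiment_lexicon <- function(posts, seeds = default_sentiment_seeds(),
                                     window = Inf, min_count = 10L,
                                     rank = 64L, k = 50L, cds = 0.75,
                                     restart = 0.15,
                                     tol = 1e-6, max_iter = 10000L) {
  g <- build_graph(tokenize(posts$text), window = window,
                   min_count = min_count, rank = rank, k = k, cds = cds)
  propagate(g, seeds, restart = restart, tol = tol, max_iter = max_iter)
}

#' Induce a weather-severity lexicon for one condition
#'
#' Appends percentile tags to the condition's extreme posts, rebuilds the
#' word-association graph on the tagged corpus, and propagates with the tags
#' as weighted seeds (high tags positive, low tags negative, weights from
#' the scheme). Tags absent from the graph (empty band or pruned by
#' `min_count`) are dropped with a warning. Tag tokens are removed from the
#' returned lexicon. Repeat per condition for five severity classifiers.
#'
#' @param posts Annotated corpus tibble (needs `z_<condition>` and `text`).
#' @param condition One of [weather_conditions()].
#' @param scheme A [tag_scheme()].
#' @inheritParams induce_sentiment_lexicon
#' @return A `token_lexicon` whose scale name is the condition.
#' @export
induce_weather_lexicon <- function(posts, condition, scheme = tag_scheme(),
                                   window = Inf, min_count = 10L,
                                   rank = 64L, k = 50L, cds = 0.75,
                                   restart = 0.15,
                                   tol = 1e-6, max_iter = 10000L) {
  tagged <- tag_percentiles(posts, condition, scheme)
  g <- build_graph(tokenize(tagged$text), window = window,
                   min_count = min_count, rank = rank, k = k, cds = cds)
  in_vocab <- function(tags, w) {
    present <- tags %in% g$vocabulary$token
    if (!all(present)) {
      warning("tags absent from the graph: ",
              paste(tags[!present], collapse = ", "))
    }
    setNames(w[present], tags[present])
  }
  pos <- in_vocab(scheme$high_tags, scheme$tag_weights)
  neg <- in_vocab(scheme$low_tags, scheme$tag_weights)
  if (length(pos) == 0L || length(neg) == 0L) {
    wx_abort("no tags of one polarity survive in the graph vocabulary")
  }
  lex <- propagate(g, seed_spec(pos, neg, name = condition),
                   restart = restart, tol = tol, max_iter = max_iter)
  keep <- !lex$token %in% c(scheme$high_tags, scheme$low_tags)
  token_lexicon(tibble::as_tibble(lex)[keep, ], scale_name = condition)
}

#' Read / write a lexicon as two-column TSV
#'
#' UTF-8, token TAB valence, emojis raw.
#'
#' @param lexicon A `token_lexicon`.
#' @param path File path.
#' @param scale_name Scale label to attach on reading.
#' @return `write_lexicon_tsv` returns the path; `read_lexicon_tsv` a
#'   `token_lexicon`.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(lexicon$token,
                   format(lexicon$valence, digits = 15, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path, scale_name = "sentiment") {
  ln <- readLines(path, encoding = "UTF-8")
  parts <- stringi::stri_split_fixed(ln, "\t", n = 2)
  token_lexicon(tibble::tibble(
    token = vapply(parts, `[`, character(1), 1),
    valence = as.numeric(vapply(parts, `[`, character(1), 2))),
    scale_name = scale_name)
}
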