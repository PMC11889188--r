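# Five-stage filtering cascade reducing a raw thematic corpus to
# human-authored weather posts, with a per-stage audit report.

ci_contains <- function(x, pattern) {
  # case-insensitive literal substring, with full Unicode case folding
  out <- stringi::stri_detect_regex(x, paste0("\\Q", pattern, "\\E"),
                                    case_insensitive = TRUE)
  out[is.na(out)] <- FALSE
  out
}

#' Keep posts whose text contains a theme term
#'
#' Case-insensitive literal substring match ("whetherby" does not match
#' "weather"; "Lovely WEATHER" does).
#'
#' @param posts Corpus tibble with a `text` column.
#' @param term Non-empty search term (default "weather").
#' @return The retained posts.
#' @export
thematic_filter <- function(posts, term = "weather") {
  if (!nzchar(term)) wx_abort("term must be non-empty")
  posts[ci_contains(posts$text, term), ]
}

#' Remove high-volume accounts
#'
#' Drops every post from any account whose share of the *input* corpus
#' strictly exceeds `threshold` (shares are computed once, not iteratively).
#' The strict inequality reads the "over 1 percent" rule literally: an
#' account at exactly the threshold is retained.
#'
#' @param posts Corpus tibble with an `account` column.
#' @param threshold Share threshold in (0, 1), default 0.01.
#' @return A list with `posts` (retained) and `removed_accounts` (character).
#' @export
high_volume_account_filter <- function(posts, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) wx_abort("threshold must be in (0,1)")
  if (nrow(posts) == 0L) {
    return(list(posts = posts, removed_accounts = character(0)))
  }
  share <- table(posts$account) / nrow(posts)
  bad <- names(share)[share > threshold]
  list(posts = posts[!posts$account %in% bad, ],
       removed_accounts = sort(bad))
}

#' Remove accounts with a blocked substring in the username
#'
#' @param posts Corpus tibble with a `username` column.
#' @param substring Case-insensitive blocked substring (default "weather").
#' @return A list with `posts` and `removed_accounts`.
#' @export
username_filter <- function(posts, substring = "weather") {
  if (!nzchar(substring)) wx_abort("substring must be non-empty")
  hit <- ci_contains(posts$username, substring)
  list(posts = posts[!hit, ],
       removed_accounts = sort(unique(posts$account[hit])))
}

#' Remove posts containing standalone measurement units
#'
#' Drops posts whose text contains any of `units` (default "mph", "hPa",
#' case-insensitive) not flanked by an alphabetic character on either side:
#' "40mph" counts as standalone (the automated-report format being targeted)
#' while "oomph" and "toothpaste" do not.
#'
#' @param posts Corpus tibble with a `text` column.
#' @param units Character vector of unit strings.
#' @return The retained posts.
#' @export
unit_token_filter <- function(posts, units = c("mph", "hPa")) {
  pat <- paste0("(?<!\\p{L})(", paste0("\\Q", units, "\\E", collapse = "|"),
                ")(?!\\p{L})")
  hit <- stringi::stri_detect_regex(posts$text, pat, case_insensitive = TRUE)
  hit[is.na(hit)] <- FALSE
  posts[!hit, ]
}

#' Remove posts containing a blocked phrase
#'
#' Case-insensitive literal substring match, default the idiom
#' "under the weather".
#'
#' @param posts Corpus tibble with a `text` column.
#' @param phrase Non-empty blocked phrase.
#' @return The retained posts.
#' @export
phrase_filter <- function(posts, phrase = "under the weather") {
  if (!nzchar(phrase)) wx_abort("phrase must be non-empty")
  posts[!ci_contains(posts$text, phrase), ]
}

#' Run the five-stage filtering cascade
#'
#' Stages in order: thematic term, high-volume accounts, username block,
#' standalone units, blocked phrase. The high-volume share is computed on the
#' thematically filtered corpus, so stage order matters. The pipeline is
#' idempotent: re-running it on its own output removes nothing.
#'
#' @param posts Corpus tibble (`id`, `account`, `username`, `text`, ...).
#' @param term Thematic term.
#' @param threshold High-volume account share threshold.
#' @param username_block Blocked username substring.
#' @param units Standalone unit strings.
#' @param phrase Blocked phrase.
#' @return A list with `posts` (the surviving corpus) and `report`, a
#'   `filter_report` tibble chaining input/output counts per stage with the
#'   accounts removed at account-level stages.
#' @export
run_filter_pipeline <- function(posts, term = "weather", threshold = 0.01,
                                username_block = "weather",
                                units = c("mph", "hPa"),
                                phrase = "under the weather") {
  stages <- c("thematic", "high_volume", "username", "unit_token", "phrase")
  input <- integer(5); output <- integer(5)
  removed <- list(character(0), character(0), character(0),
                  character(0), character(0))

  input[1] <- nrow(posts)
  posts <- thematic_filter(posts, term)
  output[1] <- nrow(posts)

  input[2] <- nrow(posts)
  hv <- high_volume_account_filter(posts, threshold)
  posts <- hv$posts; removed[[2]] <- hv$removed_accounts
  output[2] <- nrow(posts)

  input[3] <- nrow(posts)
  un <- username_filter(posts, username_block)
  posts <- un$posts; removed[[3]] <- un$removed_accounts
  output[3] <- nrow(posts)

  input[4] <- nrow(posts)
  posts <- unit_token_filter(posts, units)
  output[4] <- nrow(posts)

  input[5] <- nrow(posts)
  posts <- phrase_filter(posts, phrase)
  output[5] <- nrow(posts)

  report <- tibble::tibble(stage = stages, input_count = input,
                           output_count = output,
                           removed_accounts = removed)
  class(report) <- c("filter_report", class(report))
  list(posts = posts, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  df <- as.data.frame(x[, c("stage", "input_count", "output_count")])
  df$removed <- df$input_count - df$output_count
  df$removed_accounts <- vapply(x$removed_accounts, length, integer(1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a filter report as JSON
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report_json <- function(report, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(report)), function(i) {
      list(stage = report$stage[i],
           input_count = report$input_count[i],
           output_count = report$output_count[i],
           removed_accounts = report$removed_accounts[[i]])
    }),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
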