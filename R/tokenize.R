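# Tokenization shared by lexicon induction and scoring.

.emoji_regex <- paste0(
  "[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}",
  "\\x{2190}-\\x{21FF}\\x{2B50}\\x{2728}]",
  "[\\x{FE0F}\\x{1F3FB}-\\x{1F3FF}]?")

#' Tokenize text into lowercased word and emoji tokens
#'
#' URLs and @-mentions are dropped, emojis are emitted as single tokens
#' (variation selectors and skin-tone modifiers stay attached), punctuation is
#' stripped except apostrophes inside words, and word tokens are lowercased.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input element (a single
#'   string still yields a one-element list).
#' @examples
#' tokenize("Lovely weather ☀️!")
#' @export
tokenize <- function(text) {
  lapply(tokenize_detail(text), `[[`, "tokens")
}

#' Tokenize with modifier-relevant detail
#'
#' Like [tokenize()] but also reports, per token, whether the original token
#' was written in all capitals (two or more letters), and the number of
#' exclamation marks in the text (used by the scorer's emphasis modifiers).
#'
#' @param text Character vector.
#' @return A list with one element per input: `tokens` (character),
#'   `allcaps` (logical, parallel to `tokens`) and `n_excl` (integer).
#' @export
tokenize_detail <- function(text) {
  text <- as.character(text)
  n_excl <- stringi::stri_count_fixed(text, "!")
  x <- stringi::stri_replace_all_regex(text, "(?i)\\bhttps?://\\S+|\\bwww\\.\\S+", " ")
  x <- stringi::stri_replace_all_regex(x, "@\\w+", " ")
  x <- stringi::stri_replace_all_fixed(x, "’", "'")
  # isolate emoji tokens
  x <- stringi::stri_replace_all_regex(x, paste0("(", .emoji_regex, ")"), " $1 ")
  # everything that is not a letter, digit, apostrophe, whitespace or emoji
  # becomes a separator
  x <- stringi::stri_replace_all_regex(
    x, paste0("[^\\p{L}\\p{N}'\\s\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}",
              "\\x{2B00}-\\x{2BFF}\\x{2190}-\\x{21FF}\\x{FE0F}]"), " ")
  toks <- stringi::stri_split_regex(x, "\\s+", omit_empty = TRUE)
  lapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    if (length(tk) == 0L) {
      return(list(tokens = character(0), allcaps = logical(0),
                  n_excl = as.integer(n_excl[i])))
    }
    tk <- stringi::stri_replace_all_regex(tk, "^'+|'+$", "")
    keep <- nzchar(tk)
    tk <- tk[keep]
    allcaps <- stringi::stri_detect_regex(tk, "^[[:upper:]]{2,}$")
    list(tokens = stringi::stri_trans_tolower(tk),
         allcaps = allcaps,
         n_excl = as.integer(n_excl[i]))
  })
}
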