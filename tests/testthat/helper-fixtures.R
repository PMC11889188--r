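# Shared fixtures: a small two-region study, corpus builders, and a manual
# association-graph constructor for propagation oracles.

fixture_conditions <- function() weather_conditions()

fixture_regions <- function(scale_north = 1.5, scale_south = 1) {
  mu_n <- c(temperature = 8, precipitation = 4, humidity = 85, wind = 6,
            pressure = 1008)
  sd_n <- c(temperature = 4.5, precipitation = 4, humidity = 8, wind = 3,
            pressure = 9)
  mu_s <- c(temperature = 13, precipitation = 2.5, humidity = 75, wind = 4,
            pressure = 1014)
  sd_s <- c(temperature = 6, precipitation = 3, humidity = 10, wind = 2.5,
            pressure = 7)
  list(region_spec("north", 1:4, mu_n, sd_n, sentiment_scale = scale_north),
       region_spec("south", 5:8, mu_s, sd_s, sentiment_scale = scale_south))
}

fixture_grid <- function() make_grid(4, 2)

fixture_study <- function(n_posts = 2000, seed = 101, n_days = 365,
                          contamination = contamination_spec()) {
  regions <- fixture_regions()
  grid <- fixture_grid()
  field <- generate_weather(grid, regions, n_days = n_days, seed = seed)
  truth <- synthetic_truth()
  corpus <- generate_corpus(field, regions, truth, contamination,
                            n_posts = n_posts, seed = seed + 1)
  list(grid = grid, regions = regions, field = field, truth = truth,
       corpus = corpus, clim = climatology_from_regions(regions))
}

# minimal corpus tibble from raw text (ids/accounts autogenerated)
posts_from_text <- function(text, username = NULL, account = NULL) {
  n <- length(text)
  tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    account = account %||% sprintf("a%03d", seq_len(n)),
    username = username %||% sprintf("u%03d", seq_len(n)),
    date = as.Date("2021-06-01") + seq_len(n) %% 28,
    lon = -5.5, lat = 50.25, polygon = NA_character_,
    text = text)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built association graph from a symmetric weight matrix
manual_graph <- function(W, vocab = NULL) {
  vocab <- vocab %||% letters[seq_len(nrow(W))]
  structure(list(
    vocabulary = tibble::tibble(token = vocab, count = rep(10L, nrow(W))),
    weights = Matrix::Matrix(W, sparse = TRUE),
    params = list(window = Inf, min_count = 1L, rank = NA, k = NA, cds = 1)),
    class = "assoc_graph")
}

# independent oracle: direct linear solve of the random-walk fixed point
rwr_solve <- function(W, e, restart) {
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  solve(diag(nrow(W)) - (1 - restart) * t(P), restart * e)
}

# brute-force scoring without modifiers: plain lexicon sum + normalization
brute_score <- function(tokens, lexicon, alpha = 15) {
  v <- sum(lexicon$valence[match(tokens, lexicon$token)], na.rm = TRUE)
  v / sqrt(v^2 + alpha)
}
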