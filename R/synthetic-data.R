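# Synthetic study generator: gridded AR(1) weather with region-specific
# climatological baselines, and a contaminated multi-region post corpus with
# known token loadings and a known latent mood response. Every downstream
# stage (filtering, climatology joins, lexicon induction, scoring, response
# curves) can be validated against the generator's truth tables.

#' The generator's fixed vocabulary
#'
#' A fixed wordlist shipped with the package: 500 neutral filler tokens, 60
#' loaded tokens per scale (five weather-severity scales plus sentiment,
#' ordered within each scale from the low extreme to the high extreme) and
#' 10 emojis.
#'
#' @return A tibble with columns `token` and `scale`.
#' @export
default_wordlist <- function() {
  path <- system.file("extdata", "wordlist.tsv", package = "weatherlex")
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Default latent mood response to a weather anomaly
#'
#' A piecewise-linear response of latent mood to the condition z-score:
#' flat at -0.3 below z = -2, rising linearly to a peak of +0.3 at z = 1.5,
#' falling to -0.2 at z = 3 and flat beyond; constant outside `[-4, 4]`.
#' This is the familiar "pleasant up to moderately unusual warmth, unpleasant
#' at the extremes" shape. By default only temperature carries a response.
#'
#' @return A named list of functions, one per condition.
#' @export
default_response_curves <- function() {
  f_temp <- approxfun(c(-4, -2, 1.5, 3, 4), c(-0.3, -0.3, 0.3, -0.2, -0.2),
                      rule = 2)
  zero <- function(z) rep(0, length(z))
  list(temperature = f_temp, precipitation = zero, humidity = zero,
       wind = zero, pressure = zero)
}

#' Region specification for the synthetic study
#'
#' A region owns a disjoint set of grid cells and a per-condition
#' climatological baseline: mean `mu` and standard deviation `sigma` (units:
#' temperature deg C, precipitation mm, humidity %, wind m/s, pressure hPa).
#' `sentiment_scale` multiplies the intensity of expressed mood in the
#' region's posts (regional "expressiveness").
#'
#' @param name Region label.
#' @param cells Integer vector of grid-cell ids (non-empty, disjoint across
#'   regions).
#' @param mu,sigma Named numeric vectors over [weather_conditions()];
#'   `sigma` must be strictly positive.
#' @param sentiment_scale Positive multiplier on expressed mood intensity.
#' @return A `region_spec` object.
#' @export
region_spec <- function(name, cells, mu, sigma, sentiment_scale = 1) {
  conds <- weather_conditions()
  if (length(cells) < 1L) wx_abort("region must own at least one cell")
  if (!all(conds %in% names(mu)) || !all(conds %in% names(sigma))) {
    wx_abort("mu and sigma must be named over all five conditions")
  }
  mu <- mu[conds]; sigma <- sigma[conds]
  if (any(!is.finite(mu)) || any(!is.finite(sigma))) {
    wx_abort("mu/sigma must be finite")
  }
  if (any(sigma <= 0)) wx_abort("sigma must be strictly positive")
  if (sentiment_scale <= 0) wx_abort("sentiment_scale must be positive")
  structure(list(name = name, cells = as.integer(cells), mu = mu,
                 sigma = sigma, sentiment_scale = sentiment_scale),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>", x$name, "-", length(x$cells), "cells, sentiment_scale",
      x$sentiment_scale, "\n")
  print(rbind(mu = x$mu, sigma = x$sigma))
  invisible(x)
}

check_regions <- function(regions) {
  if (length(regions) == 0L) wx_abort("empty region list")
  stopifnot(all(vapply(regions, inherits, logical(1), "region_spec")))
  cells <- unlist(lapply(regions, `[[`, "cells"))
  if (anyDuplicated(cells)) wx_abort("region cells must be disjoint")
  invisible(cells)
}

#' Ground-truth generative parameters for a synthetic corpus
#'
#' Token emission follows `P(w) propto exp(lambda_w * z_cond(w) + s_w * m)`
#' where `z` is the post's condition z-score under the generating climatology
#' and `m` the post's latent mood. By default each loaded scale's 60 tokens
#' get loadings evenly spaced over `loading_range` following the wordlist
#' order (low extreme to high extreme); the 10 emojis get sentiment loadings
#' at the extremes.
#'
#' @param wordlist Tibble from [default_wordlist()] (token, scale).
#' @param loading_range Range of severity loadings `lambda` (and sentiment
#'   loadings `s`), low to high.
#' @param response_curves Named list of per-condition mood response functions
#'   defined on z in `[-4, 4]`, as from [default_response_curves()].
#' @param noise_sd Standard deviation of the mood noise added to the response.
#' @return A `synthetic_truth` object with tibbles `severity_loading`
#'   (token, condition, lambda) and `sentiment_loading` (token, s).
#' @export
synthetic_truth <- function(wordlist = default_wordlist(),
                            loading_range = c(-2, 2),
                            response_curves = default_response_curves(),
                            noise_sd = 0.15) {
  conds <- weather_conditions()
  sev <- dplyr::bind_rows(lapply(conds, function(cn) {
    tok <- wordlist$token[wordlist$scale == cn]
    if (length(tok) == 0L) return(NULL)
    tibble::tibble(token = tok, condition = cn,
                   lambda = seq(loading_range[1], loading_range[2],
                                length.out = length(tok)))
  }))
  sent_tok <- wordlist$token[wordlist$scale == "sentiment"]
  emo_tok <- wordlist$token[wordlist$scale == "emoji"]
  sent <- tibble::tibble(
    token = c(sent_tok, emo_tok),
    s = c(seq(loading_range[1], loading_range[2], length.out = length(sent_tok)),
          # first half of the emoji block is negative, second half positive
          rep(c(loading_range[1], loading_range[2]),
              times = c(ceiling(length(emo_tok) / 2),
                        floor(length(emo_tok) / 2)))))
  if (any(!is.finite(sev$lambda)) || any(!is.finite(sent$s))) {
    wx_abort("loadings must be finite")
  }
  structure(list(vocabulary = wordlist, severity_loading = sev,
                 sentiment_loading = sent, response_curves = response_curves,
                 noise_sd = noise_sd),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", nrow(x$vocabulary), "tokens;",
      nrow(x$severity_loading), "severity loadings;",
      nrow(x$sentiment_loading), "sentiment loadings; noise_sd",
      x$noise_sd, "\n")
  invisible(x)
}

#' Contamination plan for a synthetic corpus
#'
#' Controls the injected junk that the filtering cascade must remove: bot
#' accounts posting automated updates, station accounts with "weather" in the
#' username, unit-formatted automated posts (standalone "mph"/"hPa") and
#' idiomatic posts ("under the weather").
#'
#' Deterministic accounting (ceiling rounding so any nonzero fraction yields
#' at least one instance): the number of bot accounts is
#' `ceiling(bot_fraction / bot_account_share)` and each emits
#' `ceiling(bot_account_share * n_posts)` posts; each station account emits
#' `station_post_count` posts; unit and idiom posts number
#' `ceiling(fraction * n_posts)` each.
#'
#' @param bot_fraction Fraction of the clean post count emitted by bot
#'   accounts in total.
#' @param bot_account_share Fraction of the clean post count that one bot
#'   account emits (drives the high-volume filter).
#' @param station_account_count Number of accounts with "weather" in the
#'   username.
#' @param station_post_count Posts emitted by each station account.
#' @param unit_post_fraction Fraction of posts containing standalone
#'   "mph"/"hPa".
#' @param idiom_fraction Fraction of posts containing "under the weather".
#' @return A `contamination_spec` object.
#' @export
contamination_spec <- function(bot_fraction = 0, bot_account_share = 0.02,
                               station_account_count = 0L,
                               station_post_count = 10L,
                               unit_post_fraction = 0,
                               idiom_fraction = 0) {
  fr <- c(bot_fraction, bot_account_share, unit_post_fraction, idiom_fraction)
  if (any(fr < 0) || any(fr > 1)) wx_abort("fractions must lie in [0, 1]")
  if (station_account_count < 0 || station_post_count < 1) {
    wx_abort("station counts must be non-negative / positive")
  }
  structure(list(bot_fraction = bot_fraction,
                 bot_account_share = bot_account_share,
                 station_account_count = as.integer(station_account_count),
                 station_post_count = as.integer(station_post_count),
                 unit_post_fraction = unit_post_fraction,
                 idiom_fraction = idiom_fraction),
            class = "contamination_spec")
}

#' Expected contaminant counts for a corpus size
#'
#' The exact deterministic accounting used by [generate_corpus()]; filter
#' tests compare [run_filter_pipeline()] reports against these numbers.
#'
#' @param spec A [contamination_spec()].
#' @param n_posts Number of clean posts requested.
#' @return A tibble with columns `class`, `n_accounts`, `n_posts`.
#' @export
contamination_counts <- function(spec, n_posts) {
  n_bot_accounts <- if (spec$bot_fraction > 0) {
    as.integer(ceiling(spec$bot_fraction / spec$bot_account_share))
  } else 0L
  posts_per_bot <- if (n_bot_accounts > 0) {
    as.integer(ceiling(spec$bot_account_share * n_posts))
  } else 0L
  tibble::tibble(
    class = c("bot", "station", "unit", "idiom"),
    n_accounts = c(n_bot_accounts, spec$station_account_count,
                   as.integer(ceiling(spec$unit_post_fraction * n_posts)),
                   as.integer(ceiling(spec$idiom_fraction * n_posts))),
    n_posts = c(n_bot_accounts * posts_per_bot,
                spec$station_account_count * spec$station_post_count,
                as.integer(ceiling(spec$unit_post_fraction * n_posts)),
                as.integer(ceiling(spec$idiom_fraction * n_posts))))
}

#' Build a regular lon/lat grid
#'
#' @param nx,ny Grid dimensions.
#' @param lon0,lat0 Coordinates of the first (south-west) node.
#' @param spacing Node spacing in degrees.
#' @return A tibble with `cell_id`, `lon`, `lat` (row-major, west to east
#'   then south to north), plus a `spacing` attribute.
#' @export
make_grid <- function(nx, ny, lon0 = -6, lat0 = 50, spacing = 0.25) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  g <- tibble::tibble(
    cell_id = seq_len(nx * ny),
    lon = rep(lon0 + (seq_len(nx) - 1) * spacing, times = ny),
    lat = rep(lat0 + (seq_len(ny) - 1) * spacing, each = nx))
  attr(g, "spacing") <- spacing
  g
}

#' Generate a gridded daily weather field
#'
#' Each (cell, condition) series is a stationary AR(1) process around the
#' owning region's climatological mean `mu` with stationary standard
#' deviation `sigma`: day-to-day weather persists (default autoregressive
#' coefficient 0.7) but the long-run mean and spread match the region's
#' baseline.
#'
#' @param grid Grid tibble from [make_grid()].
#' @param regions List of [region_spec()] objects covering (a subset of) the
#'   grid cells.
#' @param n_days Number of days (>= 1).
#' @param seed Integer seed; the field is deterministic given the seed.
#' @param start_date First day of the series.
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param missing_rate Fraction of values set missing at random (default 0).
#' @return A `weather_field` object: grid, dates, conditions and a 3-d value
#'   array `[cell, day, condition]` over the cells owned by the regions.
#' @export
generate_weather <- function(grid, regions, n_days, seed,
                             start_date = as.Date("2011-01-01"),
                             ar_coef = 0.7, missing_rate = 0) {
  check_regions(regions)
  if (n_days < 1) wx_abort("n_days must be >= 1")
  if (ar_coef < 0 || ar_coef >= 1) wx_abort("ar_coef must be in [0, 1)")
  cells <- sort(unlist(lapply(regions, `[[`, "cells")))
  if (!all(cells %in% grid$cell_id)) {
    wx_abort("regions reference cells outside the grid")
  }
  conds <- weather_conditions()
  set.seed(as.integer(seed))
  vals <- array(NA_real_, dim = c(length(cells), n_days, length(conds)),
                dimnames = list(cell = cells, day = NULL, condition = conds))
  for (r in regions) {
    for (cn in conds) {
      mu <- r$mu[[cn]]; sg <- r$sigma[[cn]]
      eps_sd <- sg * sqrt(1 - ar_coef^2)
      for (cell in r$cells) {
        i <- match(cell, cells)
        x0 <- rnorm(1, 0, sg)
        eps <- rnorm(n_days, 0, eps_sd)
        x <- as.numeric(stats::filter(eps, ar_coef, method = "recursive",
                                      init = x0))
        vals[i, , match(cn, conds)] <- mu + x
      }
    }
  }
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(vals)) < missing_rate)
    vals[drop] <- NA_real_
  }
  region_of_cell <- setNames(
    rep(vapply(regions, `[[`, character(1), "name"),
        vapply(regions, function(r) length(r$cells), integer(1))),
    unlist(lapply(regions, `[[`, "cells")))
  structure(list(grid = grid[match(cells, grid$cell_id), ],
                 spacing = attr(grid, "spacing") %||% NA_real_,
                 dates = start_date + 0:(n_days - 1),
                 conditions = conds,
                 values = vals,
                 region = region_of_cell[as.character(cells)]),
            class = "weather_field")
}

#' @export
print.weather_field <- function(x, ...) {
  cat("<weather_field>", nrow(x$grid), "cells x", length(x$dates), "days x",
      length(x$conditions), "conditions (",
      format(min(x$dates)), "to", format(max(x$dates)), ")\n")
  invisible(x)
}

# z-scores of field values against the generating (region) climatology
field_truth_z <- function(field, regions) {
  conds <- weather_conditions()
  z <- field$values
  for (r in regions) {
    idx <- match(r$cells, as.integer(dimnames(field$values)$cell))
    for (k in seq_along(conds)) {
      z[idx, , k] <- (field$values[idx, , k] - r$mu[[conds[k]]]) /
        r$sigma[[conds[k]]]
    }
  }
  z
}

#' Generate a contaminated multi-region post corpus with known truth
#'
#' Clean posts draw a uniform cell and date, compute condition z-scores under
#' the generating climatology, set latent mood
#' `m = sentiment_scale * (sum_c f_c(z_c) + noise)` and emit tokens with
#' probability proportional to `exp(lambda_w * z + s_w * m)`. Every clean
#' post contains the literal token "weather" so the thematic filter is
#' non-destructive on clean content. Contaminants (bots, station accounts,
#' unit posts, idiom posts) are appended per the [contamination_spec()]
#' accounting and each is caught by exactly one later filter stage.
#'
#' @param field A [generate_weather()] field.
#' @param regions The region list used to generate `field`.
#' @param truth A [synthetic_truth()].
#' @param contamination A [contamination_spec()].
#' @param n_posts Number of clean posts (>= 1).
#' @param seed Integer seed; byte-identical output for identical inputs.
#' @param tokens_mean Mean of the truncated Poisson post length.
#' @param tokens_min Minimum tokens per post (Poisson draws below this are
#'   redrawn).
#' @param n_accounts Size of the clean-account pool; clean posts are assigned
#'   round-robin so no clean account can cross the high-volume threshold.
#' @return A `synthetic_corpus`: list with `posts` (tibble: id, account,
#'   username, date, lon, lat, polygon, text), `truth_posts` (tibble: id,
#'   class, region, cell_id, date, z_* per condition, m) and the input specs.
#' @export
generate_corpus <- function(field, regions, truth,
                            contamination = contamination_spec(),
                            n_posts, seed, tokens_mean = 12, tokens_min = 3,
                            n_accounts = 200L) {
  check_regions(regions)
  if (n_posts < 1) wx_abort("n_posts must be >= 1")
  if (nrow(truth$vocabulary) == 0L) wx_abort("truth vocabulary is empty")
  cc <- contamination_counts(contamination, n_posts)
  if (sum(cc$n_posts[cc$class %in% c("unit", "idiom")]) +
      ceiling(contamination$bot_fraction * n_posts) > n_posts) {
    wx_abort("contamination fractions sum above 1")
  }
  conds <- weather_conditions()
  cells <- as.integer(dimnames(field$values)$cell)
  region_names <- vapply(regions, `[[`, character(1), "name")
  cell_region <- field$region
  scale_of <- setNames(vapply(regions, `[[`, numeric(1), "sentiment_scale"),
                       region_names)

  set.seed(as.integer(seed))

  # vocabulary and loading vectors
  vocab <- truth$vocabulary$token
  V <- length(vocab)
  lam <- matrix(0, V, length(conds), dimnames = list(vocab, conds))
  sev <- truth$severity_loading
  lam[cbind(match(sev$token, vocab), match(sev$condition, conds))] <- sev$lambda
  svec <- setNames(numeric(V), vocab)
  svec[truth$sentiment_loading$token] <- truth$sentiment_loading$s

  # clean posts -------------------------------------------------------------
  cell_idx <- sample.int(length(cells), n_posts, replace = TRUE)
  day_idx <- sample.int(length(field$dates), n_posts, replace = TRUE)
  ztruth <- field_truth_z(field, regions)
  zmat <- matrix(NA_real_, n_posts, length(conds),
                 dimnames = list(NULL, conds))
  for (k in seq_along(conds)) {
    zmat[, k] <- ztruth[cbind(cell_idx, day_idx, k)]
  }
  reg <- cell_region[cell_idx]
  fsum <- rowSums(vapply(conds, function(cn) {
    truth$response_curves[[cn]](zmat[, cn])
  }, numeric(n_posts)))
  m <- scale_of[reg] * (fsum + rnorm(n_posts, 0, truth$noise_sd))

  len <- rpois(n_posts, tokens_mean)
  while (any(len < tokens_min)) {
    i <- len < tokens_min
    len[i] <- rpois(sum(i), tokens_mean)
  }

  texts <- character(n_posts)
  chunk <- 5000L
  for (lo in seq(1L, n_posts, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_posts)
    idx <- lo:hi
    logits <- lam %*% t(zmat[idx, , drop = FALSE]) +
      outer(svec, m[idx])                     # V x chunk
    logits <- sweep(logits, 2, apply(logits, 2, max))
    p <- exp(logits)
    p <- sweep(p, 2, colSums(p), "/")
    texts[idx] <- vapply(seq_along(idx), function(j) {
      tk <- vocab[sample.int(V, len[idx[j]], replace = TRUE, prob = p[, j])]
      paste(sample(c(tk, "weather")), collapse = " ")
    }, character(1))
  }

  grid_lookup <- field$grid
  clean <- tibble::tibble(
    id = sprintf("p%07d", seq_len(n_posts)),
    account = sprintf("acct%04d", ((seq_len(n_posts) - 1L) %% n_accounts) + 1L),
    username = sprintf("user%04d", ((seq_len(n_posts) - 1L) %% n_accounts) + 1L),
    date = field$dates[day_idx],
    lon = grid_lookup$lon[cell_idx],
    lat = grid_lookup$lat[cell_idx],
    polygon = NA_character_,
    text = texts)
  truth_clean <- tibble::tibble(
    id = clean$id, class = "clean", region = unname(reg),
    cell_id = cells[cell_idx], date = clean$date,
    m = unname(m))
  for (k in seq_along(conds)) {
    truth_clean[[paste0("z_", conds[k])]] <- zmat[, k]
  }

  # contaminants ------------------------------------------------------------
  contam <- list()
  next_id <- n_posts
  add_posts <- function(n, account, username, text_fun, class) {
    if (n == 0L) return(NULL)
    ci <- sample.int(length(cells), n, replace = TRUE)
    di <- sample.int(length(field$dates), n, replace = TRUE)
    ids <- sprintf("p%07d", next_id + seq_len(n))
    next_id <<- next_id + n
    list(posts = tibble::tibble(
      id = ids, account = account, username = username,
      date = field$dates[di],
      lon = grid_lookup$lon[ci], lat = grid_lookup$lat[ci],
      polygon = NA_character_,
      text = text_fun(n)),
      truth = tibble::tibble(id = ids, class = class,
                             region = unname(cell_region[ci]),
                             cell_id = cells[ci],
                             date = field$dates[di], m = NA_real_))
  }

  n_bot_accounts <- cc$n_accounts[cc$class == "bot"]
  posts_per_bot <- if (n_bot_accounts > 0) {
    as.integer(ceiling(contamination$bot_account_share * n_posts))
  } else 0L
  for (b in seq_len(n_bot_accounts)) {
    contam[[length(contam) + 1L]] <- add_posts(
      posts_per_bot,
      account = sprintf("bot%02d", b),
      username = sprintf("AutoUpdates%02d", b),
      text_fun = function(n) sprintf(
        "weather update %02d00 temp %d pressure reading normal",
        sample.int(23, n, replace = TRUE), sample.int(30, n, replace = TRUE)),
      class = "bot")
  }
  for (s in seq_len(contamination$station_account_count)) {
    contam[[length(contam) + 1L]] <- add_posts(
      contamination$station_post_count,
      account = sprintf("station%02d", s),
      username = sprintf("TownWeather%02d", s),
      text_fun = function(n) sprintf(
        "weather report issued %02d00 for the local area",
        sample.int(23, n, replace = TRUE)),
      class = "station")
  }
  n_unit <- cc$n_posts[cc$class == "unit"]
  if (n_unit > 0) {
    contam[[length(contam) + 1L]] <- add_posts(
      n_unit,
      account = sprintf("unituser%04d", seq_len(n_unit)),
      username = sprintf("casual%04d", seq_len(n_unit)),
      text_fun = function(n) sprintf(
        "weather now wind %d mph pressure %d hPa",
        sample.int(60, n, replace = TRUE),
        980L + sample.int(60, n, replace = TRUE)),
      class = "unit")
  }
  n_idiom <- cc$n_posts[cc$class == "idiom"]
  if (n_idiom > 0) {
    contam[[length(contam) + 1L]] <- add_posts(
      n_idiom,
      account = sprintf("idiomuser%04d", seq_len(n_idiom)),
      username = sprintf("person%04d", seq_len(n_idiom)),
      text_fun = function(n) rep("feeling a bit under the weather today", n),
      class = "idiom")
  }

  posts <- dplyr::bind_rows(c(list(clean), lapply(contam, `[[`, "posts")))
  truth_posts <- dplyr::bind_rows(c(list(truth_clean),
                                    lapply(contam, `[[`, "truth")))
  ord <- sample.int(nrow(posts))
  structure(list(posts = posts[ord, ],
                 truth_posts = truth_posts[ord, ],
                 truth = truth, contamination = contamination,
                 expected_contamination = cc,
                 regions = regions, seed = as.integer(seed)),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  tab <- table(x$truth_posts$class)
  cat("<synthetic_corpus>", nrow(x$posts), "posts (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}
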