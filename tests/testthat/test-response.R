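scored_fixture <- function(n_posts = 1500, seed = 71) {
  st <- fixture_study(n_posts = n_posts, seed = seed)
  ann <- annotate_corpus(st$corpus$posts, st$field, st$clim)
  tr <- st$corpus$truth_posts
  ann$region <- tr$region[match(ann$id, tr$id)]
  lex <- token_lexicon(
    tibble::tibble(token = st$truth$sentiment_loading$token,
                   valence = pmin(1, pmax(-1,
                     st$truth$sentiment_loading$s / 2))),
    scale_name = "sentiment")
  list(posts = score_corpus(ann, lex), st = st)
}

test_that("binned curves equal hand-computed two-bin means", {
  posts <- posts_from_text(rep("x", 4))
  posts$z_temperature <- c(-1, -0.5, 0.5, 1)
  posts$score_sentiment <- c(1, 1, -1, -1)
  curve <- binned_response(posts, "temperature", "zscore", n_bins = 2,
                           min_fraction = 0)
  expect_equal(curve$bin_mean, c(1, -1))
  expect_equal(curve$bin_count, c(2L, 2L))
})

test_that("bin inclusion uses the at-least rule at the boundary", {
  posts <- posts_from_text(rep("x", 1000))
  posts$z_wind <- c(rep(0.5, 999), 5)     # one post isolated in the top bin
  posts$score_sentiment <- 0
  curve <- binned_response(posts, "wind", "zscore", n_bins = 30,
                           min_fraction = 0.001)
  expect_true(curve$included[curve$bin_count == 1])   # 1 >= 0.001 * 1000
  curve2 <- binned_response(posts, "wind", "zscore", n_bins = 30,
                            min_fraction = 0.0011)
  expect_false(curve2$included[curve2$bin_count == 1])
})

test_that("binned means match a brute-force group-by to 1e-12", {
  fx <- scored_fixture()
  curve <- binned_response(fx$posts, "temperature", "zscore")
  x <- fx$posts$z_temperature
  y <- fx$posts$score_sentiment
  edges <- attr(curve, "edges")
  idx <- as.integer(cut(x, edges, include.lowest = TRUE))
  brute <- tapply(y, idx, mean)
  got <- curve$bin_mean[as.integer(names(brute))]
  expect_equal(as.numeric(got), as.numeric(brute), tolerance = 1e-12)
  expect_equal(sum(curve$bin_count), length(x))
})

test_that("degenerate condition values produce a single warned bin", {
  posts <- posts_from_text(rep("x", 10))
  posts$z_pressure <- 1
  posts$score_sentiment <- seq(0, 0.9, 0.1)
  expect_warning(curve <- binned_response(posts, "pressure", "zscore"),
                 "identical")
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$bin_mean, mean(posts$score_sentiment))
})

test_that("group z-scores use the n-1 divisor and are shift-invariant", {
  posts <- posts_from_text(rep("x", 4))
  posts$region <- c("a", "a", "b", "b")
  posts$score_sentiment <- c(0, 1, 5, 7)
  z <- zscore_scores(posts, "region")
  expect_equal(z$score_z[1:2], c(-1, 1) / sqrt(2))
  shifted <- posts
  shifted$score_sentiment <- shifted$score_sentiment + 0.2
  expect_equal(zscore_scores(shifted, "region")$score_z, z$score_z,
               tolerance = 1e-12)
})

test_that("z-scored scores have unit spread within each region", {
  fx <- scored_fixture()
  z <- zscore_scores(fx$posts, "region")
  for (r in c("north", "south")) {
    expect_equal(sd(z$score_z[z$region == r]), 1, tolerance = 1e-12)
    expect_lt(abs(mean(z$score_z[z$region == r])), 1e-12)
  }
})

test_that("zero-spread groups are flagged and scored missing", {
  posts <- posts_from_text(rep("x", 3))
  posts$region <- c("a", "a", "b")
  posts$score_sentiment <- c(0.5, 0.5, 0.1)
  expect_warning(z <- zscore_scores(posts, "region"), "spread")
  expect_true(all(is.na(z$score_z)))
})

test_that("pair grids apply the minimum-count rule exactly", {
  posts <- posts_from_text(rep("x", 9))
  posts$z_temperature <- c(rep(0.1, 4), rep(2, 5))
  posts$z_humidity <- c(rep(0.1, 4), rep(2, 5))
  posts$score_sentiment <- c(rep(0.4, 4), rep(-0.2, 5))
  pg <- pair_grid(posts, "temperature", "humidity", gridsize = 2,
                  min_count = 5)
  expect_equal(nrow(pg), 2L)
  expect_equal(pg$included, c(FALSE, TRUE))   # 4 < 5 excluded, 5 >= 5 kept
  expect_equal(pg$mean_score[pg$included], -0.2)
})

test_that("pair-grid means match a brute-force group-by", {
  fx <- scored_fixture()
  pg <- pair_grid(fx$posts, "temperature", "humidity", gridsize = 10)
  total <- sum(pg$count)
  expect_equal(total, sum(!is.na(fx$posts$z_temperature) &
                            !is.na(fx$posts$z_humidity)))
  # recompute one populated cell by hand
  cell <- pg[which.max(pg$count), ]
  zx <- fx$posts$z_temperature; zy <- fx$posts$z_humidity
  ex <- seq(min(zx), max(zx), length.out = 11)
  ey <- seq(min(zy), max(zy), length.out = 11)
  ix <- as.integer(cut(zx, ex, include.lowest = TRUE))
  iy <- as.integer(cut(zy, ey, include.lowest = TRUE))
  sel <- ix == cell$ix & iy == cell$iy
  expect_equal(cell$count, sum(sel))
  expect_equal(cell$mean_score, mean(fx$posts$score_sentiment[sel]),
               tolerance = 1e-12)
})

test_that("a planted interaction shows up in the pair grid", {
  fx <- scored_fixture(n_posts = 4000, seed = 73)
  posts <- fx$posts
  # plant: mood high only when z_temp around 1 and humidity below normal
  boost <- !is.na(posts$z_temperature) & posts$z_temperature > 0.5 &
    posts$z_temperature < 1.5 & posts$z_humidity < 0
  posts$score_sentiment <- posts$score_sentiment * 0.1 + ifelse(boost, 0.8, 0)
  pg <- pair_grid(posts, "temperature", "humidity", gridsize = 8)
  inc <- pg[pg$included, ]
  top <- inc[which.max(inc$mean_score), ]
  expect_gt(top$x_mid, 0.4)
  expect_lt(top$y_mid, 0.2)
})

test_that("word scatter joins lexicons and rejects disjoint ones", {
  s <- token_lexicon(tibble::tibble(token = c("a", "b", "c"),
                                    valence = c(0.5, -0.5, 0.1),
                                    count = c(10L, 10L, 2L)), "sentiment")
  w <- token_lexicon(tibble::tibble(token = c("b", "c", "d"),
                                    valence = c(0.9, -0.2, 0)), "temperature")
  ws <- word_scatter(s, w)
  expect_equal(ws$token, c("b", "c"))
  expect_equal(ws$severity, c(0.9, -0.2))
  expect_equal(ws$sentiment, c(-0.5, 0.1))
  ws2 <- word_scatter(s, w, min_count = 5)
  expect_equal(ws2$token, "b")
  d <- token_lexicon(tibble::tibble(token = "zz", valence = 0), "wind")
  expect_error(word_scatter(s, d), "share no tokens")
})

test_that("severity-vs-sentiment quadrants recover planted signs", {
  st <- fixture_study(n_posts = 8000, seed = 79)
  ann <- annotate_corpus(st$corpus$posts, st$field, st$clim)
  sent <- induce_sentiment_lexicon(ann, min_count = 5)
  wx <- induce_weather_lexicon(ann, "temperature", min_count = 5)
  ws <- word_scatter(sent, wx)
  sev <- st$truth$severity_loading
  sl <- st$truth$sentiment_loading
  hot <- sev$token[sev$condition == "temperature" & sev$lambda > 0.5]
  ws_hot <- ws[ws$token %in% hot, ]
  expect_gt(mean(ws_hot$severity > 0), 0.8)
})

test_that("region assignment follows containment and the overlap rule", {
  a <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  b <- matrix(c(1, 0, 2, 0, 2, 1, 1, 1), ncol = 2, byrow = TRUE)
  c_ <- matrix(c(2, 0, 3, 0, 3, 1, 2, 1), ncol = 2, byrow = TRUE)
  regions <- list(A = a, B = b, C = c_)

  posts <- posts_from_text(rep("x", 4))
  posts$lon <- c(0.5, NA, NA, NA)
  posts$lat <- c(0.5, NA, NA, NA)
  # polygon 49% in A, 51% in B
  posts$polygon <- c(NA,
                     format_wkt(matrix(c(0.51, 0.2, 1.51, 0.2, 1.51, 0.8,
                                         0.51, 0.8), ncol = 2, byrow = TRUE)),
                     # 32% / 40% / 28% across three regions -> unassigned
                     format_wkt(matrix(c(0.2, 0.2, 2.7, 0.2, 2.7, 0.8,
                                         0.2, 0.8), ncol = 2, byrow = TRUE)),
                     # fully inside C
                     format_wkt(matrix(c(2.2, 0.2, 2.8, 0.2, 2.8, 0.8,
                                         2.2, 0.8), ncol = 2, byrow = TRUE)))
  res <- assign_regions(posts, regions)
  expect_equal(res$region, c("A", "B", NA, "C"))
})

test_that("curve correlation behaves at the trivial extremes", {
  posts <- posts_from_text(rep("x", 300))
  set.seed(5)
  posts$z_wind <- rnorm(300)
  posts$score_sentiment <- sin(posts$z_wind)
  edges <- seq(min(posts$z_wind), max(posts$z_wind), length.out = 11)
  c1 <- binned_response(posts, "wind", "zscore", edges = edges,
                        min_fraction = 0)
  expect_equal(curve_correlation(c1, c1)$r, 1)
  c2 <- c1
  c2$bin_mean <- -c2$bin_mean
  expect_equal(curve_correlation(c1, c2)$r, -1)
  c3 <- binned_response(posts, "wind", "zscore", min_fraction = 0)
  expect_error(curve_correlation(c1, c3), "share bin edges")
})
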