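test_that("thematic filter is a case-insensitive substring match", {
  posts <- posts_from_text(c("Lovely WEATHER today", "Lovely day",
                             "whetherby is nice", "wheatherish weather"))
  kept <- thematic_filter(posts, "weather")
  expect_equal(kept$text, c("Lovely WEATHER today", "wheatherish weather"))
  expect_error(thematic_filter(posts, ""), "non-empty")
})

test_that("high-volume filter removes accounts strictly over the threshold", {
  # 100 posts: account A has 2 (2%), account B exactly 1 (1%)
  posts <- posts_from_text(rep("weather", 100),
                           account = c(rep("A", 2), "B",
                                       sprintf("c%02d", 1:97)))
  res <- high_volume_account_filter(posts, threshold = 0.01)
  expect_equal(res$removed_accounts, "A")
  expect_true("B" %in% res$posts$account)
  expect_equal(nrow(res$posts), 98L)
  expect_error(high_volume_account_filter(posts, 0), "threshold")
  expect_error(high_volume_account_filter(posts, 1), "threshold")
})

test_that("share is computed once on the input, not iteratively", {
  # after removing A (12/100), B's share of the remainder would exceed 1%
  # but B's input share is below the threshold, so B stays
  posts <- posts_from_text(rep("weather", 100),
                           account = c(rep("A", 12), rep("B", 1),
                                       sprintf("c%02d", 1:87)))
  res <- high_volume_account_filter(posts, threshold = 0.011)
  expect_equal(res$removed_accounts, "A")
  expect_true(all(res$posts$account != "A"))
})

test_that("username filter matches case-insensitively", {
  posts <- posts_from_text(rep("hi weather", 3),
                           username = c("FavershamWeather", "Wx_Fan",
                                        "WEATHERGUY"))
  res <- username_filter(posts, "weather")
  expect_equal(res$posts$username, "Wx_Fan")
  expect_length(res$removed_accounts, 2L)
})

test_that("unit filter removes standalone mph/hPa but not within words", {
  posts <- posts_from_text(c("Gusts 40mph from the west",
                             "that soup has oomph, great weather",
                             "fresh toothpaste weather vibes",
                             "pressure 1012 hPa steady",
                             "reading HPA documentation weather"))
  kept <- unit_token_filter(posts)
  expect_equal(kept$text[1:2], c("that soup has oomph, great weather",
                                 "fresh toothpaste weather vibes"))
  # "HPA" adjacent to whitespace counts as standalone
  expect_equal(nrow(kept), 2L)
})

test_that("phrase filter removes the idiom case-insensitively", {
  posts <- posts_from_text(c("feeling under the weather today",
                             "under this weather system",
                             "Under The Weather again"))
  kept <- phrase_filter(posts)
  expect_equal(kept$text, "under this weather system")
})

test_that("pipeline chains counts, is idempotent, and is order-sensitive", {
  spec <- contamination_spec(bot_fraction = 0.04, bot_account_share = 0.02,
                             station_account_count = 2,
                             unit_post_fraction = 0.01,
                             idiom_fraction = 0.005)
  st <- fixture_study(n_posts = 2000, seed = 55, contamination = spec)
  cc <- st$corpus$expected_contamination
  res <- run_filter_pipeline(st$corpus$posts)
  rep <- res$report

  # counts chain
  expect_equal(rep$input_count[-1], rep$output_count[-5])
  expect_true(all(rep$output_count <= rep$input_count))
  # per-stage removals match the generator's accounting exactly
  expect_equal(rep$input_count[1] - rep$output_count[1], 0L)
  expect_equal(rep$input_count[2] - rep$output_count[2],
               cc$n_posts[cc$class == "bot"])
  expect_equal(rep$input_count[3] - rep$output_count[3],
               cc$n_posts[cc$class == "station"])
  expect_equal(rep$input_count[4] - rep$output_count[4],
               cc$n_posts[cc$class == "unit"])
  expect_equal(rep$input_count[5] - rep$output_count[5],
               cc$n_posts[cc$class == "idiom"])
  expect_equal(nrow(res$posts), 2000L)

  # idempotence
  res2 <- run_filter_pipeline(res$posts)
  expect_equal(res2$posts$id, res$posts$id)
  expect_true(all(res2$report$input_count == res2$report$output_count))

  # order sensitivity: an account over 1% of the raw corpus but not of the
  # thematic subset survives when the thematic filter runs first
  off_theme <- posts_from_text(rep("sunny out", 60),
                               account = rep("loud", 60))
  on_theme <- posts_from_text(rep("weather chat", 400),
                              account = sprintf("q%03d", 1:400))
  mixed <- dplyr::bind_rows(off_theme, on_theme)
  mixed$id <- sprintf("m%03d", seq_len(nrow(mixed)))
  piped <- run_filter_pipeline(mixed)
  expect_equal(nrow(piped$posts), 400L)  # "loud" removed by theme, not share
  direct <- high_volume_account_filter(mixed, 0.01)
  expect_true("loud" %in% direct$removed_accounts)
})

test_that("a fixture with exactly five over-threshold accounts loses five", {
  spec <- contamination_spec(bot_fraction = 0.1, bot_account_share = 0.02)
  st <- fixture_study(n_posts = 1000, seed = 91, contamination = spec)
  res <- run_filter_pipeline(st$corpus$posts)
  expect_length(res$report$removed_accounts[[2]], 5L)
})

test_that("an empty corpus passes through with zero counts", {
  empty <- posts_from_text(character(0))
  res <- run_filter_pipeline(empty)
  expect_equal(nrow(res$posts), 0L)
  expect_true(all(res$report$input_count == 0L))
  expect_true(all(res$report$output_count == 0L))
})
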