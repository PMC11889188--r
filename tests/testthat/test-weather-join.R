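make_constant_field <- function(value = 10, n_days = 40) {
  regions <- fixture_regions()
  field <- generate_weather(fixture_grid(), regions, n_days = n_days,
                           seed = 1)
  field$values[] <- value
  field
}

test_that("climatology is the sample mean / sd with the n-1 divisor", {
  field <- make_constant_field(10)
  # two-point series {0, 10} on one cell/condition
  field$values["1", , "temperature"] <- rep(c(0, 10), length.out = 40)
  clim <- compute_climatology(field)
  i <- match(1L, clim$cells)
  expect_equal(clim$mu[i, "temperature"], 5)
  expect_equal(clim$sigma[i, "temperature"],
               sd(rep(c(0, 10), length.out = 40)))
  # constant series: sigma 0, degenerate flag
  expect_equal(clim$mu[i, "pressure"], 10)
  expect_equal(clim$sigma[i, "pressure"], 0)
  expect_true(clim$degenerate[i, "pressure"])
})

test_that("climatology recovers the generating parameters on long series", {
  regions <- fixture_regions()
  field <- generate_weather(fixture_grid(), regions, n_days = 3650, seed = 4)
  clim <- compute_climatology(field)
  north <- regions[[1]]
  i <- match(north$cells[1], clim$cells)
  for (cn in fixture_conditions()) {
    k <- match(cn, fixture_conditions())
    se <- north$sigma[[cn]] / sqrt(3650 / 10)  # AR(1) effective n
    expect_lt(abs(clim$mu[i, k] - north$mu[[cn]]), 3 * se)
  }
})

test_that("insufficient data marks cells unusable with a warning", {
  field <- make_constant_field(5, n_days = 10)
  expect_warning(clim <- compute_climatology(field, min_days = 30),
                 "unusable")
  expect_false(any(clim$usable))
})

test_that("condition assignment follows the node-overlap and nearest rules", {
  field <- make_constant_field()
  g <- field$grid
  field$values[1, , "temperature"] <- 10   # cell 1
  field$values[2, , "temperature"] <- 20   # cell 2
  d <- field$dates[3]

  # point exactly on a node takes that node's values
  cv <- assign_conditions(field, d, lon = g$lon[2], lat = g$lat[2])
  expect_equal(cv$raw[["temperature"]], 20)
  expect_equal(cv$mode, "nearest")

  # polygon covering nodes 1 and 2 averages them
  poly <- format_wkt(matrix(c(g$lon[1] - 0.1, g$lat[1] - 0.1,
                              g$lon[2] + 0.1, g$lat[1] - 0.1,
                              g$lon[2] + 0.1, g$lat[1] + 0.1,
                              g$lon[1] - 0.1, g$lat[1] + 0.1),
                            ncol = 2, byrow = TRUE))
  cv2 <- assign_conditions(field, d, polygon = poly)
  expect_equal(sort(cv2$cells), c(1L, 2L))
  expect_equal(cv2$raw[["temperature"]], 15)

  # polygon overlapping no node falls back to the nearest node
  tiny <- format_wkt(matrix(c(g$lon[1] + 0.05, g$lat[1] + 0.05,
                              g$lon[1] + 0.08, g$lat[1] + 0.05,
                              g$lon[1] + 0.08, g$lat[1] + 0.08),
                            ncol = 2, byrow = TRUE))
  cv3 <- assign_conditions(field, d, polygon = tiny)
  expect_equal(cv3$mode, "nearest")
  expect_equal(cv3$cells, 1L)

  expect_error(assign_conditions(field, as.Date("1999-01-01"),
                                 lon = g$lon[1], lat = g$lat[1]), "date")
  expect_error(assign_conditions(field, d, lon = 40, lat = 10), "bounding")
})

test_that("z-scoring is the printed formula with degenerate-sigma handling", {
  clim <- climatology_from_regions(fixture_regions())
  raw <- setNames(c(25, 4, 85, 6, 1008), fixture_conditions())
  i <- match(1L, clim$cells)
  z <- zscore_conditions(raw, clim, cell = 1L)
  expect_equal(z[["temperature"]], (25 - clim$mu[i, 1]) / clim$sigma[i, 1])
  expect_equal(zscore_conditions(clim$mu[i, ], clim, cell = 1L),
               setNames(rep(0, 5), fixture_conditions()))

  clim0 <- clim
  clim0$sigma[i, "wind"] <- 0
  expect_warning(z0 <- zscore_conditions(raw, clim0, cell = 1L), "sigma")
  expect_true(is.na(z0[["wind"]]))
  expect_false(anyNA(z0[setdiff(fixture_conditions(), "wind")]))
})

test_that("z-scores are invariant to translation and positive scaling", {
  regions <- fixture_regions()
  field <- generate_weather(fixture_grid(), regions, n_days = 60, seed = 8)
  clim <- compute_climatology(field)
  raw <- field$values["3", 10, ]
  z1 <- zscore_conditions(raw, clim, cell = 3L)

  shift <- 7; scale <- 2.5
  field2 <- field
  field2$values <- field2$values * scale + shift
  clim2 <- compute_climatology(field2)
  z2 <- zscore_conditions(field2$values["3", 10, ], clim2, cell = 3L)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("reference-window z-scores pool to mean zero and unit sd per cell", {
  regions <- fixture_regions()
  field <- generate_weather(fixture_grid(), regions, n_days = 200, seed = 12)
  clim <- compute_climatology(field)
  for (cell in c("1", "6")) {
    i <- match(as.integer(cell), clim$cells)
    for (k in seq_along(fixture_conditions())) {
      z <- (field$values[cell, , k] - clim$mu[i, k]) / clim$sigma[i, k]
      expect_lt(abs(mean(z)), 1e-9)
      expect_equal(sd(z), 1, tolerance = 1e-12)
    }
  }
})

test_that("annotate_corpus reproduces the generator's internal z exactly", {
  st <- fixture_study(n_posts = 300, seed = 42)
  ann <- annotate_corpus(st$corpus$posts, st$field, st$clim)
  tr <- st$corpus$truth_posts
  m <- dplyr::inner_join(ann[, c("id", "cell_id", paste0("z_",
                                                         fixture_conditions()))],
                         tr[tr$class == "clean", ],
                         by = "id", suffix = c("", ".truth"))
  expect_equal(m$cell_id, m$cell_id.truth)
  for (cn in fixture_conditions()) {
    expect_equal(m[[paste0("z_", cn)]], m[[paste0("z_", cn, ".truth")]],
                 tolerance = 1e-12)
  }
  expect_false(any(ann$weather_missing))
})

test_that("annotate_corpus flags out-of-range posts and keeps going", {
  st <- fixture_study(n_posts = 20, seed = 6)
  posts <- st$corpus$posts
  posts$date[1] <- as.Date("1990-01-01")
  ann <- annotate_corpus(posts, st$field, st$clim)
  expect_equal(sum(!is.na(ann$join_error)), 1L)
  expect_true(ann$weather_missing[!is.na(ann$join_error)][1])
  expect_equal(nrow(ann), 20L)

  empty <- annotate_corpus(posts[0, ], st$field, st$clim)
  expect_equal(nrow(empty), 0L)
})
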