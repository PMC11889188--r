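# Exposure-response analysis: binned sentiment-vs-condition curves, pairwise
# condition grids, word-level scatters, regional assignment and curve
# correlations.

score_values <- function(posts, score_col) {
  if (!score_col %in% names(posts)) {
    wx_abort(paste0("posts carry no '", score_col, "' column"))
  }
  posts[[score_col]]
}

#' Binned mean-score response along one condition
#'
#' The condition axis (raw value or z-score) is divided into `n_bins` evenly
#' spaced bins spanning the observed range (right-closed except the first
#' bin, which includes its lower edge). Bins holding fewer than
#' `min_fraction` of the binned posts are flagged excluded but still
#' reported. Explicit `edges` can be supplied for cross-dataset comparisons
#' on shared axes.
#'
#' @param posts Scored, annotated corpus tibble.
#' @param condition One of [weather_conditions()].
#' @param space "raw" or "zscore".
#' @param n_bins Number of bins (default 30).
#' @param min_fraction Minimum bin share for inclusion (default 0.001).
#' @param score_col Name of the score column (default "score_sentiment").
#' @param edges Optional explicit bin edges (overrides `n_bins`).
#' @return A `binned_curve` tibble: `bin`, `lower`, `upper`, `mid`,
#'   `bin_count`, `bin_mean`, `included`, with condition/space/edges
#'   attributes.
#' @export
binned_response <- function(posts, condition, space = c("zscore", "raw"),
                            n_bins = 30L, min_fraction = 0.001,
                            score_col = "score_sentiment", edges = NULL) {
  space <- match.arg(space)
  xcol <- paste0(if (space == "raw") "raw_" else "z_", condition)
  if (!xcol %in% names(posts)) {
    wx_abort(paste0("posts carry no '", xcol, "' column"))
  }
  x <- posts[[xcol]]
  y <- score_values(posts, score_col)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) wx_abort("no posts with a non-missing condition value")
  if (is.null(edges)) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning("all condition values identical; single degenerate bin")
      edges <- c(rng[1], rng[2])
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    }
  }
  nb <- length(edges) - 1L
  idx <- if (nb == 1L) rep(1L, length(x)) else {
    as.integer(cut(x, edges, include.lowest = TRUE, right = TRUE))
  }
  keep <- !is.na(idx)
  idx <- idx[keep]; y2 <- y[keep]
  cnt <- tabulate(idx, nbins = nb)
  sums <- rep(0, nb)
  agg <- rowsum(y2, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  means <- ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)
  curve <- tibble::tibble(
    bin = seq_len(nb),
    lower = edges[-length(edges)],
    upper = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    bin_count = cnt,
    bin_mean = means,
    included = cnt >= min_fraction * sum(cnt))
  attr(curve, "condition") <- condition
  attr(curve, "space") <- space
  attr(curve, "edges") <- edges
  attr(curve, "score_col") <- score_col
  class(curve) <- c("binned_curve", class(curve))
  curve
}

#' Standardize post scores within groups
#'
#' Adds `score_z = (score - group mean) / (group sd)` (n - 1 divisor) within
#' each level of a grouping column (conventionally the region; a grid-cell
#' grouping is the stated alternative). Groups with fewer than two posts or
#' zero score spread are flagged with a warning and get missing `score_z`.
#'
#' @param posts Scored corpus tibble.
#' @param grouping Name of the grouping column (default "region").
#' @param score_col Name of the score column.
#' @return `posts` with a `score_z` column.
#' @export
zscore_scores <- function(posts, grouping = "region",
                          score_col = "score_sentiment") {
  y <- score_values(posts, score_col)
  if (!grouping %in% names(posts)) {
    wx_abort(paste0("posts carry no '", grouping, "' column"))
  }
  g <- posts[[grouping]]
  mu <- tapply(y, g, mean)
  sg <- tapply(y, g, sd)
  bad <- names(mu)[is.na(sg) | sg == 0]
  if (length(bad)) {
    warning("groups with <2 posts or zero score spread: ",
            paste(bad, collapse = ", "))
  }
  sgx <- sg[as.character(g)]
  sgx[sgx == 0] <- NA_real_
  posts$score_z <- as.numeric((y - mu[as.character(g)]) / sgx)
  posts
}

#' Mean score over a two-condition z-score grid
#'
#' Posts are binned over the (z_x, z_y) plane on a `gridsize x gridsize`
#' rectangular lattice spanning the observed ranges; cells holding fewer
#' than `min_count` posts are flagged excluded (the conventional low-volume
#' rule). Rectangular cells carry the same exclusion logic as a hexagonal
#' display would.
#'
#' @param posts Scored, annotated corpus tibble.
#' @param condition_x,condition_y Conditions for the two axes.
#' @param gridsize Cells per axis (default 30).
#' @param min_count Minimum posts per cell (default 5).
#' @param score_col Name of the score column.
#' @return A `pair_grid` tibble: `ix`, `iy`, `x_mid`, `y_mid`, `count`,
#'   `mean_score`, `included`.
#' @export
pair_grid <- function(posts, condition_x, condition_y, gridsize = 30L,
                      min_count = 5L, score_col = "score_sentiment") {
  xc <- paste0("z_", condition_x)
  yc <- paste0("z_", condition_y)
  for (cc in c(xc, yc)) {
    if (!cc %in% names(posts)) wx_abort(paste0("posts carry no '", cc, "'"))
  }
  y <- score_values(posts, score_col)
  ok <- !is.na(posts[[xc]]) & !is.na(posts[[yc]]) & !is.na(y)
  if (!any(ok)) wx_abort("no posts with both conditions present")
  zx <- posts[[xc]][ok]; zy <- posts[[yc]][ok]; sc <- y[ok]
  bin1 <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      list(idx = rep(1L, length(v)), mids = rng[1])
    } else {
      e <- seq(rng[1], rng[2], length.out = gridsize + 1L)
      list(idx = as.integer(cut(v, e, include.lowest = TRUE)),
           mids = (e[-1] + e[-length(e)]) / 2)
    }
  }
  bx <- bin1(zx); by <- bin1(zy)
  key <- (by$idx - 1L) * length(bx$mids) + bx$idx
  cnt <- tabulate(key, nbins = length(bx$mids) * length(by$mids))
  sums <- rep(0, length(cnt))
  agg <- rowsum(sc, key)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  nz <- which(cnt > 0)
  grid <- tibble::tibble(
    ix = ((nz - 1L) %% length(bx$mids)) + 1L,
    iy = ((nz - 1L) %/% length(bx$mids)) + 1L,
    x_mid = bx$mids[((nz - 1L) %% length(bx$mids)) + 1L],
    y_mid = by$mids[((nz - 1L) %/% length(bx$mids)) + 1L],
    count = cnt[nz],
    mean_score = sums[nz] / cnt[nz],
    included = cnt[nz] >= min_count)
  attr(grid, "condition_x") <- condition_x
  attr(grid, "condition_y") <- condition_y
  attr(grid, "min_count") <- min_count
  class(grid) <- c("pair_grid", class(grid))
  grid
}

#' Word-level severity-vs-sentiment scatter data
#'
#' Inner join of a sentiment lexicon and a weather-severity lexicon on
#' token, dropping tokens below a corpus-frequency floor, ordered by token.
#'
#' @param sentiment_lexicon,weather_lexicon `token_lexicon` objects (the
#'   frequency floor uses their `count` columns where present).
#' @param min_count Frequency floor (default 0: keep everything).
#' @return A tibble: `token`, `severity`, `sentiment` (and `count`).
#' @export
word_scatter <- function(sentiment_lexicon, weather_lexicon, min_count = 0L) {
  s <- tibble::as_tibble(sentiment_lexicon)
  w <- tibble::as_tibble(weather_lexicon)
  joined <- dplyr::inner_join(
    dplyr::select(s, "token", sentiment = "valence",
                  dplyr::any_of("count")),
    dplyr::select(w, "token", severity = "valence"),
    by = "token")
  if ("count" %in% names(joined)) {
    joined <- joined[joined$count >= min_count, ]
  }
  if (nrow(joined) == 0L) wx_abort("lexicons share no tokens above the floor")
  joined <- joined[order(joined$token), c("token", "severity", "sentiment",
                                          intersect("count", names(joined)))]
  joined
}

#' Assign posts to regions by location
#'
#' Point posts are assigned by containment (boundary inside). Polygon posts
#' are assigned to a region iff the overlap area fraction with that single
#' region reaches `threshold` (default 0.5); broadly located or ambiguous
#' polygons remain unassigned. Region polygons must be convex and mutually
#' exclusive.
#'
#' @param posts Corpus tibble with `lon`/`lat` and optionally `polygon` WKT.
#' @param region_polygons Named list of open rings (two-column matrices) or
#'   WKT POLYGON strings.
#' @param threshold Overlap fraction threshold.
#' @return A tibble `id`, `region` (NA when unassigned).
#' @export
assign_regions <- function(posts, region_polygons, threshold = 0.5) {
  rings <- lapply(region_polygons, function(p) {
    if (is.character(p)) parse_wkt(p)$coords else as.matrix(p)
  })
  rnames <- names(rings)
  if (is.null(rnames) || any(!nzchar(rnames))) {
    wx_abort("region polygons must be named")
  }
  has_poly <- "polygon" %in% names(posts)
  region <- rep(NA_character_, nrow(posts))
  for (i in seq_len(nrow(posts))) {
    wkt <- if (has_poly) posts$polygon[i] else NA_character_
    if (!is.na(wkt) && parse_wkt(wkt)$type == "polygon") {
      subject <- parse_wkt(wkt)$coords
      fr <- vapply(rings, function(r) {
        polygon_overlap_fraction(subject, r)
      }, numeric(1))
      hit <- which(fr >= threshold)
      if (length(hit) == 1L) region[i] <- rnames[hit]
    } else {
      inside <- vapply(rings, function(r) {
        point_in_polygon(posts$lon[i], posts$lat[i], r)
      }, logical(1))
      hit <- which(inside)
      if (length(hit) >= 1L) region[i] <- rnames[hit[1]]
    }
  }
  tibble::tibble(id = posts$id, region = region)
}

#' Correlation between two binned response curves
#'
#' Pearson correlation (with a two-sided p-value) of bin means over the bins
#' included in both curves. The curves must share bin edges — build them
#' with a common `edges` argument to [binned_response()]. Spearman is
#' available for a rank-based comparison.
#'
#' @param curve_a,curve_b `binned_curve` objects on identical edges.
#' @param method "pearson" (default) or "spearman".
#' @return A list: `r`, `p`, `n_common`.
#' @export
curve_correlation <- function(curve_a, curve_b, method = "pearson") {
  ea <- attr(curve_a, "edges"); eb <- attr(curve_b, "edges")
  if (length(ea) != length(eb) || max(abs(ea - eb)) > 1e-9) {
    wx_abort("curves must share bin edges (use binned_response(edges = ))")
  }
  common <- curve_a$included & curve_b$included &
    !is.na(curve_a$bin_mean) & !is.na(curve_b$bin_mean)
  if (sum(common) < 3L) wx_abort("fewer than 3 common included bins")
  ct <- cor.test(curve_a$bin_mean[common], curve_b$bin_mean[common],
                 method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n_common = sum(common))
}
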