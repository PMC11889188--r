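# Interchange formats: JSON Lines corpora, long-format CSV weather fields,
# TSV truth tables.

#' Write / read a corpus as JSON Lines
#'
#' One post per line with fields id, account, username, date (ISO-8601),
#' lon, lat, polygon (WKT or null) and text, plus any extra columns present.
#'
#' @param posts Corpus tibble.
#' @param path File path.
#' @return The path (write) or a corpus tibble (read).
#' @export
write_corpus_jsonl <- function(posts, path) {
  df <- as.data.frame(posts)
  if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, na = "null",
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' Write / read a weather field as long-format CSV
#'
#' Columns: cell_id, lon, lat, date, condition, value (missing values as
#' empty fields).
#'
#' @param field A `weather_field`.
#' @param path File path.
#' @return The path (write) or a `weather_field` (read).
#' @export
write_weather_csv <- function(field, path) {
  cells <- as.integer(dimnames(field$values)$cell)
  long <- expand.grid(cell_i = seq_along(cells),
                      day_i = seq_along(field$dates),
                      cond_i = seq_along(field$conditions))
  df <- tibble::tibble(
    cell_id = cells[long$cell_i],
    lon = field$grid$lon[long$cell_i],
    lat = field$grid$lat[long$cell_i],
    date = field$dates[long$day_i],
    condition = field$conditions[long$cond_i],
    value = field$values[cbind(long$cell_i, long$day_i, long$cond_i)])
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @param spacing Grid spacing (degrees) to record on reading.
#' @export
read_weather_csv <- function(path, spacing = NA_real_) {
  df <- readr::read_csv(path, col_types = readr::cols(
    cell_id = "i", lon = "d", lat = "d", date = "D", condition = "c",
    value = "d"), progress = FALSE)
  conds <- weather_conditions()
  bad <- setdiff(unique(df$condition), conds)
  if (length(bad)) {
    wx_abort(paste0("unknown conditions in file: ", paste(bad, collapse = ", ")))
  }
  cells <- sort(unique(df$cell_id))
  dates <- sort(unique(df$date))
  vals <- array(NA_real_, dim = c(length(cells), length(dates), length(conds)),
                dimnames = list(cell = cells, day = NULL, condition = conds))
  vals[cbind(match(df$cell_id, cells), match(df$date, dates),
             match(df$condition, conds))] <- df$value
  grid <- unique(df[, c("cell_id", "lon", "lat")])
  grid <- grid[order(grid$cell_id), ]
  structure(list(grid = tibble::as_tibble(grid), spacing = spacing,
                 dates = dates, conditions = conds, values = vals,
                 region = NULL),
            class = "weather_field")
}

#' Write a synthetic truth table as TSV
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param dir Output directory; writes `truth_posts.tsv`,
#'   `severity_loading.tsv` and `sentiment_loading.tsv`.
#' @return The directory, invisibly.
#' @export
write_truth_tsv <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(corpus$truth_posts, file.path(dir, "truth_posts.tsv"),
                   progress = FALSE)
  readr::write_tsv(corpus$truth$severity_loading,
                   file.path(dir, "severity_loading.tsv"), progress = FALSE)
  readr::write_tsv(corpus$truth$sentiment_loading,
                   file.path(dir, "sentiment_loading.tsv"), progress = FALSE)
  invisible(dir)
}
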