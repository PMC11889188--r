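# Join posts to gridded daily weather and convert conditions to anomaly
# z-scores against a per-location reference climatology.

#' Compute a reference climatology from a weather field
#'
#' Per (cell, condition): sample mean and sample standard deviation (n - 1
#' divisor) of the daily values inside the reference window, ignoring missing
#' days. Cells with fewer than `min_days` non-missing days for a condition
#' are marked unusable; constant series give `sigma = 0` and are flagged
#' degenerate.
#'
#' @param field A `weather_field`.
#' @param window Date range `c(from, to)` (default: the whole field).
#' @param min_days Minimum non-missing days per (cell, condition).
#' @return A `climatology`: matrices `mu`, `sigma`, logical `usable` and
#'   `degenerate` `[cell x condition]`, plus the reference window.
#' @export
compute_climatology <- function(field, window = NULL, min_days = 30L) {
  stopifnot(inherits(field, "weather_field"))
  if (is.null(window)) window <- range(field$dates)
  window <- as.Date(window)
  if (window[1] < min(field$dates) || window[2] > max(field$dates)) {
    wx_abort("window must lie within the field's dates")
  }
  sel <- field$dates >= window[1] & field$dates <= window[2]
  conds <- field$conditions
  cells <- as.integer(dimnames(field$values)$cell)
  mu <- sigma <- matrix(NA_real_, length(cells), length(conds),
                        dimnames = list(cell = cells, condition = conds))
  nobs <- matrix(0L, length(cells), length(conds))
  for (k in seq_along(conds)) {
    v <- field$values[, sel, k, drop = FALSE]
    dim(v) <- c(length(cells), sum(sel))
    nobs[, k] <- rowSums(!is.na(v))
    mu[, k] <- rowMeans(v, na.rm = TRUE)
    sigma[, k] <- apply(v, 1, sd, na.rm = TRUE)
  }
  usable <- nobs >= min_days
  dimnames(usable) <- dimnames(mu)
  if (!all(usable)) {
    warning(sum(!usable), " (cell, condition) series have fewer than ",
            min_days, " non-missing days and are marked unusable")
  }
  structure(list(cells = cells, conditions = conds, mu = mu, sigma = sigma,
                 usable = usable, degenerate = usable & (sigma == 0),
                 reference_window = window),
            class = "climatology")
}

#' Exact generating climatology of a synthetic region set
#'
#' The climatology the synthetic generator actually used (each region's `mu`
#' and `sigma` replicated over its cells); z-scores computed against it
#' reproduce the generator's internal truth exactly.
#'
#' @param regions List of [region_spec()] objects.
#' @param window Reference window to record.
#' @return A `climatology`.
#' @export
climatology_from_regions <- function(regions,
                                     window = as.Date(c("2011-01-01",
                                                        "2020-12-31"))) {
  check_regions(regions)
  conds <- weather_conditions()
  cells <- sort(unlist(lapply(regions, `[[`, "cells")))
  mu <- sigma <- matrix(NA_real_, length(cells), length(conds),
                        dimnames = list(cell = cells, condition = conds))
  for (r in regions) {
    idx <- match(r$cells, cells)
    mu[idx, ] <- matrix(r$mu[conds], length(idx), length(conds), byrow = TRUE)
    sigma[idx, ] <- matrix(r$sigma[conds], length(idx), length(conds),
                           byrow = TRUE)
  }
  structure(list(cells = cells, conditions = conds, mu = mu, sigma = sigma,
                 usable = matrix(TRUE, length(cells), length(conds),
                                 dimnames = dimnames(mu)),
                 degenerate = matrix(FALSE, length(cells), length(conds),
                                     dimnames = dimnames(mu)),
                 reference_window = as.Date(window)),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat("<climatology>", length(x$cells), "cells x", length(x$conditions),
      "conditions; window", format(x$reference_window[1]), "to",
      format(x$reference_window[2]), "\n")
  invisible(x)
}

# resolve a post location to a grid cell id (nearest node) or a set of nodes
# (polygon overlap). Returns list(cells, mode).
resolve_cells <- function(lon, lat, polygon, field) {
  g <- field$grid
  spacing <- field$spacing
  if (!is.na(polygon %||% NA_character_) && !is.na(polygon)) {
    geom <- parse_wkt(polygon)
    if (geom$type == "polygon") {
      inside <- point_in_polygon(g$lon, g$lat, geom$coords)
      if (any(inside)) {
        return(list(cells = g$cell_id[inside], mode = "overlap"))
      }
      ctr <- colMeans(geom$coords)
      lon <- ctr[1]; lat <- ctr[2]
    } else {
      lon <- geom$coords[1, 1]; lat <- geom$coords[1, 2]
    }
  }
  if (!is.na(spacing)) {
    if (lon < min(g$lon) - spacing || lon > max(g$lon) + spacing ||
        lat < min(g$lat) - spacing || lat > max(g$lat) + spacing) {
      wx_abort("location outside the grid bounding box by more than one cell")
    }
  }
  d <- geosphere::distHaversine(cbind(lon, lat), cbind(g$lon, g$lat))
  # ties broken by smallest cell id (grid rows are sorted by cell_id)
  list(cells = g$cell_id[which.min(d)], mode = "nearest")
}

#' Attach the five condition values to one location/date
#'
#' Polygon locations overlapping one or more grid nodes (node-in-polygon,
#' boundary inside) take the unweighted mean over the overlapped nodes; point
#' locations, and polygons overlapping no node, take the values at the
#' nearest node by great-circle distance (ties broken by smallest cell id).
#' Missing values at the chosen node(s) propagate as missing.
#'
#' @param field A `weather_field`.
#' @param date The post's date (must lie within the field's dates).
#' @param lon,lat Point coordinates (ignored if `polygon` is given).
#' @param polygon Optional WKT POLYGON string.
#' @return A `condition_vector`: list with `raw` (named over conditions),
#'   `cells` (contributing cell ids) and `mode` ("overlap" or "nearest").
#' @export
assign_conditions <- function(field, date, lon = NULL, lat = NULL,
                              polygon = NULL) {
  date <- as.Date(date)
  di <- match(date, field$dates)
  if (is.na(di)) wx_abort("date outside the weather field")
  rc <- resolve_cells(lon, lat, polygon %||% NA_character_, field)
  ci <- match(rc$cells, as.integer(dimnames(field$values)$cell))
  raw <- vapply(seq_along(field$conditions), function(k) {
    mean(field$values[ci, di, k])  # NA propagates by design
  }, numeric(1))
  names(raw) <- field$conditions
  structure(list(raw = raw, cells = rc$cells, mode = rc$mode, date = date),
            class = "condition_vector")
}

#' Convert raw condition values to climatological z-scores
#'
#' `z = (raw - mu) / sigma` per condition at the given cell. Conditions with
#' `sigma = 0` (degenerate climatology) yield missing z with a warning.
#'
#' @param vec A `condition_vector` from [assign_conditions()], or a named
#'   numeric vector of raw values.
#' @param clim A `climatology`.
#' @param cell Cell id at which to standardize (defaults to the first
#'   contributing cell of `vec`).
#' @return The `condition_vector` with a `z` component added (or, for a bare
#'   numeric input, a named numeric vector of z-scores).
#' @export
zscore_conditions <- function(vec, clim, cell = NULL) {
  bare <- !inherits(vec, "condition_vector")
  raw <- if (bare) vec else vec$raw
  cell <- cell %||% (if (bare) NULL else vec$cells[1])
  if (is.null(cell)) wx_abort("cell must be supplied for bare numeric input")
  i <- match(cell, clim$cells)
  if (is.na(i)) wx_abort("cell not present in climatology")
  if (!all(clim$usable[i, names(raw)])) wx_abort("unusable climatology cell")
  sg <- clim$sigma[i, names(raw)]
  mu <- clim$mu[i, names(raw)]
  z <- (raw - mu) / sg
  if (any(sg == 0, na.rm = TRUE)) {
    z[sg == 0] <- NA_real_
    warning("sigma = 0 for ", paste(names(raw)[sg == 0], collapse = ", "),
            "; z set to missing")
  }
  if (bare) return(z)
  vec$z <- z
  vec
}

#' Annotate a corpus with raw and z-scored weather conditions
#'
#' Every post gains `raw_<condition>` and `z_<condition>` columns plus
#' `cell_id`. Posts dated outside the field, or located outside the grid,
#' are flagged in `join_error` and keep missing values; posts with any
#' missing condition are flagged in `weather_missing`, not dropped.
#'
#' @param posts Corpus tibble with `date` and `lon`/`lat` (and optionally
#'   `polygon` WKT) columns.
#' @param field A `weather_field`.
#' @param clim A `climatology` covering the field's cells.
#' @return The annotated corpus tibble.
#' @export
annotate_corpus <- function(posts, field, clim) {
  conds <- field$conditions
  n <- nrow(posts)
  out <- posts
  for (cn in conds) {
    out[[paste0("raw_", cn)]] <- NA_real_
    out[[paste0("z_", cn)]] <- NA_real_
  }
  out$cell_id <- NA_integer_
  out$join_error <- NA_character_
  if (n == 0L) {
    out$weather_missing <- logical(0)
    return(out)
  }

  has_poly <- "polygon" %in% names(posts)
  loc_key <- paste(posts$lon, posts$lat,
                   if (has_poly) posts$polygon else NA, sep = "|")
  uniq <- !duplicated(loc_key)
  cell_of <- rep(NA_integer_, n)
  multi <- list()  # polygon posts overlapping several nodes, handled per post
  for (i in which(uniq)) {
    res <- tryCatch(
      resolve_cells(posts$lon[i], posts$lat[i],
                    if (has_poly) posts$polygon[i] else NA_character_, field),
      error = function(e) e)
    idx <- which(loc_key == loc_key[i])
    if (inherits(res, "error")) {
      out$join_error[idx] <- conditionMessage(res)
    } else if (length(res$cells) == 1L) {
      cell_of[idx] <- res$cells
    } else {
      multi[[as.character(i)]] <- list(idx = idx, cells = res$cells)
    }
  }

  cells_axis <- as.integer(dimnames(field$values)$cell)
  di <- match(as.Date(posts$date), field$dates)
  bad_date <- is.na(di) & is.na(out$join_error)
  out$join_error[bad_date] <- "date outside the weather field"

  ok <- !is.na(cell_of) & !is.na(di)
  ci <- match(cell_of, cells_axis)
  for (k in seq_along(conds)) {
    raw <- rep(NA_real_, n)
    raw[ok] <- field$values[cbind(ci[ok], di[ok], k)]
    i_cl <- match(cell_of, clim$cells)
    sg <- clim$sigma[cbind(i_cl, k)]
    mu <- clim$mu[cbind(i_cl, k)]
    z <- (raw - mu) / ifelse(sg == 0, NA_real_, sg)
    out[[paste0("raw_", conds[k])]] <- raw
    out[[paste0("z_", conds[k])]] <- z
  }
  out$cell_id <- cell_of

  # polygon posts overlapping multiple nodes: average raw, z against the
  # smallest contributing cell's climatology
  for (mi in multi) {
    ci2 <- match(mi$cells, cells_axis)
    lead <- min(mi$cells)
    i_cl <- match(lead, clim$cells)
    for (j in mi$idx) {
      if (is.na(di[j])) next
      raw <- vapply(seq_along(conds), function(k) {
        mean(field$values[ci2, di[j], k])
      }, numeric(1))
      for (k in seq_along(conds)) {
        sg <- clim$sigma[i_cl, k]
        out[[paste0("raw_", conds[k])]][j] <- raw[k]
        out[[paste0("z_", conds[k])]][j] <-
          if (isTRUE(sg > 0)) (raw[k] - clim$mu[i_cl, k]) / sg else NA_real_
      }
      out$cell_id[j] <- lead
    }
  }

  zc <- as.matrix(out[paste0("z_", conds)])
  out$weather_missing <- rowSums(is.na(zc)) > 0
  out
}
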