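# Minimal planar geometry for WKT points/polygons: parsing, point-in-polygon,
# convex clipping and areas. Coordinates are lon/lat degrees; areas are planar
# (adequate at the sub-degree extents used for region assignment).

#' Parse a WKT POINT or POLYGON string
#'
#' Supports `POINT (x y)` and single-ring `POLYGON ((x1 y1, ...))`. The
#' polygon ring may or may not repeat its first vertex; the parsed ring is
#' returned open (no repeated vertex).
#'
#' @param wkt A single WKT string.
#' @return A list with `type` ("point" or "polygon") and `coords`, a numeric
#'   matrix with columns `lon`, `lat` (one row for a point).
#' @export
parse_wkt <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1L, !is.na(wkt))
  s <- stringi::stri_trim_both(wkt)
  if (stringi::stri_startswith_fixed(toupper(s), "POINT")) {
    nums <- as.numeric(stringi::stri_extract_all_regex(
      s, "-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?")[[1]])
    if (length(nums) != 2L || anyNA(nums)) wx_abort("malformed WKT POINT")
    return(list(type = "point",
                coords = matrix(nums, 1, 2,
                                dimnames = list(NULL, c("lon", "lat")))))
  }
  if (stringi::stri_startswith_fixed(toupper(s), "POLYGON")) {
    inner <- stringi::stri_extract_first_regex(s, "\\(\\(.*?\\)\\)")
    if (is.na(inner)) wx_abort("malformed WKT POLYGON")
    inner <- stringi::stri_replace_all_regex(inner, "[()]", "")
    pts <- stringi::stri_split_regex(inner, ",\\s*")[[1]]
    xy <- t(vapply(pts, function(p) {
      as.numeric(stringi::stri_split_regex(
        stringi::stri_trim_both(p), "\\s+")[[1]][1:2])
    }, numeric(2)))
    if (anyNA(xy) || nrow(xy) < 3L) wx_abort("malformed WKT POLYGON")
    if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(xy) < 3L) wx_abort("degenerate WKT POLYGON")
    colnames(xy) <- c("lon", "lat")
    rownames(xy) <- NULL
    return(list(type = "polygon", coords = xy))
  }
  wx_abort("unsupported WKT geometry (only POINT and POLYGON)")
}

#' Format a point or polygon as WKT
#' @param coords Numeric matrix (lon, lat); a single row yields a POINT.
#' @return A WKT string.
#' @export
format_wkt <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) == 1L) {
    return(sprintf("POINT (%.10g %.10g)", coords[1, 1], coords[1, 2]))
  }
  ring <- rbind(coords, coords[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.10g %.10g", ring[, 1], ring[, 2]), collapse = ", "))
}

# signed area (shoelace); positive when counter-clockwise
polygon_signed_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Planar polygon area
#' @param xy Open ring as a two-column matrix.
#' @return Non-negative area in squared degrees.
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' Point-in-polygon test (boundary counts as inside)
#'
#' Ray casting with an explicit on-boundary check, so points exactly on an
#' edge or vertex are classified inside.
#'
#' @param lon,lat Point coordinates (vectorized).
#' @param poly Open polygon ring, two-column matrix.
#' @param tol Tolerance for the boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly, tol = 1e-12) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- px[c(2:n, 1L)]; qy <- py[c(2:n, 1L)]
  vapply(seq_along(lon), function(i) {
    x <- lon[i]; y <- lat[i]
    # boundary: point on any segment?
    cross <- (qx - px) * (y - py) - (qy - py) * (x - px)
    on_seg <- abs(cross) <= tol * pmax(1, abs(qx - px) + abs(qy - py)) &
      x >= pmin(px, qx) - tol & x <= pmax(px, qx) + tol &
      y >= pmin(py, qy) - tol & y <= pmax(py, qy) + tol
    if (any(on_seg)) return(TRUE)
    crossing <- ((py > y) != (qy > y)) &
      (x < px + (qx - px) * (y - py) / (qy - py))
    sum(crossing) %% 2L == 1L
  }, logical(1))
}

# Sutherland-Hodgman: clip a simple polygon by a *convex* polygon.
# Returns an open ring (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  if (polygon_signed_area(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    inside <- function(p) {
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    }
    intersect_ab <- function(p, q) {
      # intersection of segment pq with infinite line ab
      r <- q - p
      s <- b - a
      denom <- r[1] * s[2] - r[2] * s[1]
      t <- ((a[1] - p[1]) * s[2] - (a[2] - p[2]) * s[1]) / denom
      p + t * r
    }
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    for (i in seq_len(m)) {
      p <- inp[i, ]
      q <- inp[if (i == m) 1L else i + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) {
        out <- rbind(out, p)
        if (!qin) out <- rbind(out, intersect_ab(p, q))
      } else if (qin) {
        out <- rbind(out, intersect_ab(p, q))
      }
    }
  }
  colnames(out) <- c("lon", "lat")
  rownames(out) <- NULL
  out
}

#' Fraction of a polygon's area overlapping a convex region polygon
#'
#' @param subject Open ring of the (simple) subject polygon.
#' @param region Open ring of a convex region polygon.
#' @return Overlap area divided by subject area, in `[0, 1]`.
#' @export
polygon_overlap_fraction <- function(subject, region) {
  a <- polygon_area(subject)
  if (a <= 0) wx_abort("subject polygon has zero area")
  clipped <- clip_polygon_convex(subject, region)
  if (nrow(clipped) < 3L) return(0)
  min(1, polygon_area(clipped) / a)
}
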