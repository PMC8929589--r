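# Minimal planar geometry on polygon rings.
#
# A "ring" is an n x 2 numeric matrix of vertices (open or closed; the closing
# edge is implied). A "poly" is a list of one or more outer rings (holes are
# not supported). All coordinates are planar meters in an equal-area frame.

#' Build a rectangular ring
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds in meters.
#' @return A 4 x 2 matrix of vertices (counter-clockwise).
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# even-odd ray cast; points on an edge count as inside often enough for
# cell-center tests (cell centers never sit exactly on synthetic boundaries)
ring_contains <- function(ring, px, py) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xs2 <- xs[c(2:n, 1)]; ys2 <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys2[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ys2[i] - ys[i]) * (xs2[i] - xs[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' Test whether points fall inside a polygon
#'
#' @param poly A list of rings (or a single ring matrix).
#' @param px,py Point coordinate vectors.
#' @return Logical vector, `TRUE` where the point is inside any ring.
#' @export
poly_contains <- function(poly, px, py) {
  poly <- as_poly(poly)
  out <- rep(FALSE, length(px))
  for (ring in poly) out <- out | ring_contains(ring, px, py)
  out
}

as_poly <- function(poly) {
  if (is.matrix(poly)) list(poly) else poly
}

ring_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area and centroid
#'
#' Area by the shoelace formula, summed over rings; centroid is the
#' area-weighted centroid of the rings.
#'
#' @param poly A list of rings or a single ring matrix.
#' @return `poly_area()`: area in square meters. `poly_centroid()`: length-2
#'   numeric `(x, y)`.
#' @export
poly_area <- function(poly) {
  sum(vapply(as_poly(poly), function(r) abs(ring_area(r)), numeric(1)))
}

#' @rdname poly_area
#' @export
poly_centroid <- function(poly) {
  poly <- as_poly(poly)
  cx <- cy <- w <- 0
  for (ring in poly) {
    n <- nrow(ring)
    x <- ring[, 1]; y <- ring[, 2]
    x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
    cr <- x * y2 - x2 * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) next
    cx <- cx + sum((x + x2) * cr) / 6
    cy <- cy + sum((y + y2) * cr) / 6
    w <- w + a
  }
  c(x = cx / w, y = cy / w)
}

# distance from one point to a polygon boundary; 0 if inside
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2)))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance from a point to a polygon
#'
#' Zero when the point lies inside; otherwise the minimum distance to any
#' boundary edge.
#'
#' @param poly A list of rings or a single ring matrix.
#' @param px,py A single point.
#' @return Distance in meters.
#' @export
poly_distance <- function(poly, px, py) {
  poly <- as_poly(poly)
  if (poly_contains(poly, px, py)) return(0)
  best <- Inf
  for (ring in poly) {
    n <- nrow(ring)
    x <- ring[, 1]; y <- ring[, 2]
    x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
    best <- min(best, min(point_segment_dist(px, py, x, y, x2, y2)))
  }
  best
}

poly_bbox <- function(poly) {
  poly <- as_poly(poly)
  xs <- unlist(lapply(poly, function(r) r[, 1]))
  ys <- unlist(lapply(poly, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# ---- GeoJSON (geometry mapped by hand on top of jsonlite) -------------------

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  # drop the closing vertex if present
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' Read polygon features from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` geometries; interior rings (holes)
#' are not supported and raise an error. All non-geometry properties become
#' columns.
#'
#' @param path Path to a GeoJSON `FeatureCollection`.
#' @return A tibble with one row per feature and a `polygon` list-column of
#'   ring lists.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- purrr::map(gj$features, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = {
        if (length(geom$coordinates) > 1) stop("polygon holes are not supported")
        list(coords_to_ring(geom$coordinates[[1]]))
      },
      MultiPolygon = purrr::map(geom$coordinates, function(p) {
        if (length(p) > 1) stop("polygon holes are not supported")
        coords_to_ring(p[[1]])
      }),
      stop("unsupported geometry type: ", geom$type)
    )
    props <- purrr::map(f$properties, function(v) if (is.null(v)) NA else v)
    tibble::as_tibble(props) %>% dplyr::mutate(polygon = list(rings))
  })
  dplyr::bind_rows(rows)
}

#' Write polygon features to GeoJSON
#'
#' @param tbl A tibble with a `polygon` list-column (each element a list of
#'   rings); all other columns are written as feature properties.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(tbl, path) {
  props_tbl <- dplyr::select(tbl, -"polygon")
  feats <- purrr::map(seq_len(nrow(tbl)), function(i) {
    rings <- as_poly(tbl$polygon[[i]])
    geom <- if (length(rings) == 1) {
      list(type = "Polygon", coordinates = list(ring_to_coords(rings[[1]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = purrr::map(rings, function(r) list(ring_to_coords(r))))
    }
    list(type = "Feature",
         properties = as.list(props_tbl[i, , drop = FALSE]),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read and write point features as GeoJSON
#'
#' Point coordinates are taken from / written to `x`, `y` columns; all other
#' columns are feature properties.
#'
#' @param path GeoJSON path.
#' @return `read_geojson_points()`: a tibble with `x`, `y` and property
#'   columns.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- purrr::map(gj$features, function(f) {
    # a null geometry is legal (redacted coordinates)
    if (!is.null(f$geometry)) stopifnot(identical(f$geometry$type, "Point"))
    props <- purrr::map(f$properties, function(v) if (is.null(v)) NA else v)
    co <- f$geometry$coordinates
    xy <- if (is.null(co)) list(x = NA_real_, y = NA_real_) else
      list(x = as.numeric(co[[1]]), y = as.numeric(co[[2]]))
    tibble::as_tibble(c(xy, props))
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_geojson_points
#' @param tbl Tibble with `x`, `y` columns.
#' @export
write_geojson_points <- function(tbl, path) {
  props_tbl <- dplyr::select(tbl, -dplyr::any_of(c("x", "y")))
  feats <- purrr::map(seq_len(nrow(tbl)), function(i) {
    geom <- if (is.na(tbl$x[i]) || is.na(tbl$y[i])) NULL else
      list(type = "Point", coordinates = c(tbl$x[i], tbl$y[i]))
    list(type = "Feature",
         properties = as.list(props_tbl[i, , drop = FALSE]),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
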