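# Planar geometry primitives used throughout the package.
#
# All layers live in one planar metric coordinate frame (easting/northing in
# metres). Polylines and polygon rings are two-column matrices (x, y);
# feature layers are data.frames with a list-column `geometry` and an
# attribute `geom_type` of "Point", "LineString" or "Polygon".

#' Build a vector feature layer
#'
#' A feature layer is an ordinary data.frame of attributes plus a
#' list-column `geometry` holding one two-column coordinate matrix per
#' feature. Points are 1-row matrices; polygons are closed rings (first
#' vertex repeated last is optional, closure is implied).
#'
#' @param geometry list of two-column coordinate matrices.
#' @param geom_type one of "Point", "LineString", "Polygon".
#' @param ... equal-length attribute vectors.
#' @return a `dc_features` data.frame.
#' @export
dc_features <- function(geometry, geom_type = c("LineString", "Point", "Polygon"), ...) {
  geom_type <- match.arg(geom_type)
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    if (ncol(g) != 2L) stop("geometry matrices must have two columns (x, y)")
    g
  })
  props <- list(...)
  df <- if (length(props)) data.frame(props, stringsAsFactors = FALSE) else
    data.frame(row.names = seq_along(geometry))
  df$geometry <- I(geometry)
  attr(df, "geom_type") <- geom_type
  class(df) <- c("dc_features", "data.frame")
  df
}

#' @export
print.dc_features <- function(x, ...) {
  cat(sprintf("<dc_features: %d %s feature(s)>\n", nrow(x), attr(x, "geom_type")))
  print.data.frame(utils::head(x[setdiff(names(x), "geometry")], 10L))
  invisible(x)
}

geom_type <- function(x) attr(x, "geom_type")

## -- polyline measures --------------------------------------------------

seg_lengths <- function(coords) {
  d <- diff(coords)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Length of a polyline
#' @param coords two-column coordinate matrix.
#' @return length in map units.
#' @export
line_length <- function(coords) sum(seg_lengths(coords))

#' Point at a given distance along a polyline
#'
#' Distances beyond the ends are clamped to the ends.
#' @param coords two-column coordinate matrix.
#' @param d distances along the line (vector).
#' @return matrix of interpolated points.
#' @export
line_interpolate <- function(coords, d) {
  sl <- seg_lengths(coords)
  cum <- c(0, cumsum(sl))
  total <- cum[length(cum)]
  d <- pmin(pmax(d, 0), total)
  seg <- findInterval(d, cum, rightmost.closed = TRUE)
  seg[seg >= length(cum)] <- length(cum) - 1L
  frac <- ifelse(sl[seg] > 0, (d - cum[seg]) / sl[seg], 0)
  cbind(
    coords[seg, 1] + frac * (coords[seg + 1L, 1] - coords[seg, 1]),
    coords[seg, 2] + frac * (coords[seg + 1L, 2] - coords[seg, 2])
  )
}

#' Sample points at a regular spacing along a polyline
#' @param coords coordinate matrix.
#' @param step spacing in map units.
#' @return matrix of points including both endpoints.
#' @export
line_densify <- function(coords, step) {
  L <- line_length(coords)
  d <- unique(c(seq(0, L, by = step), L))
  line_interpolate(coords, d)
}

#' Split a polyline at given distances
#' @param coords coordinate matrix.
#' @param breaks increasing distances strictly inside (0, length).
#' @return list of coordinate matrices.
#' @keywords internal
line_split <- function(coords, breaks) {
  L <- line_length(coords)
  cuts <- c(0, breaks, L)
  sl <- seg_lengths(coords)
  cum <- c(0, cumsum(sl))
  out <- vector("list", length(cuts) - 1L)
  for (i in seq_len(length(cuts) - 1L)) {
    d0 <- cuts[i]; d1 <- cuts[i + 1L]
    inner <- which(cum > d0 + 1e-9 & cum < d1 - 1e-9)
    pts <- rbind(line_interpolate(coords, d0), coords[inner, , drop = FALSE],
                 line_interpolate(coords, d1))
    out[[i]] <- pts
  }
  out
}

## -- distances ----------------------------------------------------------

# squared distance of points (px,py) to one segment (ax,ay)-(bx,by)
.dist2_seg <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- ((px - ax) * dx + (py - ay) * dy) / l2
  t <- pmin(pmax(t, 0), 1)
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Distance from points to a polyline
#' @param pts two-column point matrix.
#' @param coords polyline coordinate matrix.
#' @return vector of distances.
#' @export
dist_to_line <- function(pts, coords) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(coords)
  if (n == 1L) return(sqrt((pts[, 1] - coords[1, 1])^2 + (pts[, 2] - coords[1, 2])^2))
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n - 1L)) {
    d2 <- pmin(d2, .dist2_seg(pts[, 1], pts[, 2],
                              coords[i, 1], coords[i, 2],
                              coords[i + 1L, 1], coords[i + 1L, 2]))
  }
  sqrt(d2)
}

#' Distance from points to the nearest of several polylines
#' @param pts point matrix.
#' @param lines list of coordinate matrices.
#' @return list with `dist` and `which` (index of nearest line).
#' @export
dist_to_lines <- function(pts, lines) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  best <- rep(Inf, nrow(pts)); idx <- rep(NA_integer_, nrow(pts))
  for (j in seq_along(lines)) {
    d <- dist_to_line(pts, lines[[j]])
    upd <- d < best
    best[upd] <- d[upd]; idx[upd] <- j
  }
  list(dist = best, which = idx)
}

## -- point in polygon ---------------------------------------------------

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule; `rings` may be a single ring matrix
#' or a list of rings (holes included by parity).
#' @param px,py point coordinate vectors.
#' @param rings ring matrix or list of ring matrices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1L }
    for (i in seq_len(n - 1L)) {
      x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
        hit <- px[crosses] < xint
        w <- which(crosses)[hit]
        inside[w] <- !inside[w]
      }
    }
  }
  inside
}

#' Buffer ring around a polyline with varying half-width
#'
#' Offsets each vertex perpendicular to the local direction; adequate for
#' gently curving channels (no self-intersection handling).
#' @param coords polyline.
#' @param halfwidth half-width per vertex (recycled).
#' @return closed ring matrix.
#' @export
line_buffer_ring <- function(coords, halfwidth) {
  n <- nrow(coords)
  halfwidth <- rep_len(halfwidth, n)
  d <- diff(coords)
  # vertex direction: average of adjacent segment directions
  dirs <- rbind(d[1, , drop = FALSE], (d[-nrow(d), , drop = FALSE] + d[-1, , drop = FALSE]) / 2, d[nrow(d), , drop = FALSE])
  if (n == 2L) dirs <- rbind(d, d)
  len <- sqrt(dirs[, 1]^2 + dirs[, 2]^2)
  len[len == 0] <- 1
  nx <- -dirs[, 2] / len; ny <- dirs[, 1] / len
  left <- cbind(coords[, 1] + nx * halfwidth, coords[, 2] + ny * halfwidth)
  right <- cbind(coords[, 1] - nx * halfwidth, coords[, 2] - ny * halfwidth)
  ring <- rbind(left, right[n:1, , drop = FALSE], left[1, , drop = FALSE])
  ring
}

#' Area of a polygon ring (shoelace)
#' @param ring ring matrix.
#' @return area in square map units.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1L }
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

bbox_of <- function(geoms) {
  xs <- unlist(lapply(geoms, function(g) g[, 1]))
  ys <- unlist(lapply(geoms, function(g) g[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
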