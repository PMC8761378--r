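# Planar Euclidean geometry primitives used by the boundary filter, the
# buffer-predictor builder and the block-grid linkage. All coordinates are
# metres in a projected CRS; buffers are Euclidean circles.

#' Test whether points fall inside (or on the edge of) a polygon
#'
#' Ray-casting with an explicit on-edge check, so the polygon is treated as a
#' closed set: points on a vertex or edge count as inside. Used for the
#' administrative-boundary eligibility filter.
#'
#' @param x,y Numeric vectors of point coordinates (metres).
#' @param polygon A data frame or matrix with columns `x` and `y` giving the
#'   polygon vertices in order (closing edge implied).
#' @return Logical vector, `TRUE` where the point is inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.data.frame(polygon)
  px <- polygon$x
  py <- polygon$y
  n <- length(px)
  stopifnot(n >= 3, length(x) == length(y))
  jx <- c(px[-1], px[1])
  jy <- c(py[-1], py[1])
  vapply(seq_along(x), function(k) {
    x0 <- x[k]; y0 <- y[k]
    # on-edge: zero cross product and within the segment's bounding box
    cross <- (jx - px) * (y0 - py) - (jy - py) * (x0 - px)
    on_edge <- abs(cross) < 1e-9 * pmax(1, abs(jx - px) + abs(jy - py)) &
      x0 >= pmin(px, jx) - 1e-12 & x0 <= pmax(px, jx) + 1e-12 &
      y0 >= pmin(py, jy) - 1e-12 & y0 <= pmax(py, jy) + 1e-12
    if (any(on_edge)) return(TRUE)
    crosses <- ((py > y0) != (jy > y0)) &
      (x0 < (jx - px) * (y0 - py) / (jy - py) + px)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

# Length of the part of segment (x1,y1)-(x2,y2) inside the circle of radius r
# centred at (cx,cy). Closed form via the quadratic for the circle-line
# intersection, clipped to the segment parameter range [0, 1]. Vectorised over
# segments.
segment_circle_length <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1
  dy <- y2 - y1
  fx <- x1 - cx
  fy <- y1 - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  len <- sqrt(a)
  out <- numeric(length(x1))
  ok <- disc > 0 & a > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
    t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
    out[ok] <- pmax(0, t2 - t1) * len[ok]
  }
  out
}

# Euclidean distance from point (px,py) to each segment (x1,y1)-(x2,y2).
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  a <- dx * dx + dy * dy
  t <- ifelse(a > 0, ((px - x1) * dx + (py - y1) * dy) / a, 0)
  t <- pmin(1, pmax(0, t))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

# Non-strict axis-aligned rectangle intersection (touching edges/corners
# count). Vectorised over the first rectangle set.
rects_intersect <- function(axmin, axmax, aymin, aymax, bxmin, bxmax, bymin, bymax) {
  axmin <= bxmax & axmax >= bxmin & aymin <= bymax & aymax >= bymin
}
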