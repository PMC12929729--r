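# Internal planar geometry helpers. Polygons are n x 2 numeric matrices of
# vertices in microns (image convention: y increases downward); the closing
# vertex is implicit. All routines treat the boundary as part of the polygon.

polygon_matrix <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L)
    stop("polygon must be an n x 2 numeric matrix of (x, y) vertices")
  # drop an explicit closing vertex if present
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3L || nrow(unique(p)) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  if (!all(is.finite(p))) stop("polygon has non-finite vertex coordinates")
  p
}

polygon_area <- function(p) {
  # shoelace; absolute value so vertex orientation does not matter
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L])) / 2
}

# does the closed segment p1-p2 properly or improperly intersect q1-q2?
.segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1L], b[1L]) <= c[1L] && c[1L] <= max(a[1L], b[1L]) &&
      min(a[2L], b[2L]) <= c[2L] && c[2L] <= max(a[2L], b[2L])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
    (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
}

# a polygon is simple when no pair of non-adjacent edges intersects
polygon_is_simple <- function(p) {
  n <- nrow(p)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_intersect(p[idx[i, 1L], ], p[idx[i, 2L], ],
                              p[idx[j, 1L], ], p[idx[j, 2L], ])) return(FALSE)
    }
  }
  TRUE
}

#' @title Point-in-polygon test (boundary counts as inside)
#' @description Ray-casting with explicit boundary handling: a point lying on a
#'   polygon edge or vertex is classified as inside, matching the convention
#'   used for ROI membership and region annotation.
#' @param x,y numeric vectors of point coordinates (microns).
#' @param polygon an n x 2 matrix of polygon vertices.
#' @return logical vector, `TRUE` where the point is inside or on the boundary.
#' @keywords internal
points_in_polygon <- function(x, y, polygon) {
  p <- polygon_matrix(polygon)
  n <- nrow(p)
  px <- p[, 1L]; py <- p[, 2L]
  qx <- px[c(2:n, 1L)]; qy <- py[c(2:n, 1L)]
  out <- logical(length(x))
  for (k in seq_along(x)) {
    xi <- x[k]; yi <- y[k]
    inside <- FALSE
    on_edge <- FALSE
    for (e in seq_len(n)) {
      x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
      # boundary check: collinear and within the edge's bounding box
      cross <- (x2 - x1) * (yi - y1) - (y2 - y1) * (xi - x1)
      if (cross == 0 &&
          min(x1, x2) <= xi && xi <= max(x1, x2) &&
          min(y1, y2) <= yi && yi <= max(y1, y2)) {
        on_edge <- TRUE
        break
      }
      if ((y1 > yi) != (y2 > yi)) {
        xint <- x1 + (yi - y1) * (x2 - x1) / (y2 - y1)
        if (xi < xint) inside <- !inside
      }
    }
    out[k] <- on_edge || inside
  }
  out
}

# conservative polygon-overlap test: shared interior is detected through
# edge intersections or full containment of one polygon's vertex in the other
polygons_overlap <- function(a, b) {
  a <- polygon_matrix(a); b <- polygon_matrix(b)
  # quick bounding-box rejection
  if (max(a[, 1L]) < min(b[, 1L]) || max(b[, 1L]) < min(a[, 1L]) ||
      max(a[, 2L]) < min(b[, 2L]) || max(b[, 2L]) < min(a[, 2L])) return(FALSE)
  na <- nrow(a); nb <- nrow(b)
  ia <- cbind(seq_len(na), c(2:na, 1L))
  ib <- cbind(seq_len(nb), c(2:nb, 1L))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (.segments_intersect(a[ia[i, 1L], ], a[ia[i, 2L], ],
                              b[ib[j, 1L], ], b[ib[j, 2L], ])) return(TRUE)
    }
  }
  any(points_in_polygon(a[, 1L], a[, 2L], b)) ||
    any(points_in_polygon(b[, 1L], b[, 2L], a))
}

# regular polygon approximating a circle, used for the default normal foci
circle_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
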