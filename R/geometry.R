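# Polygon primitives for morphometry and the synthetic TEM generator.
#
# Polygons are n x 2 numeric matrices (x, y) in micrometres, open rings
# (the closing edge from the last vertex back to the first is implicit).

shoelace_signed <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' Computes the area of a simple polygon from its ordered vertex list,
#' independent of orientation. This is the primitive behind all cell and
#' nucleus area statistics.
#'
#' @param vertices An n x 2 matrix of (x, y) vertices in micrometres,
#'   ordered along the boundary (open ring; n >= 3).
#' @param check If `TRUE` (default), verify the polygon is simple
#'   (non-self-intersecting) and error otherwise. Disable for polygons
#'   known simple by construction.
#' @return Area in square micrometres (a single non-negative number).
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
#' @export
polygon_area <- function(vertices, check = TRUE) {
  vertices <- as.matrix(vertices)
  abort_if(ncol(vertices) != 2L || nrow(vertices) < 3L,
           "a polygon needs an n x 2 vertex matrix with n >= 3")
  abort_if(!all(is.finite(vertices)), "polygon vertices must be finite")
  if (check) abort_if(!polygon_is_simple(vertices),
                      "polygon is self-intersecting")
  abs(shoelace_signed(vertices))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))  # degenerate: vertex mean
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Proper segment-crossing test between all non-adjacent edge pairs.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(TRUE)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip edges sharing a vertex with edge i (adjacent in the ring)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(p1[i, ], p2[i, ],
                           p1[js, , drop = FALSE], p2[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Vectorised proper-intersection test: segment (a1,a2) vs rows of (b1,b2).
segments_cross <- function(a1, a2, b1, b2) {
  d1 <- (a2[1] - a1[1]) * (b1[, 2] - a1[2]) - (a2[2] - a1[2]) * (b1[, 1] - a1[1])
  d2 <- (a2[1] - a1[1]) * (b2[, 2] - a1[2]) - (a2[2] - a1[2]) * (b2[, 1] - a1[1])
  d3 <- (b2[, 1] - b1[, 1]) * (a1[2] - b1[, 2]) - (b2[, 2] - b1[, 2]) * (a1[1] - b1[, 1])
  d4 <- (b2[, 1] - b1[, 1]) * (a2[2] - b1[, 2]) - (b2[, 2] - b1[, 2]) * (a2[1] - b1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

ensure_ccw <- function(xy) {
  if (shoelace_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Sutherland-Hodgman clip of polygon xy against half-plane a*x + b*y <= c.
clip_halfplane <- function(xy, a, b, c) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  v <- a * xy[, 1L] + b * xy[, 2L] - c
  inside <- v <= 0
  if (all(inside)) return(xy)
  if (!any(inside)) return(xy[0L, , drop = FALSE])
  nxt <- c(2:n, 1L)
  out_x <- numeric(2L * n); out_y <- numeric(2L * n); k <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (inside[i]) {
      k <- k + 1L; out_x[k] <- xy[i, 1L]; out_y[k] <- xy[i, 2L]
    }
    if (xor(inside[i], inside[j])) {
      t <- v[i] / (v[i] - v[j])
      k <- k + 1L
      out_x[k] <- xy[i, 1L] + t * (xy[j, 1L] - xy[i, 1L])
      out_y[k] <- xy[i, 2L] + t * (xy[j, 2L] - xy[i, 2L])
    }
  }
  cbind(out_x[seq_len(k)], out_y[seq_len(k)])
}

clip_rect <- function(xy, x0, x1, y0, y1) {
  xy <- clip_halfplane(xy, -1, 0, -x0)
  if (nrow(xy) < 3L) return(xy[0L, , drop = FALSE])
  xy <- clip_halfplane(xy, 1, 0, x1)
  if (nrow(xy) < 3L) return(xy[0L, , drop = FALSE])
  xy <- clip_halfplane(xy, 0, -1, -y0)
  if (nrow(xy) < 3L) return(xy[0L, , drop = FALSE])
  xy <- clip_halfplane(xy, 0, 1, y1)
  if (nrow(xy) < 3L) return(xy[0L, , drop = FALSE])
  xy
}

# Insert vertices so no boundary segment exceeds max_len.
densify_polygon <- function(xy, max_len) {
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- xy[i, ]; q <- xy[nxt[i], ]
    len <- sqrt(sum((q - p)^2))
    m <- max(1L, ceiling(len / max_len))
    t <- (seq_len(m) - 1L) / m
    pieces[[i]] <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  do.call(rbind, pieces)
}

# Exact inward offset of a convex CCW polygon by distance t:
# intersect the half-planes of each edge shifted inward.
erode_convex <- function(xy, t) {
  if (t <= 0) return(xy)
  xy <- ensure_ccw(xy)
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  poly <- xy
  for (i in seq_len(n)) {
    p <- xy[i, ]; q <- xy[nxt[i], ]
    e <- q - p
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    # outward normal of a CCW edge is (ey, -ex)/len; keep points at signed
    # distance <= -t from the edge line (i.e. at least t inside it)
    a <- e[2] / len; b <- -e[1] / len
    c0 <- a * p[1] + b * p[2]
    poly <- clip_halfplane(poly, a, b, c0 - t)
    if (nrow(poly) < 3L) return(poly[0L, , drop = FALSE])
  }
  poly
}

polygon_scale <- function(xy, center, s) {
  cbind(center[1] + s * (xy[, 1L] - center[1]),
        center[2] + s * (xy[, 2L] - center[2]))
}

# Even-odd point-in-polygon, vectorised over query points.
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- (y[i] <= py) != (yn[i] <= py)
    if (any(crosses)) {
      xi <- x[i] + (py[crosses] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xi)
    }
  }
  inside
}

# Scanline-fill a list of polygons onto a pixel-centre grid covering
# [x0, x0 + nx/res) x [y0, y0 + ny/res). Returns an ny x nx logical matrix
# (row 1 = lowest y), TRUE where the pixel centre lies inside any polygon.
fill_polygons_mask <- function(polys, x0, y0, nx, ny, res) {
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  px_x <- x0 + (seq_len(nx) - 0.5) / res
  py_y <- y0 + (seq_len(ny) - 0.5) / res
  for (poly in polys) {
    if (is.null(poly) || nrow(poly) < 3L) next
    ylo <- min(poly[, 2L]); yhi <- max(poly[, 2L])
    rows <- which(py_y >= ylo & py_y <= yhi)
    if (!length(rows)) next
    x <- poly[, 1L]; y <- poly[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    for (r in rows) {
      yy <- py_y[r]
      cr <- (y <= yy) != (yn <= yy)
      if (!any(cr)) next
      xs <- sort(x[cr] + (yy - y[cr]) / (yn[cr] - y[cr]) * (xn[cr] - x[cr]))
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        cols <- which(px_x > xs[k] & px_x < xs[k + 1L])
        if (length(cols)) mask[r, cols] <- TRUE
      }
    }
  }
  mask
}
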