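#' Polygon geometry for radiograph annotations
#'
#' Polygons are n x 2 numeric matrices of (x, y) vertex coordinates in
#' 0-based pixel units: x runs rightward along columns, y downward along
#' rows, and a vertex sits at a pixel centre. All routines treat the
#' polygon as implicitly closed (last vertex joins the first).
#'
#' @name polygon-tools
NULL

as_polygon <- function(p, min_vertices = 3L) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L)
    stop("polygon must be an n x 2 numeric matrix of (x, y) coordinates")
  if (anyNA(p)) stop("polygon contains missing coordinates")
  ## drop an explicit closing vertex
  n <- nrow(p)
  if (n >= 2L && isTRUE(all(p[1L, ] == p[n, ]))) p <- p[-n, , drop = FALSE]
  if (nrow(p) < min_vertices)
    stop(sprintf("polygon needs at least %d distinct vertices", min_vertices))
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

## signed shoelace area in squared coordinate units (positive if
## counter-clockwise in a y-down frame is irrelevant: callers take abs())
signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

## do open segments (p1,p2) and (p3,p4) properly intersect, or overlap?
## touching at shared endpoints does not count.
segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  orient <- function(a, b, c)
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(a, b, c) {
    ## c collinear with a-b: does it fall strictly inside the segment?
    min(a[1L], b[1L]) - eps < c[1L] && c[1L] < max(a[1L], b[1L]) + eps &&
    min(a[2L], b[2L]) - eps < c[2L] && c[2L] < max(a[2L], b[2L]) + eps &&
    !(isTRUE(all(abs(c - a) < eps)) || isTRUE(all(abs(c - b) < eps)))
  }
  (abs(d1) <= eps && on_seg(p3, p4, p1)) ||
  (abs(d2) <= eps && on_seg(p3, p4, p2)) ||
  (abs(d3) <= eps && on_seg(p1, p2, p3)) ||
  (abs(d4) <= eps && on_seg(p1, p2, p4))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' @param p an n x 2 vertex matrix (implicitly closed).
#' @return `TRUE` or `FALSE`.
#' @export
is_simple_polygon <- function(p) {
  p <- as_polygon(p)
  n <- nrow(p)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ## skip adjacent edges (they share an endpoint by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(p[idx[i, 1L], ], p[idx[i, 2L], ],
                         p[idx[j, 1L], ], p[idx[j, 2L], ])) return(FALSE)
    }
  }
  TRUE
}

#' Area of a simple polygon
#'
#' Shoelace formula scaled to physical units. Orientation-independent.
#'
#' @param p an n x 2 vertex matrix in pixel coordinates.
#' @param pixel_spacing physical size of one pixel (mm/pixel).
#' @return area in mm^2 (or pixel^2 when `pixel_spacing = 1`).
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3)))  # 12
polygon_area <- function(p, pixel_spacing = 1) {
  p <- as_polygon(p)
  stopifnot(is.numeric(pixel_spacing), length(pixel_spacing) == 1L,
            pixel_spacing > 0)
  if (!is_simple_polygon(p)) stop("polygon is self-intersecting")
  abs(signed_area(p)) * pixel_spacing^2
}

#' Close an annotated deviation outline with its chord
#'
#' A keel deviation is annotated as an open polyline traced along the
#' deformed boundary; the enclosed area is estimated by joining the two
#' extremes of the outline with a straight chord. Returns the closed
#' polygon with the chord recorded (for rendering) as an attribute.
#'
#' @param polyline an n x 2 matrix (n >= 3) of ordered outline vertices;
#'   an already-closed ring (first vertex repeated at the end) is accepted
#'   and returned unchanged without the duplicate.
#' @return the closed polygon (n x 2 matrix) with attribute `"chord"`, a
#'   2 x 2 matrix holding the chord endpoints (last vertex, first vertex).
#' @export
close_deviation_outline <- function(polyline) {
  p <- as_polygon(polyline)   # drops a duplicated closing vertex
  if (!is_simple_polygon(p))
    stop("closing the outline with a chord creates a self-intersection")
  attr(p, "chord") <- p[c(nrow(p), 1L), , drop = FALSE]
  p
}

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd (parity) fill evaluated at pixel centres: pixel (row r, col c)
#' of the mask, 1-based in R, has centre (x = c - 1, y = r - 1) in the
#' 0-based annotation frame.
#'
#' @param p polygon vertex matrix.
#' @param nrow,ncol dimensions of the target image.
#' @return a logical matrix of the requested dimensions.
#' @export
polygon_mask <- function(p, nrow, ncol) {
  p <- as_polygon(p)
  m <- matrix(FALSE, nrow, ncol)
  xs <- p[, 1L]; ys <- p[, 2L]
  n <- length(xs)
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  for (r in seq_len(nrow)) {
    y <- r - 1
    ## half-open rule on y so a vertex lying on a scanline counts once
    hit <- (ys <= y & y < ye) | (ye <= y & y < ys)
    if (!any(hit)) next
    cross <- xs[hit] + (y - ys[hit]) * (xe[hit] - xs[hit]) / (ye[hit] - ys[hit])
    cross <- sort(cross)
    for (k in seq(1L, length(cross) - 1L, by = 2L)) {
      ## pixel centres in [x_enter, x_exit)
      c0 <- ceiling(cross[k] - 1e-9)
      c1 <- ceiling(cross[k + 1L] - 1e-9) - 1L
      c0 <- max(c0, 0L); c1 <- min(c1, ncol - 1L)
      if (c0 <= c1) m[r, (c0 + 1L):(c1 + 1L)] <- TRUE
    }
  }
  m
}

## clip a polygon against the half-plane x >= c (keep = "right") or
## x <= c ("left"); Sutherland-Hodgman against a single vertical plane.
clip_polygon_vertical <- function(p, cut, keep = c("right", "left")) {
  keep <- match.arg(keep)
  sgn <- if (keep == "right") 1 else -1
  inside <- function(v) sgn * (v[1L] - cut) >= 0
  cross_pt <- function(a, b) {
    t <- (cut - a[1L]) / (b[1L] - a[1L])
    c(cut, a[2L] + t * (b[2L] - a[2L]))
  }
  n <- nrow(p)
  out <- list()
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
    ia <- inside(a); ib <- inside(b)
    if (ia) out[[length(out) + 1L]] <- a
    if (ia != ib) out[[length(out) + 1L]] <- cross_pt(a, b)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
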