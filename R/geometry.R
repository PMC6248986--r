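# 2D polygon primitives used by the reconstruction stage. Coordinates are
# physical (micron) en-face positions within one C-scan plane.

#' Order margin points into a simple polygon
#'
#' Orders a set of en-face margin points counter-clockwise by angle about their
#' centroid. Margin points clicked by a human grader are typically stored in
#' click order, but files may shuffle them; angular ordering recovers a simple
#' polygon for any star-shaped (in practice, any hand-marked) pore outline.
#' Input that is already CCW-ordered is returned unchanged.
#'
#' @param points numeric matrix with two columns (x, y) in micrometres,
#'   at least 3 non-collinear rows.
#' @return a matrix of the same points ordered counter-clockwise.
#' @examples
#' sq <- rbind(c(1, 1), c(0, 0), c(0, 1), c(1, 0))
#' order_margin_points(sq)
#' @export
order_margin_points <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3L) {
    stop("at least 3 margin points are required to form a polygon")
  }
  if (points_collinear(points)) {
    stop("margin points are collinear; they do not bound an area")
  }
  if (is_ccw_ordered(points)) {
    return(points)
  }
  ctr <- colMeans(points)
  ang <- atan2(points[, 2] - ctr[2], points[, 1] - ctr[1])
  ord <- order(ang, sqrt(rowSums(sweep(points, 2, ctr)^2)))
  out <- points[ord, , drop = FALSE]
  if (!polygon_is_simple(out)) {
    stop("angular ordering produced a self-intersecting polygon; ",
         "the point set is too strongly non-convex for a star-shaped outline")
  }
  out
}

#' Area of a simple polygon
#'
#' Shoelace-formula area of a simple polygon, in square micrometres.
#' Orientation-independent (the absolute value is returned).
#'
#' @param polygon numeric matrix of ordered vertices (x, y) in micrometres.
#' @return polygon area in square micrometres.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygon_area <- function(polygon) {
  polygon <- as_point_matrix(polygon)
  if (nrow(polygon) < 3L) stop("a polygon needs at least 3 vertices")
  if (!polygon_is_simple(polygon)) {
    stop("polygon is self-intersecting; area is undefined")
  }
  abs(signed_polygon_area(polygon))
}

signed_polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(p) {
  # area-weighted centroid; falls back to the vertex mean for degenerate areas
  a <- signed_polygon_area(p)
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(p))
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

is_ccw_ordered <- function(p) {
  signed_polygon_area(p) > 0 && polygon_is_simple(p)
}

points_collinear <- function(p, tol = 1e-12) {
  if (nrow(p) < 3L) return(TRUE)
  p0 <- sweep(p, 2, colMeans(p))
  sv <- svd(p0)$d
  sv[2] <= tol * max(sv[1], 1)
}

# Simplicity test: no two non-adjacent edges intersect. Vectorized over all
# edge pairs; O(n^2) memory is fine for the ~10-100 vertex outlines here.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- !(j == i + 1L | (i == 1L & j == n))  # skip edges sharing a vertex
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(TRUE)
  # edge i: A1->A2, edge j: B1->B2
  d <- function(px, py, qx, qy, rx, ry) {  # cross(q - p, r - p)
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  # orientation of each endpoint of one edge relative to the other edge
  d1 <- d(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
  d2 <- d(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
  d3 <- d(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
  d4 <- d(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
  proper <- (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
               ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
  if (any(proper)) return(FALSE)
  on_seg <- function(px, py, qx, qy, rx, ry) {  # r collinear with p-q
    pmin(px, qx) <= rx & rx <= pmax(px, qx) &
      pmin(py, qy) <= ry & ry <= pmax(py, qy)
  }
  touch <- (d1 == 0 & on_seg(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])) |
    (d2 == 0 & on_seg(ax[j], ay[j], bx[j], by[j], bx[i], by[i])) |
    (d3 == 0 & on_seg(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])) |
    (d4 == 0 & on_seg(ax[i], ay[i], bx[i], by[i], bx[j], by[j]))
  !any(touch)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points)) {
    stop("points must be a numeric matrix with columns (x, y)")
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("points contain non-finite coordinates")
  }
  unname(points)
}
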