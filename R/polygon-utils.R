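# Closed outlines are plain two-column matrices (x, y) in micrometres,
# y-axis up, last vertex != first (closure implied). Counterclockwise
# orientation (positive signed area) is the package-wide convention.

#' Signed area of a closed polygon
#'
#' Shoelace formula; positive for counterclockwise vertex order under the
#' mathematical (y-up) convention used throughout the package.
#'
#' @param poly Two-column numeric matrix of vertices (closure implied).
#' @return Signed area (squared input units).
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon_matrix(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#'
#' @inheritParams polygon_area
#' @return Total edge length including the closing edge.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon_matrix(poly)
  d <- diff(rbind(poly, poly[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid (area-weighted)
#'
#' @inheritParams polygon_area
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon_matrix(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps^0.5) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Force counterclockwise orientation
#'
#' @inheritParams polygon_area
#' @return The polygon, with vertex order reversed if it was clockwise.
#' @export
ensure_ccw <- function(poly) {
  poly <- as_polygon_matrix(poly)
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

#' Symmetric Hausdorff distance between two closed outlines
#'
#' Distances are measured from the vertices of each polygon to the closed
#' polyline of the other (point-to-segment), symmetrized by taking the
#' larger directed maximum.
#'
#' @param a,b Two-column coordinate matrices (closed polygons).
#' @return Nonnegative scalar.
#' @export
hausdorff_distance <- function(a, b) {
  max(max(outline_distances(a, b)), max(outline_distances(b, a)))
}

# Mean distance from each vertex of `a` to the polyline of `b` (closed).
# Used for reconstruction-error curves.
mean_outline_distance <- function(a, b) {
  mean(outline_distances(a, b))
}

# distance from each vertex of `a` to the closed polyline of `b`
outline_distances <- function(a, b) {
  a <- as_polygon_matrix(a); b <- as_polygon_matrix(b)
  bseg <- rbind(b, b[1L, , drop = FALSE])
  p1 <- bseg[-nrow(bseg), , drop = FALSE]
  p2 <- bseg[-1L, , drop = FALSE]
  v <- p2 - p1
  len2 <- pmax(rowSums(v^2), .Machine$double.eps)
  vapply(seq_len(nrow(a)), function(i) {
    w <- cbind(a[i, 1L] - p1[, 1L], a[i, 2L] - p1[, 2L])
    tt <- pmin(pmax((w[, 1L] * v[, 1L] + w[, 2L] * v[, 2L]) / len2, 0), 1)
    dx <- w[, 1L] - tt * v[, 1L]
    dy <- w[, 2L] - tt * v[, 2L]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1L))
}

as_polygon_matrix <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly)
  if (!is.matrix(poly) || ncol(poly) != 2L || !is.numeric(poly))
    stop("a polygon must be a two-column numeric matrix of (x, y) vertices")
  if (nrow(poly) < 3L) stop("a polygon needs at least 3 vertices")
  if (anyNA(poly) || any(!is.finite(poly))) stop("polygon contains non-finite coordinates")
  unname(poly)
}
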