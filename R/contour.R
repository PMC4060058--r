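#' Closed planar contour of a traced section boundary
#'
#' A `bone_contour` stores the ordered vertices (in mm) of one closed tracing
#' from a transverse bone section: the medullary cavity boundary, a cyclical
#' growth mark (CGM), the periosteal surface, or a hatchling reference
#' surface. On construction the vertex list is normalised to the package
#' convention: counter-clockwise orientation, first vertex not repeated at
#' the end. Degenerate input (fewer than 3 distinct vertices, zero enclosed
#' area, or a self-intersecting outline) is a hard error.
#'
#' @param x,y Vertex coordinates in mm. `x` may also be a two-column matrix
#'   or data frame, in which case `y` must be `NULL`.
#' @param label Contour label: `"medullary"`, `"surface"`,
#'   `"hatchling_surface"`, or `"cgm<k>"` for the k-th growth mark.
#' @param check If `TRUE` (default), verify that the outline is simple
#'   (non-self-intersecting). The check is quadratic in the number of edges;
#'   it can be disabled for contours that are simple by construction.
#' @return An object of class `bone_contour`: a list with elements
#'   `vertices` (n x 2 numeric matrix, counter-clockwise, open ring) and
#'   `label`.
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' perimeter(sq)      # 4
#' enclosed_area(sq)  # 1
#' @export
contour <- function(x, y = NULL, label = "surface", check = TRUE) {
  if (is.null(y)) {
    v <- as.matrix(x)
    if (ncol(v) != 2L)
      stop("'x' must be a two-column matrix when 'y' is missing")
  } else {
    if (length(x) != length(y))
      stop("'x' and 'y' lengths differ")
    v <- cbind(x, y)
  }
  storage.mode(v) <- "double"
  if (anyNA(v)) stop("contour vertices contain missing values")
  n <- nrow(v)
  if (n >= 2L && isTRUE(all.equal(v[1L, ], v[n, ], tolerance = 1e-12,
                                  check.attributes = FALSE))) {
    v <- v[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("degenerate contour: fewer than 3 vertices")
  a <- .signed_area(v)
  if (abs(a) < 1e-12) stop("degenerate contour: zero enclosed area")
  if (a < 0) v <- v[n:1L, , drop = FALSE]  # store counter-clockwise
  if (isTRUE(check) && .self_intersects(v))
    stop("degenerate contour: outline is self-intersecting")
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(vertices = v, label = as.character(label)[1L]),
            class = "bone_contour")
}

#' @export
print.bone_contour <- function(x, ...) {
  cat(sprintf("<bone_contour '%s': %d vertices, perimeter %.4g mm, area %.4g mm^2>\n",
              x$label, nrow(x$vertices), perimeter(x), enclosed_area(x)))
  invisible(x)
}

.is_contour <- function(x) inherits(x, "bone_contour")

.check_contour <- function(x) {
  if (!.is_contour(x)) stop("expected a 'bone_contour' object")
  x
}

# Shoelace signed area; positive for counter-clockwise rings.
.signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Segment-sweep simplicity test: any two non-adjacent edges that properly
# intersect (or overlap) make the outline invalid. Vectorised over the
# partner edge for each anchor edge.
.self_intersects <- function(v) {
  n <- nrow(v)
  p <- v
  q <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]           # edge n is adjacent to edge 1
    if (!length(j)) next
    d1 <- .cross(q[i, 1L] - p[i, 1L], q[i, 2L] - p[i, 2L],
                 p[j, 1L] - p[i, 1L], p[j, 2L] - p[i, 2L])
    d2 <- .cross(q[i, 1L] - p[i, 1L], q[i, 2L] - p[i, 2L],
                 q[j, 1L] - p[i, 1L], q[j, 2L] - p[i, 2L])
    d3 <- .cross(q[j, 1L] - p[j, 1L], q[j, 2L] - p[j, 2L],
                 p[i, 1L] - p[j, 1L], p[i, 2L] - p[j, 2L])
    d4 <- .cross(q[j, 1L] - p[j, 1L], q[j, 2L] - p[j, 2L],
                 q[i, 1L] - p[j, 1L], q[i, 2L] - p[j, 2L])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

.cross <- function(ax, ay, bx, by) ax * by - ay * bx

#' Perimeter of a closed contour
#'
#' Sum of consecutive edge lengths including the closing edge, in mm.
#'
#' @param c A [contour()].
#' @return Perimeter in mm (strictly positive).
#' @export
perimeter <- function(c) {
  v <- .check_contour(c)$vertices
  d <- v[c(2:nrow(v), 1L), , drop = FALSE] - v
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

#' Area enclosed by a closed contour
#'
#' Absolute shoelace area, independent of stored orientation, in mm^2.
#'
#' @param c A [contour()].
#' @return Enclosed area in mm^2.
#' @export
enclosed_area <- function(c) {
  abs(.signed_area(.check_contour(c)$vertices))
}

# Area-weighted polygon moments about the origin for a CCW vertex ring:
# A, integral x dA, integral y dA, integral x^2 dA, integral y^2 dA,
# integral xy dA. Standard Green's-theorem closed forms.
.polygon_moments <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  list(
    area = A,
    sx   = sum((x + xn) * cr) / 6,
    sy   = sum((y + yn) * cr) / 6,
    sxx  = sum((x^2 + x * xn + xn^2) * cr) / 12,
    syy  = sum((y^2 + y * yn + yn^2) * cr) / 12,
    sxy  = sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  )
}

#' Polygonal approximation of an ellipse
#'
#' Convenience constructor for elliptical contours, used for fixtures,
#' examples, and as the base shape of the synthetic growth-ring generator.
#'
#' @param a,b Semi-axes in mm.
#' @param n Number of vertices.
#' @param centre Centre point, length-2 numeric.
#' @param rotation Rotation of the major axis in radians.
#' @param label Contour label.
#' @return A [contour()] with `n` vertices on the ellipse.
#' @export
ellipse_contour <- function(a, b = a, n = 120L, centre = c(0, 0),
                            rotation = 0, label = "surface") {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- a * cos(th); y0 <- b * sin(th)
  x <- centre[1L] + x0 * cos(rotation) - y0 * sin(rotation)
  y <- centre[2L] + x0 * sin(rotation) + y0 * cos(rotation)
  contour(x, y, label = label, check = FALSE)
}

# Even-odd point-in-polygon, vectorised over points.
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}
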