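#' Annular region of cortical bone between two contours
#'
#' Pairs an outer boundary (a growth mark or the periosteal surface) with the
#' medullary boundary it encloses. The inner contour may be absent, in which
#' case the region is the full cross-section. When present, the inner contour
#' must lie strictly within the outer one and enclose less area.
#'
#' @param outer A [contour()] forming the outer boundary.
#' @param inner A [contour()] forming the inner (medullary) boundary, or
#'   `NULL`.
#' @return An object of class `annular_section`.
#' @export
annular_section <- function(outer, inner = NULL) {
  .check_contour(outer)
  if (!is.null(inner)) {
    .check_contour(inner)
    vi <- inner$vertices
    if (!all(.points_in_polygon(vi[, 1L], vi[, 2L], outer$vertices)))
      stop("nesting error: inner contour is not contained in the outer contour")
    if (enclosed_area(inner) >= enclosed_area(outer))
      stop("nesting error: inner contour encloses at least as much area as the outer")
  }
  structure(list(outer = outer, inner = inner), class = "annular_section")
}

.check_section <- function(s) {
  if (!inherits(s, "annular_section")) stop("expected an 'annular_section' object")
  s
}

#' @export
print.annular_section <- function(x, ...) {
  cat(sprintf("<annular_section: outer '%s'%s, cortical area %.4g mm^2>\n",
              x$outer$label,
              if (is.null(x$inner)) "" else sprintf(", inner '%s'", x$inner$label),
              cortical_area(x)))
  invisible(x)
}

#' Cortical area of an annular section
#'
#' Area of bone between the outer boundary and the medullary boundary:
#' `enclosed_area(outer) - enclosed_area(inner)`, or the full enclosed area
#' when no inner contour is present. This is the quantity tabulated as
#' "cortical area" for each growth level.
#'
#' @param s An [annular_section()].
#' @return Cortical area in mm^2.
#' @export
cortical_area <- function(s) {
  .check_section(s)
  a <- enclosed_area(s$outer)
  if (!is.null(s$inner)) a <- a - enclosed_area(s$inner)
  a
}

#' Geometric centroid of the cortical annulus
#'
#' Centroid of the annular region by signed-area composition,
#' `C = (A_o C_o - A_i C_i) / (A_o - A_i)`. The medullary cavity is not bone,
#' so the cavity area is subtracted rather than included.
#'
#' @param s An [annular_section()].
#' @return Length-2 numeric, centroid coordinates in mm.
#' @export
region_centroid <- function(s) {
  .check_section(s)
  mo <- .polygon_moments(s$outer$vertices)
  sx <- mo$sx; sy <- mo$sy; A <- mo$area
  if (!is.null(s$inner)) {
    mi <- .polygon_moments(s$inner$vertices)
    sx <- sx - mi$sx; sy <- sy - mi$sy; A <- A - mi$area
  }
  if (abs(A) < 1e-12) stop("zero-area error: outer and inner areas are equal")
  c(x = sx / A, y = sy / A)
}

#' Principal frame of the cortical annulus
#'
#' Computes the second area moments of the annular region about its centroid
#' by polygon moment formulas (inner boundary subtracted) and derives the
#' principal axes as the eigenvectors of the 2 x 2 moment tensor. The major
#' axis is the direction of the larger variance of bone area. Second moments
#' follow the engineering convention: `Ixx = integral y'^2 dA`,
#' `Iyy = integral x'^2 dA`, `Ixy = integral x'y' dA` in centroidal
#' coordinates, so the variance tensor is `[[Iyy, Ixy], [Ixy, Ixx]]`.
#'
#' For (numerically) isotropic sections the eigenvalues tie and the axes
#' default deterministically to the +x/+y coordinate frame. Axis signs are
#' fixed so that the major axis has a positive x component (positive y when
#' perpendicular to x), making four-ray radial profiles reproducible.
#'
#' @param s An [annular_section()].
#' @return An object of class `principal_frame`: list with `centroid` (mm),
#'   `major_axis`, `minor_axis` (unit vectors), `second_moments`
#'   (named `Ixx`, `Iyy`, `Ixy`, mm^4) and `eigenvalues` (major, minor).
#' @export
principal_frame <- function(s) {
  .check_section(s)
  mo <- .polygon_moments(s$outer$vertices)
  A <- mo$area; sx <- mo$sx; sy <- mo$sy
  sxx <- mo$sxx; syy <- mo$syy; sxy <- mo$sxy
  if (!is.null(s$inner)) {
    mi <- .polygon_moments(s$inner$vertices)
    A <- A - mi$area; sx <- sx - mi$sx; sy <- sy - mi$sy
    sxx <- sxx - mi$sxx; syy <- syy - mi$syy; sxy <- sxy - mi$sxy
  }
  if (abs(A) < 1e-12) stop("zero-area error: outer and inner areas are equal")
  cx <- sx / A; cy <- sy / A
  # central second moments (parallel-axis shift)
  vxx <- sxx - A * cx^2
  vyy <- syy - A * cy^2
  vxy <- sxy - A * cx * cy
  M <- matrix(c(vxx, vxy, vxy, vyy), 2L, 2L)  # variance tensor [[x2, xy], [xy, y2]]
  scale <- max(abs(M)) + 1e-300
  if (abs(vxx - vyy) / scale < 1e-9 && abs(vxy) / scale < 1e-9) {
    major <- c(1, 0); minor <- c(0, 1)
    ev <- c(vxx, vyy)
  } else {
    e <- eigen(M, symmetric = TRUE)
    major <- e$vectors[, 1L]
    minor <- e$vectors[, 2L]
    ev <- e$values
  }
  if (major[1L] < 0 || (abs(major[1L]) < 1e-12 && major[2L] < 0)) major <- -major
  if (minor[2L] < 0 || (abs(minor[2L]) < 1e-12 && minor[1L] < 0)) minor <- -minor
  structure(list(
    centroid = c(x = cx, y = cy),
    major_axis = major,
    minor_axis = minor,
    second_moments = c(Ixx = vyy, Iyy = vxx, Ixy = vxy),
    eigenvalues = ev
  ), class = "principal_frame")
}

#' @export
print.principal_frame <- function(x, ...) {
  cat(sprintf("<principal_frame: centroid (%.4g, %.4g) mm, major axis (%.4f, %.4f)>\n",
              x$centroid[1L], x$centroid[2L], x$major_axis[1L], x$major_axis[2L]))
  invisible(x)
}

# First boundary crossing along ray origin + t*dir (t > 0) against the edges
# of a vertex ring. Returns the smallest positive t, the number of distinct
# crossings found, or NA when the ray misses the contour.
.ray_crossing <- function(origin, dir, v) {
  n <- nrow(v)
  p <- v
  q <- v[c(2:n, 1L), , drop = FALSE]
  ex <- q[, 1L] - p[, 1L]; ey <- q[, 2L] - p[, 2L]
  denom <- dir[1L] * ey - dir[2L] * ex
  wx <- p[, 1L] - origin[1L]; wy <- p[, 2L] - origin[2L]
  t <- (wx * ey - wy * ex) / denom
  u <- (wx * dir[2L] - wy * dir[1L]) / denom
  # a small tolerance on the edge parameter keeps rays that pass exactly
  # through a shared vertex from slipping between the two adjacent edges
  ok <- is.finite(t) & is.finite(u) & t > 1e-12 & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(ok)) return(list(t = NA_real_, k = 0L))
  ts <- sort(t[ok])
  # collapse numerically duplicate hits at shared vertices
  k <- sum(c(TRUE, diff(ts) > 1e-9 * pmax(1, ts[-1L])))
  list(t = ts[1L], k = k)
}

#' Four-ray radial profile of a contour
#'
#' Distances in mm from the frame centroid to the first crossing of the
#' contour along the +major, -major, +minor, and -minor principal directions,
#' together with their mean. The mean of the four distances is the cumulative
#' cortical radial thickness `T_n` recorded at each growth mark.
#'
#' The contour must be star-convex with respect to the centroid; if a ray
#' crosses the boundary more than once the nearest crossing is used and a
#' warning is issued (real diaphyseal sections are near-convex).
#'
#' @param frame A [principal_frame()].
#' @param c A [contour()].
#' @return List with `distances` (named length-4 numeric, mm) and `mean`
#'   (cumulative radial thickness, mm).
#' @export
radial_profile <- function(frame, c) {
  if (!inherits(frame, "principal_frame")) stop("expected a 'principal_frame' object")
  v <- .check_contour(c)$vertices
  dirs <- rbind(frame$major_axis, -frame$major_axis,
                frame$minor_axis, -frame$minor_axis)
  d <- numeric(4L)
  multi <- FALSE
  for (i in 1:4) {
    hit <- .ray_crossing(frame$centroid, dirs[i, ], v)
    if (is.na(hit$t))
      stop("geometry error: ray from centroid does not intersect the contour")
    if (hit$k > 1L) multi <- TRUE
    d[i] <- hit$t
  }
  if (multi)
    warning("contour is not star-convex about the centroid; nearest crossings used")
  names(d) <- c("major_pos", "major_neg", "minor_pos", "minor_neg")
  list(distances = d, mean = mean(d))
}

#' Measure a traced section into growth-level rows
#'
#' Applies the full geometry pipeline to one section's contour set: the
#' medullary boundary, any fully traced growth marks, and the periosteal
#' surface. Circumference (perimeter) and cortical area (level area minus
#' medullary area) are reported per level; cumulative cortical radial
#' thickness is the four-ray mean distance from the geometric centroid of
#' the whole cortical annulus (surface minus medullary cavity), measured
#' along its principal axes, following the convention that one centroid and
#' one axis frame serve all levels of a section.
#'
#' @param contours List of [contour()] objects for one section. Labels must
#'   include `"medullary"` and `"surface"`; growth marks are labelled
#'   `"cgm1"`, `"cgm2"`, ... .
#' @return Data frame with columns `level`, `circumference_mm`, `area_mm2`,
#'   `thickness_mm` (NA for the medullary row).
#' @export
measure_section <- function(contours) {
  labs <- vapply(contours, function(ct) .check_contour(ct)$label, character(1L))
  if (!"surface" %in% labs) stop("section has no 'surface' contour")
  if (!"medullary" %in% labs) stop("section has no 'medullary' contour")
  med <- contours[[match("medullary", labs)]]
  surf <- contours[[match("surface", labs)]]
  frame <- principal_frame(annular_section(surf, med))
  cgm_labs <- labs[grepl("^cgm[0-9]+$", labs)]
  cgm_labs <- cgm_labs[order(as.integer(sub("^cgm", "", cgm_labs)))]
  levels <- c("medullary", cgm_labs, "surface")
  out <- data.frame(level = levels, circumference_mm = NA_real_,
                    area_mm2 = NA_real_, thickness_mm = NA_real_,
                    stringsAsFactors = FALSE)
  med_area <- enclosed_area(med)
  for (i in seq_along(levels)) {
    ct <- contours[[match(levels[i], labs)]]
    out$circumference_mm[i] <- perimeter(ct)
    if (levels[i] == "medullary") {
      out$area_mm2[i] <- med_area
    } else {
      out$area_mm2[i] <- enclosed_area(ct) - med_area
      out$thickness_mm[i] <- radial_profile(frame, ct)$mean
    }
  }
  out
}
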