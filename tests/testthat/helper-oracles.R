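# Independent geometry oracles and polygon generators used across the suite.
# All are deliberately written as brute-force / closed-form alternatives to
# the package's Green's-theorem implementations.

# Random star-convex polygon about `centre`: perturbed ellipse radii.
random_star_polygon <- function(n = 80L, r0 = 1, aspect = 1.5, amp = 0.08,
                                centre = c(0, 0), label = "surface") {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- r0 * sqrt(aspect); b <- r0 / sqrt(aspect)
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  for (k in 2:4)
    r <- r * (1 + runif(1, 0, amp) * cos(k * th + runif(1, 0, 2 * pi)))
  contour(centre[1L] + r * cos(th), centre[2L] + r * sin(th), label = label)
}

# Nested pair sharing a star centre: inner well inside outer.
random_nested_pair <- function(n = 80L) {
  outer <- random_star_polygon(n, r0 = runif(1, 2, 3), aspect = runif(1, 1.1, 1.8))
  inner <- random_star_polygon(n, r0 = runif(1, 0.4, 0.8),
                               aspect = runif(1, 1, 1.4),
                               centre = runif(2, -0.2, 0.2), label = "medullary")
  annular_section(outer, inner)
}

# Exact oracle: triangle-fan decomposition from an interior point, using the
# closed-form area / centroid / second-moment formulas of a triangle.
fan_region_stats <- function(vo, vi = NULL, apex = c(0, 0)) {
  one <- function(v) {
    v <- unname(v); apex <- unname(apex)
    n <- nrow(v)
    A <- 0; sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
    for (i in seq_len(n)) {
      p1 <- apex; p2 <- v[i, ]; p3 <- v[if (i == n) 1L else i + 1L, ]
      at <- ((p2[1] - p1[1]) * (p3[2] - p1[2]) -
               (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
      x <- c(p1[1], p2[1], p3[1]); y <- c(p1[2], p2[2], p3[2])
      A <- A + at
      sx <- sx + at * mean(x); sy <- sy + at * mean(y)
      sxx <- sxx + at / 6 * (sum(x^2) + x[1] * x[2] + x[2] * x[3] + x[1] * x[3])
      syy <- syy + at / 6 * (sum(y^2) + y[1] * y[2] + y[2] * y[3] + y[1] * y[3])
      sxy <- sxy + at / 12 * (2 * sum(x * y) + x[1] * y[2] + x[2] * y[1] +
                                x[2] * y[3] + x[3] * y[2] + x[1] * y[3] + x[3] * y[1])
    }
    list(A = A, sx = sx, sy = sy, sxx = sxx, syy = syy, sxy = sxy)
  }
  o <- one(vo)
  if (!is.null(vi)) {
    i <- one(vi)
    o <- Map(`-`, o, i)
  }
  cx <- o$sx / o$A; cy <- o$sy / o$A
  list(area = o$A, centroid = c(cx, cy),
       vxx = o$sxx - o$A * cx^2, vyy = o$syy - o$A * cy^2,
       vxy = o$sxy - o$A * cx * cy)
}

# Even-odd point-in-polygon, written independently for the rasterisation
# oracle.
oracle_pip <- function(px, py, v) {
  n <- nrow(v); inside <- logical(length(px)); j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# Rasterisation oracle: midpoint grid classification of the annular region.
grid_region_stats <- function(vo, vi = NULL, n = 500L) {
  xr <- range(vo[, 1]); yr <- range(vo[, 2])
  gx <- seq(xr[1], xr[2], length.out = n)
  gy <- seq(yr[1], yr[2], length.out = n)
  px <- rep(gx, times = n); py <- rep(gy, each = n)
  ins <- oracle_pip(px, py, vo)
  if (!is.null(vi)) ins <- ins & !oracle_pip(px, py, vi)
  cell <- diff(xr) / (n - 1) * diff(yr) / (n - 1)
  list(area = sum(ins) * cell, centroid = c(mean(px[ins]), mean(py[ins])))
}

# Brute-force ray/boundary oracle: scan every edge as a segment and return
# the nearest positive crossing distance.
edge_scan_distance <- function(origin, dir, v) {
  origin <- unname(origin); dir <- unname(dir); v <- unname(v)
  n <- nrow(v)
  best <- Inf
  for (i in seq_len(n)) {
    p <- v[i, ]; q <- v[if (i == n) 1L else i + 1L, ]
    e <- q - p
    den <- dir[1] * e[2] - dir[2] * e[1]
    if (abs(den) < 1e-14) next
    w <- p - origin
    t <- (w[1] * e[2] - w[2] * e[1]) / den
    u <- (w[1] * dir[2] - w[2] * dir[1]) / den
    if (t > 1e-12 && u >= -1e-9 && u <= 1 + 1e-9) best <- min(best, t)
  }
  if (is.finite(best)) best else NA_real_
}

# Minimal measurement-table row constructor for hand-built fixtures.
meas_row <- function(individual, element, side, level, circ = NA, area = NA,
                     thick = NA, status = "fully_traceable", partial = FALSE) {
  data.frame(individual = individual, element = element, side = side,
             level = level, circumference_mm = circ, area_mm2 = area,
             thickness_mm = thick, status = status, partial_year = partial,
             stringsAsFactors = FALSE)
}

# Hand-built element record from a cumulative-thickness series (marks only).
record_from_thickness <- function(thick_marks, surface, hatchling = NA,
                                  element = "femur", side = "left",
                                  individual = "T-1", medullary_circ = 1,
                                  partial = FALSE, statuses = NULL) {
  rows <- meas_row(individual, element, side, "medullary", circ = medullary_circ,
                   area = 0.5)
  if (!is.na(hatchling))
    rows <- rbind(rows, meas_row(individual, element, side, "hatchling",
                                 circ = 2, area = 1, thick = hatchling))
  for (i in seq_along(thick_marks)) {
    st <- if (is.null(statuses)) {
      if (is.na(thick_marks[i])) "not_fully_traceable" else "fully_traceable"
    } else statuses[i]
    rows <- rbind(rows, meas_row(individual, element, side, paste0("cgm", i),
                                 circ = if (st == "fully_traceable") 4 + i else NA,
                                 area = if (st == "fully_traceable") 2 + i else NA,
                                 thick = thick_marks[i], status = st))
  }
  rows <- rbind(rows, meas_row(individual, element, side, "surface",
                               circ = 20, area = 30, thick = surface,
                               partial = partial))
  element_records(rows)[[1L]]
}
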